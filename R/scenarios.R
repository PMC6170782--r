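#' Run a colony to a target cell count
#'
#' The workhorse loop behind the scenario runners: repeatedly calls
#' [step_colony()] until the colony holds `n_target` cells (or `max_steps`
#' is hit), recording metrics every `metrics_every` steps and full cell
#' snapshots every `snapshot_every` steps.  Each emitted snapshot carries
#' the per-cell displacement and rotation accumulated since the previous
#' snapshot (`acc_dx`, `acc_dy`, `acc_rot`), the source of ground-truth
#' velocity fields.
#'
#' @param colony a [colony].
#' @param n_target stop once `nrow(cells) >= n_target`.
#' @param max_steps hard step limit.
#' @param metrics_every record a [colony_metrics_row()] every this many
#'   steps (`NULL` = only at the end).
#' @param snapshot_every record a snapshot every this many steps
#'   (`NULL` = none).
#' @param with_circularity include circularity in recorded metrics.
#' @param adhesion_on engine adhesion code path toggle.
#' @return A list `(colony, metrics, snapshots)`.
#' @export
simulate_colony <- function(colony, n_target, max_steps = 100000L,
                            metrics_every = NULL, snapshot_every = NULL,
                            with_circularity = FALSE, adhesion_on = TRUE) {
  metrics <- list()
  snapshots <- list()
  take_snapshot <- function(co) {
    snap <- list(time = co$time, step = co$step_index, cells = co$cells)
    snapshots[[length(snapshots) + 1L]] <<- snap
    reset_displacement_record(co)
  }
  if (!is.null(snapshot_every)) colony <- take_snapshot(colony)
  steps <- 0L
  while (nrow(colony$cells) < n_target && steps < max_steps) {
    colony <- step_colony(colony, adhesion_on = adhesion_on)
    steps <- steps + 1L
    if (!is.null(metrics_every) && steps %% metrics_every == 0L)
      metrics[[length(metrics) + 1L]] <-
        colony_metrics_row(colony, with_circularity)
    if (!is.null(snapshot_every) && steps %% snapshot_every == 0L)
      colony <- take_snapshot(colony)
  }
  metrics[[length(metrics) + 1L]] <- colony_metrics_row(colony, with_circularity)
  if (!is.null(snapshot_every) && colony$step_index %% snapshot_every != 0L)
    colony <- take_snapshot(colony)
  list(colony = colony, metrics = do.call(rbind, metrics),
       snapshots = snapshots)
}

new_scenario_result <- function(name, params, metrics, snapshots, seed,
                                extra = list()) {
  structure(c(list(scenario = name, params = params, metrics = metrics,
                   snapshots = snapshots, seed = seed), extra),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result: %s> seed %d, %d metric rows, %d snapshots\n",
              x$scenario, x$seed, nrow(x$metrics), length(x$snapshots)))
  if (!is.null(x$metrics) && nrow(x$metrics) > 0) {
    last <- x$metrics[nrow(x$metrics), ]
    cat(sprintf("  final: %d cells at t = %.2f h, radius %.1f um\n",
                last$n_cells, last$time, last$colony_radius))
  }
  invisible(x)
}

#' Microcolony morphology experiment
#'
#' Grows a single founder to `n_target` cells at the given adhesion
#' strength, recording circularity along the way.  At zero adhesion the
#' colony outline stays near-circular; strong adhesion suppresses cell
#' slippage and produces chained, less circular outlines.
#'
#' @param adhesion adhesion strength (simulation units).
#' @param n_target target cell count.
#' @param seed RNG seed.
#' @param params physics parameter overrides (named list).
#' @param metrics_every,snapshot_every recording cadence in steps.
#' @return A `scenario_result`.
#' @export
run_microcolony <- function(adhesion, n_target = 200, seed = 1,
                            params = list(), metrics_every = 25L,
                            snapshot_every = NULL) {
  stopifnot(adhesion >= 0, n_target >= 1)
  p <- do.call(physics_params,
               modifyList(list(adhesion_default = adhesion, seed = seed),
                          params))
  set.seed(derive_seed(seed, "physics"))
  colony <- colony_founder(p)
  res <- simulate_colony(colony, n_target, metrics_every = metrics_every,
                         snapshot_every = snapshot_every,
                         with_circularity = TRUE)
  new_scenario_result("microcolony",
                      list(adhesion = adhesion, n_target = n_target,
                           physics = p),
                      res$metrics, res$snapshots, as.integer(seed),
                      extra = list(colony = res$colony))
}

#' Two-domain lineage colony experiment
#'
#' Starts from two identical touching founder cells, one green and one red,
#' with uniform adhesion between all cells, and grows to `n_target` cells
#' recording the interdomain contact ratio.  The ratio of contacts between
#' cells of different domains to all contacts measures the interaction area
#' between the two lineages.
#'
#' @inheritParams run_microcolony
#' @return A `scenario_result`.
#' @export
run_two_domain <- function(adhesion, n_target = 5000, seed = 1,
                           params = list(), metrics_every = 50L,
                           snapshot_every = NULL) {
  stopifnot(adhesion >= 0, n_target >= 2)
  p <- do.call(physics_params,
               modifyList(list(adhesion_default = adhesion, seed = seed),
                          params))
  set.seed(derive_seed(seed, "physics"))
  colony <- colony_two_founders(p)
  res <- simulate_colony(colony, n_target, metrics_every = metrics_every,
                         snapshot_every = snapshot_every)
  new_scenario_result("two_domain",
                      list(adhesion = adhesion, n_target = n_target,
                           physics = p),
                      res$metrics, res$snapshots, as.integer(seed),
                      extra = list(colony = res$colony))
}

#' Chain force-propagation experiment
#'
#' A chain of `n_cells` identical non-growing cells lying side by side in
#' contact along their long axes.  Antiparallel forces of magnitude
#' `force_magnitude`, directed along the cells' long axis (perpendicular to
#' the chain axis), are applied to the two end cells; the chain is stepped
#' until each end cell has slid `displacement_target` micrometres, and the
#' displacement of every cell is recorded.  Repeated for each adhesion
#' strength.  Without adhesion the ends slide off freely and interior cells
#' barely move; adhesion propagates force and motion down the chain.
#'
#' @param n_cells chain length (>= 3).
#' @param force_magnitude end-cell force (simulation units).
#' @param adhesion_values adhesion strengths to sweep.  The default spans
#'   the force-propagating regime; above roughly 4 the transverse drag
#'   saturates into rigid tangential coupling and the whole chain starts to
#'   translate and rotate as one body, flattening the lateral profile.
#' @param displacement_target end-cell displacement (um) at which each run
#'   stops.
#' @param cell_length axis length of the chain cells (um).
#' @param params physics parameter overrides.
#' @param max_steps per-run step limit; exceeded -> error.
#' @return Data frame with columns `adhesion`, `cell` (1..n, ordered along
#'   the chain), `disp_x` (signed displacement along the force direction),
#'   `disp_y`, `displacement` (absolute along-force displacement).
#' @export
run_chain <- function(n_cells = 10, force_magnitude = 5,
                      adhesion_values = c(0, 0.5, 1, 2, 3),
                      displacement_target = 2, cell_length = 4,
                      params = list(), max_steps = 2000L) {
  stopifnot(n_cells >= 3, displacement_target > 0)
  p <- do.call(physics_params, params)
  # integrate in short bursts so the end-displacement stop condition is
  # checked at fine granularity (a full relaxation budget per check would
  # overshoot any target in one call)
  p$relax_iters <- 20L
  out <- list()
  for (adh in adhesion_values) {
    cells <- new_cells(seq_len(n_cells),
                       x = rep(0, n_cells),
                       y = (seq_len(n_cells) - (n_cells + 1) / 2) *
                         2 * p$cap_radius,
                       dx = 1, dy = 0,
                       length = cell_length, radius = p$cap_radius,
                       growth_rate = 0, division_length = Inf,
                       domain_label = "green", adhesin = adh,
                       growing = FALSE)
    colony <- new_colony(cells, p)
    colony <- apply_external_force(
      colony, data.frame(id = c(1L, n_cells),
                         fx = c(force_magnitude, -force_magnitude),
                         fy = c(0, 0)))
    x0 <- colony$cells$x
    y0 <- colony$cells$y
    steps <- 0L
    repeat {
      colony <- relax_colony(colony)
      steps <- steps + 1L
      dend <- abs(colony$cells$x[c(1L, n_cells)] - x0[c(1L, n_cells)])
      if (all(dend >= displacement_target)) break
      if (steps >= max_steps)
        stop(sprintf("displacement target unreachable within %d steps (adhesion %g)",
                     max_steps, adh))
    }
    out[[length(out) + 1L]] <- data.frame(
      adhesion = adh, cell = seq_len(n_cells),
      disp_x = colony$cells$x - x0, disp_y = colony$cells$y - y0,
      displacement = abs(colony$cells$x - x0))
  }
  do.call(rbind, out)
}

#' Rasterize a snapshot stream into a synthetic time-lapse
#'
#' Renders each snapshot as a fluorescence-like frame (capsule interiors at
#' unit intensity, Gaussian point-spread blur, additive Gaussian noise) on
#' a fixed canvas covering the whole movie, and computes the ground-truth
#' per-pixel velocity field for every consecutive frame pair from the
#' recorded per-cell displacements by nearest-cell rigid-motion assignment.
#'
#' @param snapshots snapshot list from [simulate_colony()] (or a
#'   `scenario_result` run with `snapshot_every`).
#' @param pixel_size um per pixel (default 0.1, confocal-like).
#' @param frame_interval minutes between snapshots (bookkeeping only; must
#'   match the simulation cadence used to produce the snapshots).
#' @param psf_sigma Gaussian point-spread sigma in pixels.
#' @param noise_sd additive Gaussian noise standard deviation as a fraction
#'   of the maximum intensity.
#' @param seed RNG seed for the noise stream.
#' @param pad canvas margin (um).
#' @param truth_pairs indices of frame pairs for which to compute the
#'   ground-truth field (pair `i` spans frames `i, i+1`); `NULL` computes
#'   every pair.  Restricting the set keeps memory modest for long movies.
#' @param frames_every emit a movie frame every this many snapshots.  With
#'   snapshots recorded every simulation step and `frames_every` chosen so
#'   that frames fall `frame_interval` apart, the ground-truth field of a
#'   frame pair is composed step by step (material points are tracked
#'   through every intermediate snapshot), which keeps the motion model
#'   accurate across divisions and large rotations.
#' @return A list of class `timelapse`: `frames` (list of intensity
#'   matrices in `[0, 1+noise]`), `masks` (logical, pixels covered by any
#'   cell), `truth` (list of `(u, v)` ground-truth fields in px/frame, one
#'   per frame pair, `NA` outside the pair's mask), `labels0` (integer
#'   raster of founder domains in frame 1: 0 background, 1 green, 2 red),
#'   `pixel_size`, `frame_interval`.
#' @export
render_timelapse <- function(snapshots, pixel_size = 0.1, frame_interval = 10,
                             psf_sigma = 2, noise_sd = 0.02, seed = 1,
                             pad = 3, frames_every = 1, truth_pairs = NULL) {
  if (inherits(snapshots, "scenario_result")) snapshots <- snapshots$snapshots
  if (length(snapshots) == 0L || any(vapply(snapshots, function(s)
    nrow(s$cells) == 0L, logical(1))))
    stop("empty snapshot")
  stopifnot(pixel_size > 0)
  ext <- function(s) {
    e <- max(s$cells$length / 2 + s$cells$radius)
    c(min(s$cells$x) - e, max(s$cells$x) + e,
      min(s$cells$y) - e, max(s$cells$y) + e)
  }
  bb <- vapply(snapshots, ext, numeric(4))
  x0 <- min(bb[1, ]) - pad; x1 <- max(bb[2, ]) + pad
  y0 <- min(bb[3, ]) - pad; y1 <- max(bb[4, ]) + pad
  nc <- as.integer(ceiling((x1 - x0) / pixel_size))
  nr <- as.integer(ceiling((y1 - y0) / pixel_size))
  set.seed(derive_seed(seed, "render"))
  kern <- if (psf_sigma > 0) gaussian_kernel(psf_sigma) else NULL
  frame_idx <- seq(1L, length(snapshots), by = as.integer(frames_every))
  n_frames <- length(frame_idx)
  frames <- vector("list", n_frames)
  masks <- vector("list", n_frames)
  idx_maps <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    cl <- snapshots[[frame_idx[f]]]$cells
    ras <- rasterize_cells_cpp(cl$x, cl$y, cl$dx, cl$dy, cl$length, cl$radius,
                               cl$brightness, x0, y0, pixel_size, nr, nc)
    masks[[f]] <- ras$index > 0
    idx_maps[[f]] <- ras$index
    img <- ras$intensity
    if (!is.null(kern)) img <- sep_filter2_cpp(img, kern, kern)
    if (noise_sd > 0) img <- img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    frames[[f]] <- pmax(img, 0)
  }
  # ground truth per frame pair: track the frame's mask pixels through every
  # intermediate snapshot (sub-interval mappings composed in world space)
  truth <- vector("list", n_frames - 1L)
  if (is.null(truth_pairs)) truth_pairs <- seq_len(n_frames - 1L)
  for (f in intersect(truth_pairs, seq_len(n_frames - 1L))) {
    msk <- masks[[f]]
    pix <- which(msk)
    prow <- (pix - 1L) %% nr + 1L
    pcol <- (pix - 1L) %/% nr + 1L
    wx0 <- x0 + (pcol - 0.5) * pixel_size
    wy0 <- y0 + (prow - 0.5) * pixel_size
    wx <- wx0; wy <- wy0
    for (k in frame_idx[f]:(frame_idx[f + 1L] - 1L)) {
      cl <- snapshots[[k + 1L]]$cells
      prex <- cl$x - cl$acc_dx
      prey <- cl$y - cl$acc_dy
      ct <- cos(-cl$acc_rot); st <- sin(-cl$acc_rot)
      pdx <- ct * cl$dx - st * cl$dy
      pdy <- st * cl$dx + ct * cl$dy
      tp <- truth_points_cpp(prex, prey, pdx, pdy,
                             cl$length / cl$acc_stretch, cl$radius,
                             cl$acc_dx, cl$acc_dy, cl$acc_rot, cl$acc_stretch,
                             wx, wy)
      wx <- wx + tp$dx
      wy <- wy + tp$dy
    }
    u <- v <- matrix(NA_real_, nr, nc)
    u[pix] <- (wx - wx0) / pixel_size
    v[pix] <- (wy - wy0) / pixel_size
    truth[[f]] <- list(u = u, v = v, mask = msk)
  }
  lab <- setNames(c(green = 1L, red = 2L)[snapshots[[1L]]$cells$domain_label],
                  NULL)
  lab[is.na(lab)] <- 1L
  labels0 <- matrix(0L, nr, nc)
  nz <- idx_maps[[1L]] > 0
  labels0[nz] <- lab[idx_maps[[1L]][nz]]
  structure(list(frames = frames, masks = masks, truth = truth,
                 labels0 = labels0, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 origin = c(x0, y0)),
            class = "timelapse")
}

#' @export
print.timelapse <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<timelapse> %d frames of %d x %d px (%.3g um/px, %g min/frame)\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}
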