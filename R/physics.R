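#' Physics parameters for the colony engine
#'
#' Units: 1 length unit = 1 micrometre, 1 time unit = 1 hour; adhesion
#' strength is a dimensionless multiplier ("simulation units") on the
#' transverse contact drag.
#'
#' @param dt simulation time step (h).
#' @param gamma translational drag coefficient per unit cell length
#'   (drag = `gamma * (length + 2 * radius)`).
#' @param gamma_rot rotational drag per unit cell length cubed.
#' @param k_contact linear repulsion stiffness resolving overlap.
#' @param adhesion_default global adhesion strength given to founder cells.
#' @param relax_iters maximum constraint-relaxation sub-steps per step.
#' @param overlap_tol maximum residual overlap (um) accepted as converged.
#' @param dt_sub relaxation sub-step (h); chosen small enough that
#'   `k_contact * dt_sub / (gamma * L)` stays well below 1.
#' @param contact_margin contact declaration margin (um).
#' @param mean_growth_rate mean relative elongation rate (1/h).  With the
#'   default division geometry (birth at 1 um axis, division at 3 um) the
#'   default rate gives a generation time of about 71 min, a typical pace
#'   for plasmid-carrying rod bacteria on solid media at 37 C.
#' @param growth_noise_cv coefficient of variation of daughter growth rates.
#' @param mean_division_length mean axis length (um) triggering division.
#' @param division_noise_cv coefficient of variation of division length.
#' @param daughter_jitter_deg half-width (degrees) of the uniform angular
#'   jitter given to daughter orientations; seeds buckling instabilities.
#' @param brightness_cv lognormal sigma of the per-division jitter on the
#'   heritable per-cell fluorescence brightness (cell-to-cell expression
#'   variability; gives rendered movies realistic texture).
#' @param cap_radius capsule cap radius (um).
#' @param seed RNG seed recorded with the run.
#' @return A list of class `physics_params`.
#' @export
physics_params <- function(dt = 1 / 24,
                           gamma = 1,
                           gamma_rot = 1,
                           k_contact = 200,
                           adhesion_default = 0,
                           relax_iters = 600,
                           overlap_tol = 0.01,
                           dt_sub = 0.004,
                           contact_margin = 0.05,
                           mean_growth_rate = log(2) / 0.75,
                           growth_noise_cv = 0.05,
                           mean_division_length = 3,
                           division_noise_cv = 0.05,
                           daughter_jitter_deg = 0.5,
                           brightness_cv = 0.15,
                           cap_radius = 0.5,
                           seed = 1L) {
  p <- list(dt = dt, gamma = gamma, gamma_rot = gamma_rot,
            k_contact = k_contact, adhesion_default = adhesion_default,
            relax_iters = as.integer(relax_iters), overlap_tol = overlap_tol,
            dt_sub = dt_sub, contact_margin = contact_margin,
            mean_growth_rate = mean_growth_rate,
            growth_noise_cv = growth_noise_cv,
            mean_division_length = mean_division_length,
            division_noise_cv = division_noise_cv,
            daughter_jitter_deg = daughter_jitter_deg,
            brightness_cv = brightness_cv,
            cap_radius = cap_radius, seed = as.integer(seed))
  stopifnot(p$dt > 0, p$gamma > 0, p$gamma_rot > 0, p$overlap_tol > 0,
            p$relax_iters >= 1, p$dt_sub > 0, p$contact_margin >= 0,
            p$adhesion_default >= 0)
  class(p) <- "physics_params"
  p
}

new_cells <- function(id, x, y, dx, dy, length, radius, growth_rate,
                      division_length, domain_label, adhesin, growing) {
  nrm <- sqrt(dx^2 + dy^2)
  data.frame(id = as.integer(id), x = x, y = y, dx = dx / nrm, dy = dy / nrm,
             length = length, radius = radius, growth_rate = growth_rate,
             division_length = division_length,
             domain_label = as.character(domain_label), adhesin = adhesin,
             growing = growing, brightness = 1,
             acc_dx = 0, acc_dy = 0, acc_rot = 0, acc_stretch = 1)
}

#' Create a colony
#'
#' @param cells a cell table as produced internally (see
#'   [colony_founder()]); advanced use only.
#' @param params a [physics_params] object.
#' @param time initial simulation time (h).
#' @return An object of class `colony`: a list with elements `cells`
#'   (data frame), `time`, `step_index`, `params`, `external` (persistent
#'   per-cell forces) and `next_id`.
#' @export
new_colony <- function(cells, params = physics_params(), time = 0) {
  stopifnot(!anyDuplicated(cells$id))
  structure(list(cells = cells, time = time, step_index = 0L,
                 params = params,
                 external = data.frame(id = integer(), fx = numeric(),
                                       fy = numeric()),
                 next_id = max(cells$id) + 1L,
                 last = NULL),
            class = "colony")
}

#' Founder colonies
#'
#' `colony_founder()` builds a single-cell colony; `colony_two_founders()`
#' builds two identical side-by-side touching founders with distinct
#' lineage labels (green and red), the initial condition of the two-domain
#' experiment.
#'
#' @param params a [physics_params] object.
#' @param length founder axis length (um).
#' @param adhesin per-cell adhesion level; defaults to
#'   `params$adhesion_default`.
#' @param domain_label lineage label of the single founder.
#' @return A [colony].
#' @export
colony_founder <- function(params = physics_params(), length = 2,
                           adhesin = params$adhesion_default,
                           domain_label = "green") {
  cells <- new_cells(1L, 0, 0, 1, 0, length, params$cap_radius,
                     params$mean_growth_rate, params$mean_division_length,
                     domain_label, adhesin, TRUE)
  new_colony(cells, params)
}

#' @rdname colony_founder
#' @export
colony_two_founders <- function(params = physics_params(), length = 2,
                                adhesin = params$adhesion_default) {
  r <- params$cap_radius
  cells <- new_cells(1:2, c(0, 0), c(-r, r), c(1, 1), c(0, 0),
                     c(length, length), r,
                     params$mean_growth_rate, params$mean_division_length,
                     c("green", "red"), adhesin, TRUE)
  new_colony(cells, params)
}

#' @export
print.colony <- function(x, ...) {
  cat(sprintf("<colony> %d cells, t = %.3f h, step %d\n",
              nrow(x$cells), x$time, x$step_index))
  cat(sprintf("  adhesion default %.3g, dt %.4g h, k_contact %.3g\n",
              x$params$adhesion_default, x$params$dt, x$params$k_contact))
  invisible(x)
}

#' Plot a colony
#'
#' Draws each capsule as a thick rounded segment, coloured by lineage label.
#'
#' @param x a [colony].
#' @param cols named colours for domain labels.
#' @param ... passed to `plot.default`.
#' @export
plot.colony <- function(x, cols = c(green = "#2E8B57", red = "#C23B22"), ...) {
  cl <- x$cells
  hx <- cl$dx * cl$length / 2
  hy <- cl$dy * cl$length / 2
  ext <- max(cl$length / 2 + cl$radius)
  xr <- range(cl$x) + c(-ext, ext)
  yr <- range(cl$y) + c(-ext, ext)
  plot(NA, xlim = xr, ylim = yr, asp = 1, xlab = "x (um)", ylab = "y (um)", ...)
  usr <- graphics::par("usr")
  pin <- graphics::par("pin")
  lwd <- 2 * cl$radius / (usr[2] - usr[1]) * pin[1] * 96
  col <- cols[cl$domain_label]
  col[is.na(col)] <- "grey40"
  segments(cl$x - hx, cl$y - hy, cl$x + hx, cl$y + hy,
           col = col, lwd = pmax(lwd, 0.5), lend = "round")
  invisible(x)
}

#' Grow cells by exponential elongation
#'
#' Each growing cell's axis length is multiplied by
#' `exp(growth_rate * dt)`; positions and directions are untouched
#' (displacement arises only from contact resolution).
#'
#' @param colony a [colony].
#' @param dt elapsed time (h); defaults to the engine time step.
#' @return The updated colony.
#' @export
grow_cells <- function(colony, dt = colony$params$dt) {
  stopifnot(dt > 0)
  g <- colony$cells$growing
  f <- exp(colony$cells$growth_rate[g] * dt)
  colony$cells$length[g] <- colony$cells$length[g] * f
  colony$cells$acc_stretch[g] <- colony$cells$acc_stretch[g] * f
  colony
}

#' Divide cells that reached their division length
#'
#' Every cell with `length >= division_length` is replaced by two equally
#' sized daughters that exactly tile the parent capsule: axis length
#' `length / 2 - radius`, centres at `(length + 2 radius) / 4` along the
#' parent axis on either side of the parent centre, so the facing cap
#' spheres are tangent (zero overlap -- the incompressible-capsule reading
#' of bisection; material is neither created nor displaced at division).
#' Daughters inherit direction (plus a small uniform angular jitter),
#' lineage label and adhesin; their growth rate and division length are
#' resampled around the engine means with the configured coefficients of
#' variation.  Ids are fresh and deterministic given the RNG state.
#'
#' @param colony a [colony].
#' @return The updated colony.
#' @export
divide_cells <- function(colony) {
  p <- colony$params
  cl <- colony$cells
  div <- which(cl$growing & cl$length >= cl$division_length &
                 cl$length > 2 * cl$radius)
  if (length(div) == 0L) return(colony)
  par <- cl[div, , drop = FALSE]
  off <- (par$length + 2 * par$radius) / 4  # daughter centre offset along axis
  dlen <- par$length / 2 - par$radius
  n <- length(div)
  jit <- runif(2 * n, -p$daughter_jitter_deg, p$daughter_jitter_deg) * pi / 180
  gr <- rnorm(2 * n, p$mean_growth_rate, p$growth_noise_cv * p$mean_growth_rate)
  gr <- pmax(gr, 0.2 * p$mean_growth_rate)
  dl <- rnorm(2 * n, p$mean_division_length,
              p$division_noise_cv * p$mean_division_length)
  dl <- pmax(dl, 0.5 * p$mean_division_length)
  sgn <- rep(c(-1, 1), each = n)
  idx <- rep(seq_len(n), 2)
  ct <- cos(jit); st <- sin(jit)
  ndx <- ct * par$dx[idx] - st * par$dy[idx]
  ndy <- st * par$dx[idx] + ct * par$dy[idx]
  daughters <- new_cells(
    id = colony$next_id + seq_len(2 * n) - 1L,
    x = par$x[idx] + sgn * off[idx] * par$dx[idx],
    y = par$y[idx] + sgn * off[idx] * par$dy[idx],
    dx = ndx, dy = ndy,
    length = dlen[idx], radius = par$radius[idx],
    growth_rate = gr, division_length = dl,
    domain_label = par$domain_label[idx],
    adhesin = par$adhesin[idx], growing = par$growing[idx]
  )
  # lineage bookkeeping for ground-truth velocities: tiling bisection moves
  # no material, so daughters inherit the parent's accumulated displacement
  # unchanged (their centres are new, their material is not)
  daughters$acc_dx <- par$acc_dx[idx]
  daughters$acc_dy <- par$acc_dy[idx]
  daughters$brightness <- pmin(pmax(
    par$brightness[idx] * exp(rnorm(2 * n, 0, p$brightness_cv)), 0.3), 3)
  daughters$acc_rot <- par$acc_rot[idx]
  daughters$acc_stretch <- par$acc_stretch[idx]
  colony$cells <- rbind(cl[-div, , drop = FALSE], daughters)
  rownames(colony$cells) <- NULL
  colony$next_id <- colony$next_id + 2L * n
  # external forces on a divided cell are dropped (its id disappears)
  colony$external <- colony$external[colony$external$id %in% colony$cells$id, ,
                                     drop = FALSE]
  colony
}

#' Relax overlaps under overdamped dynamics
#'
#' Iterates overdamped sub-steps `v = F / (gamma * L_eff)`,
#' `omega = tau / (gamma_rot * L_eff^3)` with `L_eff = length + 2 radius`,
#' where `F` composes contact repulsion, persistent external forces and
#' (unless `adhesion_on = FALSE`) the transverse adhesion drag evaluated at
#' the current iterate's tentative velocities.  Stops when the worst
#' overlap falls within `overlap_tol` (if no external forces act) or after
#' `relax_iters` sub-steps, in which case a warning is logged and the state
#' accepted.
#'
#' @param colony a [colony].
#' @param adhesion_on logical; `FALSE` selects the adhesion-free code path
#'   (the adhesion term is skipped entirely, not just zeroed).
#' @param warn_nonconverged warn when the iteration budget is exhausted
#'   with residual overlap; quiet by default inside long runs.
#' @return The colony with updated poses; the per-cell displacements,
#'   rotations and iteration record of the relaxation are stored in
#'   `$last`.
#' @export
relax_colony <- function(colony, adhesion_on = TRUE, warn_nonconverged = FALSE) {
  p <- colony$params
  cl <- colony$cells
  fx <- fy <- numeric(nrow(cl))
  if (nrow(colony$external) > 0) {
    m <- match(colony$external$id, cl$id)
    fx[m] <- colony$external$fx
    fy[m] <- colony$external$fy
  }
  res <- relax_cpp(cl$x, cl$y, cl$dx, cl$dy, cl$length, cl$radius, cl$adhesin,
                   fx, fy, p$k_contact, p$gamma, p$gamma_rot,
                   p$dt_sub, p$relax_iters, p$overlap_tol, p$contact_margin,
                   adhesion_on)
  if (!res$converged && warn_nonconverged)
    warning(sprintf("relaxation did not converge: residual overlap %.4g after %d iters",
                    res$max_overlap, res$iters))
  colony$cells$x <- res$x
  colony$cells$y <- res$y
  colony$cells$dx <- res$dx
  colony$cells$dy <- res$dy
  colony$cells$acc_dx <- cl$acc_dx + res$disp_x
  colony$cells$acc_dy <- cl$acc_dy + res$disp_y
  colony$cells$acc_rot <- cl$acc_rot + res$rot
  colony$last <- list(disp_x = res$disp_x, disp_y = res$disp_y,
                      rot = res$rot, iters = res$iters,
                      elapsed = res$elapsed,
                      max_overlap = res$max_overlap,
                      converged = res$converged)
  colony
}

#' Advance the colony by one time step
#'
#' Composition grow -> relax -> divide; time advances by `dt`.  Cell count
#' is non-decreasing and the per-cell displacement of the step is recorded
#' in `$last`.
#'
#' @inheritParams relax_colony
#' @return The advanced colony.
#' @export
step_colony <- function(colony, adhesion_on = TRUE) {
  colony <- grow_cells(colony)
  colony <- relax_colony(colony, adhesion_on = adhesion_on)
  colony <- divide_cells(colony)
  colony$time <- colony$time + colony$params$dt
  colony$step_index <- colony$step_index + 1L
  colony
}

#' Apply persistent external forces to named cells
#'
#' Forces are added into every subsequent relaxation until cleared with
#' [clear_external_forces()].  Used by the chain experiment.
#'
#' @param colony a [colony].
#' @param forces a data frame with columns `id`, `fx`, `fy` (or a named
#'   list of 2-vectors keyed by cell id).
#' @return The updated colony.
#' @export
apply_external_force <- function(colony, forces) {
  if (is.list(forces) && !is.data.frame(forces)) {
    forces <- data.frame(id = as.integer(names(forces)),
                         fx = vapply(forces, `[`, numeric(1), 1),
                         fy = vapply(forces, `[`, numeric(1), 2))
  }
  if (nrow(forces) == 0L) return(colony)
  missing <- setdiff(forces$id, colony$cells$id)
  if (length(missing) > 0)
    stop("unknown cell id(s): ", paste(missing, collapse = ", "))
  keep <- !(colony$external$id %in% forces$id)
  colony$external <- rbind(colony$external[keep, , drop = FALSE], forces)
  rownames(colony$external) <- NULL
  colony
}

#' @rdname apply_external_force
#' @export
clear_external_forces <- function(colony) {
  colony$external <- colony$external[0, , drop = FALSE]
  colony
}

# Zero the accumulated displacement record (called when a snapshot is
# emitted, so the next snapshot carries displacement since this one).
reset_displacement_record <- function(colony) {
  colony$cells$acc_dx <- 0
  colony$cells$acc_dy <- 0
  colony$cells$acc_rot <- 0
  colony$cells$acc_stretch <- 1
  colony
}
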