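#' Dense optical-flow parameters
#'
#' Parameters of the pyramidal polynomial-expansion (Farneback-style) dense
#' flow estimator.
#'
#' @param levels number of pyramid levels (downscale factor 2 per level).
#' @param winsize side of the uniform integration window (odd, px).
#' @param iterations displacement refinement iterations per level.
#' @param poly_n side of the polynomial expansion neighbourhood (odd, px).
#' @param poly_sigma Gaussian applicability sigma for the expansion (px).
#' @return A list of class `flow_params`.
#' @export
flow_params <- function(levels = 5, winsize = 21, iterations = 3,
                        poly_n = 7, poly_sigma = 1.5) {
  stopifnot(levels >= 1, winsize >= 3, winsize %% 2 == 1,
            iterations >= 1, poly_n >= 3, poly_n %% 2 == 1, poly_sigma > 0)
  structure(list(levels = as.integer(levels), winsize = as.integer(winsize),
                 iterations = as.integer(iterations),
                 poly_n = as.integer(poly_n), poly_sigma = poly_sigma),
            class = "flow_params")
}

# Quadratic polynomial expansion f(x) ~ c + b'x + x'Ax over a Gaussian
# applicability, via separable correlations with the moment kernels and the
# precomputed inverse Gram matrix of the basis (1, x, y, x^2, y^2, xy).
poly_expansion <- function(f, poly_n, poly_sigma) {
  h <- (poly_n - 1L) %/% 2L
  xs <- -h:h
  a <- exp(-xs^2 / (2 * poly_sigma^2))
  k0 <- a; k1 <- a * xs; k2 <- a * xs^2
  s0 <- sum(a); s2 <- sum(a * xs^2); s4 <- sum(a * xs^4)
  G <- matrix(0, 6, 6)
  G[1, 1] <- s0 * s0
  G[1, 4] <- G[4, 1] <- G[1, 5] <- G[5, 1] <- s2 * s0
  G[2, 2] <- G[3, 3] <- s2 * s0
  G[4, 4] <- G[5, 5] <- s4 * s0
  G[4, 5] <- G[5, 4] <- s2 * s2
  G[6, 6] <- s2 * s2
  Gi <- solve(G)
  # moment images m_pq = sum a(u)a(v) u^p v^q f(y+v, x+u);
  # sep_filter2_cpp takes (ky, kx): v runs along rows, u along columns
  m00 <- sep_filter2_cpp(f, k0, k0)
  m10 <- sep_filter2_cpp(f, k0, k1)
  m01 <- sep_filter2_cpp(f, k1, k0)
  m20 <- sep_filter2_cpp(f, k0, k2)
  m02 <- sep_filter2_cpp(f, k2, k0)
  m11 <- sep_filter2_cpp(f, k1, k1)
  # coefficients r = Gi %*% (m00, m10, m01, m20, m02, m11)
  lincomb <- function(row) {
    Gi[row, 1] * m00 + Gi[row, 2] * m10 + Gi[row, 3] * m01 +
      Gi[row, 4] * m20 + Gi[row, 5] * m02 + Gi[row, 6] * m11
  }
  list(bx = lincomb(2), by = lincomb(3),
       axx = lincomb(4), ayy = lincomb(5), axy = lincomb(6) / 2)
}

pyr_down <- function(m) {
  k <- gaussian_kernel(1)
  s <- sep_filter2_cpp(m, k, k)
  s[seq(1, nrow(s), 2), seq(1, ncol(s), 2), drop = FALSE]
}

resize_bilinear <- function(m, nr, nc) {
  sy <- nrow(m) / nr
  sx <- ncol(m) / nc
  mapy <- matrix((seq_len(nr) - 0.5) * sy + 0.5, nr, nc)
  mapx <- matrix((seq_len(nc) - 0.5) * sx + 0.5, nr, nc, byrow = TRUE)
  warp_bilinear_cpp(m, mapy, mapx)
}

# One pyramid level of displacement refinement.
flow_refine <- function(e1, e2, u, v, winsize, iterations) {
  nr <- nrow(u); nc <- ncol(u)
  Y <- matrix(seq_len(nr), nr, nc)
  X <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (it in seq_len(iterations)) {
    mapy <- Y + v
    mapx <- X + u
    a11 <- 0.5 * (e1$axx + warp_bilinear_cpp(e2$axx, mapy, mapx))
    a22 <- 0.5 * (e1$ayy + warp_bilinear_cpp(e2$ayy, mapy, mapx))
    a12 <- 0.5 * (e1$axy + warp_bilinear_cpp(e2$axy, mapy, mapx))
    dbx <- 0.5 * (e1$bx - warp_bilinear_cpp(e2$bx, mapy, mapx)) +
      a11 * u + a12 * v
    dby <- 0.5 * (e1$by - warp_bilinear_cpp(e2$by, mapy, mapx)) +
      a12 * u + a22 * v
    g11 <- box_filter_cpp(a11 * a11 + a12 * a12, winsize)
    g12 <- box_filter_cpp(a12 * (a11 + a22), winsize)
    g22 <- box_filter_cpp(a22 * a22 + a12 * a12, winsize)
    h1 <- box_filter_cpp(a11 * dbx + a12 * dby, winsize)
    h2 <- box_filter_cpp(a12 * dbx + a22 * dby, winsize)
    lam <- 1e-3 * mean(g11 + g22)
    g11 <- g11 + lam
    g22 <- g22 + lam
    det <- g11 * g22 - g12^2
    u <- (g22 * h1 - g12 * h2) / det
    v <- (g11 * h2 - g12 * h1) / det
  }
  list(u = u, v = v)
}

#' Binary colony footprint from a fluorescence frame
#'
#' Gaussian smoothing, Otsu threshold, hole filling.
#'
#' @param frame intensity matrix.
#' @param smooth_sigma smoothing sigma (px).
#' @return Logical matrix.
#' @export
frame_mask <- function(frame, smooth_sigma = 2) {
  f <- (frame - min(frame)) / max(1e-12, max(frame) - min(frame))
  if (smooth_sigma > 0) {
    k <- gaussian_kernel(smooth_sigma)
    f <- sep_filter2_cpp(f, k, k)
  }
  thr <- EBImage::otsu(EBImage::Image(f), range = c(0, 1))
  m <- EBImage::fillHull(EBImage::Image((f > thr) * 1))
  EBImage::imageData(m) > 0
}

#' Estimate dense optical flow between two frames
#'
#' Pyramidal polynomial-expansion dense flow: each image is locally
#' approximated by a quadratic polynomial over a Gaussian applicability;
#' equating the expansions of the two frames yields, per pixel, a linear
#' constraint on the displacement which is integrated over a window and
#' solved, with coarse-to-fine pyramid refinement to capture large motions.
#'
#' @param frame_a,frame_b intensity matrices of identical shape and scale.
#' @param params a [flow_params] object.
#' @param pixel_size um/px carried into the result.
#' @param frame_interval minutes between the frames.
#' @return An object of class `velocity_field`: matrices `u`, `v`
#'   (displacement in px/frame, x- and y-components), logical `mask`
#'   (colony footprint of `frame_a`), `pixel_size`, `frame_interval`.
#' @export
estimate_flow <- function(frame_a, frame_b, params = flow_params(),
                          pixel_size = 1, frame_interval = 1) {
  if (!identical(dim(frame_a), dim(frame_b)))
    stop("frame shapes differ")
  pyr_a <- list(frame_a)
  pyr_b <- list(frame_b)
  lv <- params$levels
  while (length(pyr_a) < lv &&
         min(dim(pyr_a[[length(pyr_a)]])) >= 2 * (params$poly_n + 1)) {
    pyr_a[[length(pyr_a) + 1L]] <- pyr_down(pyr_a[[length(pyr_a)]])
    pyr_b[[length(pyr_b) + 1L]] <- pyr_down(pyr_b[[length(pyr_b)]])
  }
  lv <- length(pyr_a)
  u <- v <- matrix(0, nrow(pyr_a[[lv]]), ncol(pyr_a[[lv]]))
  for (l in rev(seq_len(lv))) {
    e1 <- poly_expansion(pyr_a[[l]], params$poly_n, params$poly_sigma)
    e2 <- poly_expansion(pyr_b[[l]], params$poly_n, params$poly_sigma)
    res <- flow_refine(e1, e2, u, v, params$winsize, params$iterations)
    if (l > 1) {
      nr <- nrow(pyr_a[[l - 1]])
      nc <- ncol(pyr_a[[l - 1]])
      u <- resize_bilinear(res$u, nr, nc) * 2
      v <- resize_bilinear(res$v, nr, nc) * 2
    } else {
      u <- res$u
      v <- res$v
    }
  }
  structure(list(u = u, v = v, mask = frame_mask(frame_a),
                 pixel_size = pixel_size, frame_interval = frame_interval),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  sp <- sqrt(x$u[x$mask]^2 + x$v[x$mask]^2)
  cat(sprintf("<velocity_field> %d x %d px, mean speed in mask %.3f px/frame\n",
              nrow(x$u), ncol(x$u), mean(sp)))
  invisible(x)
}

#' Per-pixel relative flow error
#'
#' `100 * mean(|v_est - v_true|) / (mean(|v_true|) + eps)` over mask
#' pixels: the mean endpoint error normalized by the mean true speed,
#' expressed in percent.
#'
#' @param estimated,truth velocity fields (objects with `u`, `v`) on the
#'   same grid.
#' @param mask logical matrix of pixels entering the average.
#' @param eps guard against a zero-motion ground truth (px).
#' @return Error in percent.
#' @export
flow_error <- function(estimated, truth, mask, eps = 1e-6) {
  if (!any(mask)) stop("empty mask")
  ok <- mask & is.finite(truth$u) & is.finite(truth$v)
  epe <- sqrt((estimated$u[ok] - truth$u[ok])^2 +
              (estimated$v[ok] - truth$v[ok])^2)
  ref <- mean(sqrt(truth$u[ok]^2 + truth$v[ok]^2))
  100 * mean(epe) / (ref + eps)
}

#' Calibrate flow parameters against rendered ground truth
#'
#' Evaluates each candidate parameter set by its mean [flow_error()] over
#' frame pairs of a rendered simulation movie with known per-pixel
#' velocities, and returns the ranked report.  Mirrors the validation of
#' the estimator against simulations before applying it to micrographs.
#'
#' @param timelapse a [render_timelapse()] result (frames + truth), or a
#'   list with `frames`, `truth`.
#' @param param_grid list of [flow_params()] objects.
#' @param pairs indices of frame pairs to evaluate (pair `i` is frames
#'   `i, i+1`); default: up to 8 pairs evenly spread over the movie.
#' @return An object of class `flow_calibration`: `report` (data frame of
#'   parameters and errors, ranked), `best_params`, `best_error`.
#' @export
calibrate_flow <- function(timelapse, param_grid = default_flow_grid(),
                           pairs = NULL) {
  if (length(param_grid) == 0) stop("empty parameter grid")
  n_pairs <- length(timelapse$truth)
  if (n_pairs < 1) stop("need at least two frames")
  if (is.null(pairs))
    pairs <- unique(round(seq(max(1, n_pairs %/% 3), n_pairs,
                              length.out = min(8, n_pairs))))
  errs <- matrix(NA_real_, length(param_grid), length(pairs))
  for (gi in seq_along(param_grid)) {
    for (pi in seq_along(pairs)) {
      fp <- pairs[pi]
      est <- estimate_flow(timelapse$frames[[fp]], timelapse$frames[[fp + 1]],
                           param_grid[[gi]])
      tr <- timelapse$truth[[fp]]
      errs[gi, pi] <- flow_error(est, tr, tr$mask)
    }
  }
  mean_err <- rowMeans(errs)
  rep <- data.frame(
    set = seq_along(param_grid),
    levels = vapply(param_grid, `[[`, integer(1), "levels"),
    winsize = vapply(param_grid, `[[`, integer(1), "winsize"),
    iterations = vapply(param_grid, `[[`, integer(1), "iterations"),
    poly_n = vapply(param_grid, `[[`, integer(1), "poly_n"),
    poly_sigma = vapply(param_grid, `[[`, numeric(1), "poly_sigma"),
    error = mean_err)
  rep <- rep[order(rep$error), ]
  rownames(rep) <- NULL
  structure(list(report = rep,
                 best_params = param_grid[[rep$set[1]]],
                 best_error = rep$error[1],
                 pairs = pairs),
            class = "flow_calibration")
}

#' @export
print.flow_calibration <- function(x, ...) {
  cat(sprintf("<flow_calibration> best error %.3f%% per pixel over %d frame pairs\n",
              x$best_error, length(x$pairs)))
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Default flow calibration grid
#'
#' A small grid around the expected operating point, including a
#' deliberately degenerate small-window set as a sanity floor.
#'
#' @return List of [flow_params()] objects.
#' @export
default_flow_grid <- function() {
  list(flow_params(levels = 5, winsize = 21, iterations = 3),
       flow_params(levels = 5, winsize = 31, iterations = 3),
       flow_params(levels = 6, winsize = 21, iterations = 3),
       flow_params(levels = 6, winsize = 31, iterations = 4),
       flow_params(levels = 4, winsize = 15, iterations = 3),
       flow_params(levels = 3, winsize = 5, iterations = 1, poly_n = 5,
                   poly_sigma = 1.1))
}

#' Vorticity of a velocity field
#'
#' The curl `dv/dx - du/dy` by central differences, falling back to
#' one-sided differences at mask borders; pixels without enough masked
#' neighbours in either direction are `NA` and excluded from downstream
#' statistics.  Units: frame^-1 (divide by `frame_interval` for min^-1).
#'
#' @param field a `velocity_field` (or list with `u`, `v`, optional
#'   `mask`).
#' @return Matrix of vorticity values (`NA` outside the mask).
#' @export
vorticity <- function(field) {
  u <- field$u; v <- field$v
  mask <- if (is.null(field$mask)) matrix(TRUE, nrow(u), ncol(u)) else field$mask
  masked_deriv_x <- function(f) masked_deriv(f, mask, along = 2L)
  masked_deriv_y <- function(f) masked_deriv(f, mask, along = 1L)
  w <- masked_deriv_x(v) - masked_deriv_y(u)
  w[!mask] <- NA_real_
  w
}

# derivative along rows (along=1, d/dy) or columns (along=2, d/dx) with
# central differences inside the mask and one-sided at its borders
masked_deriv <- function(f, mask, along) {
  if (along == 1L) {
    f <- t(f); mask <- t(mask)
  }
  nr <- nrow(f); nc <- ncol(f)
  fm <- cbind(NA_real_, f[, -nc, drop = FALSE])     # f(x-1)
  fp <- cbind(f[, -1, drop = FALSE], NA_real_)      # f(x+1)
  mm <- cbind(FALSE, mask[, -nc, drop = FALSE])
  mp <- cbind(mask[, -1, drop = FALSE], FALSE)
  d <- matrix(NA_real_, nr, nc)
  ctr <- mask & mm & mp
  d[ctr] <- (fp[ctr] - fm[ctr]) / 2
  fwd <- mask & !mm & mp
  d[fwd] <- fp[fwd] - f[fwd]
  bwd <- mask & mm & !mp
  d[bwd] <- f[bwd] - fm[bwd]
  if (along == 1L) d <- t(d)
  d
}

#' Root-mean-square vorticity over the colony
#'
#' `sqrt(mean(omega^2))` over mask pixels with a defined vorticity;
#' sign-blind, so clockwise and counter-clockwise rotation do not cancel.
#'
#' @param w vorticity matrix (from [vorticity()]).
#' @param mask logical matrix.
#' @return Scalar RMS vorticity.
#' @export
rms_vorticity <- function(w, mask) {
  if (!any(mask)) stop("empty mask")
  vals <- w[mask]
  vals <- vals[is.finite(vals)]
  sqrt(mean(vals^2))
}

#' Mean speed of a velocity field
#'
#' @param field a `velocity_field`.
#' @param mask logical matrix; defaults to the field's own mask.
#' @return Mean of `sqrt(u^2 + v^2)` over the mask (px/frame).
#' @export
mean_speed <- function(field, mask = field$mask) {
  if (!any(mask)) stop("empty mask")
  mean(sqrt(field$u[mask]^2 + field$v[mask]^2))
}

#' Align series of (colony area, value) onto a common area grid
#'
#' Linearly interpolates each colony's readout onto a log-spaced grid of
#' colony areas spanning the largest common minimum to the smallest common
#' maximum, so colonies imaged at different times are compared at
#' equivalent colony area.
#'
#' @param series a list of data frames with columns `area` and `value`.
#' @param n_grid number of grid points.
#' @return Data frame: `area` plus one interpolated column per series.
#' @export
align_by_area <- function(series, n_grid = 20) {
  if (length(series) == 0) stop("empty series")
  lo <- max(vapply(series, function(s) min(s$area), numeric(1)))
  hi <- min(vapply(series, function(s) max(s$area), numeric(1)))
  if (!(hi > lo)) stop("series do not share an area range")
  grid <- pmin(pmax(exp(seq(log(lo), log(hi), length.out = n_grid)), lo), hi)
  out <- data.frame(area = grid)
  for (i in seq_along(series)) {
    s <- series[[i]]
    out[[paste0("value", i)]] <- approx(s$area, s$value, xout = grid,
                                        ties = mean)$y
  }
  names(out)[-1] <- if (!is.null(names(series)) && all(nzchar(names(series))))
    names(series) else paste0("value", seq_along(series))
  out
}

#' Advect a label image through a velocity-field sequence
#'
#' Successively applies each frame's velocity field to an initial integer
#' label raster (falsely coloured founder cells) by inverse mapping with
#' nearest-neighbour sampling, which keeps labels discrete; the warped
#' sequence reveals the lineage domains implied by the motion alone.
#'
#' @param label_image integer matrix (0 = background).
#' @param field_sequence list of velocity fields (`u`, `v` in px/frame)
#'   matching the label shape.
#' @return List of label matrices, one per field application (the initial
#'   image first, length `length(field_sequence) + 1`).
#' @export
advect_labels <- function(label_image, field_sequence) {
  stopifnot(is.matrix(label_image))
  nr <- nrow(label_image); nc <- ncol(label_image)
  Y <- matrix(seq_len(nr), nr, nc)
  X <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  lab <- matrix(as.integer(label_image), nr, nc)
  out <- vector("list", length(field_sequence) + 1L)
  out[[1L]] <- lab
  for (i in seq_along(field_sequence)) {
    f <- field_sequence[[i]]
    u <- f$u; v <- f$v
    u[!is.finite(u)] <- 0
    v[!is.finite(v)] <- 0
    lab <- warp_nearest_int_cpp(lab, Y - v, X - u)
    out[[i + 1L]] <- lab
  }
  out
}

#' Line integral convolution rendering of a velocity field
#'
#' Convolves a white-noise texture along the field's streamlines,
#' producing streaks aligned with the local flow direction.
#'
#' @param field a `velocity_field` (or list with `u`, `v`).
#' @param seed noise seed (deterministic output given the seed).
#' @param kernel_length streamline integration half-length (px).
#' @return Matrix in `[0, 1]`.
#' @export
lic_render <- function(field, seed = 1, kernel_length = 15) {
  u <- field$u; v <- field$v
  u[!is.finite(u)] <- 0
  v[!is.finite(v)] <- 0
  set.seed(derive_seed(seed, "lic"))
  noise <- matrix(runif(length(u)), nrow(u), ncol(u))
  out <- lic_cpp(u, v, noise, as.integer(kernel_length))
  (out - min(out)) / max(1e-12, max(out) - min(out))
}
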