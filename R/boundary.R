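#' Segment two-channel colony images into domain masks
#'
#' Each channel is Gaussian-smoothed and thresholded with Otsu's method,
#' the standard parameter-free choice.  Intensities are rescaled to
#' `[0, 1]` per channel before thresholding.
#'
#' @param image a list with matrices `channel_g` and `channel_r` of equal
#'   shape (and optionally `pixel_size`, um/px).
#' @param smooth_sigma Gaussian smoothing sigma in pixels (>= 0).
#' @return A list `(mask_g, mask_r)` of logical matrices.
#' @export
segment_domains <- function(image, smooth_sigma = 2) {
  stopifnot(smooth_sigma >= 0)
  chans <- list(g = image$channel_g, r = image$channel_r)
  if (is.null(chans$g) || is.null(chans$r))
    stop("image must have channel_g and channel_r")
  if (!identical(dim(chans$g), dim(chans$r)))
    stop("channel shapes differ")
  masks <- lapply(names(chans), function(nm) {
    ch <- chans[[nm]]
    if (max(ch) <= min(ch))
      stop(sprintf("channel_%s is blank (no foreground)", nm))
    ch <- (ch - min(ch)) / (max(ch) - min(ch))
    if (smooth_sigma > 0) {
      k <- gaussian_kernel(smooth_sigma)
      ch <- sep_filter2_cpp(ch, k, k)
    }
    thr <- EBImage::otsu(EBImage::Image(ch), range = c(0, 1))
    ch > thr
  })
  names(masks) <- c("mask_g", "mask_r")
  masks
}

# border pixels of a mask (foreground pixels 4-adjacent to background)
mask_edge <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- rbind(FALSE, m[-nr, , drop = FALSE])
  dn <- rbind(m[-1, , drop = FALSE], FALSE)
  lf <- cbind(FALSE, m[, -nc, drop = FALSE])
  rt <- cbind(m[, -1, drop = FALSE], FALSE)
  m & !(up & dn & lf & rt)
}

dilate_disc <- function(m, radius) {
  if (radius <= 0) return(m)
  br <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  EBImage::imageData(EBImage::dilate(EBImage::Image(m * 1), br)) > 0
}

#' Extract the interdomain boundary skeleton
#'
#' Edge pixels of each domain mask are found; the outline of the colony --
#' the edge of the hole-filled union mask, dilated by `rim_dilate` pixels
#' to avoid 1-px leakage -- is subtracted, leaving the edges where the two
#' domains meet; the result is thinned to a single-pixel-wide 8-connected
#' skeleton.  Because rasterized colonies can be slightly porous (unlike
#' saturated micrographs), an edge pixel only qualifies when the opposite
#' domain lies within `meet_dist` pixels, so gaps interior to one domain do
#' not masquerade as interdomain boundary.
#'
#' @param mask_g,mask_r logical matrices of equal shape.
#' @param rim_dilate dilation radius (px) applied to the colony outline
#'   before subtraction.
#' @param meet_dist maximum distance (px) to the opposite domain for an
#'   edge pixel to count as interface.
#' @return Logical matrix, the skeleton (empty with a warning when the
#'   domains are not adjacent).
#' @export
extract_boundary <- function(mask_g, mask_r, rim_dilate = 3, meet_dist = 3) {
  stopifnot(identical(dim(mask_g), dim(mask_r)))
  e_g <- mask_edge(mask_g)
  e_r <- mask_edge(mask_r)
  union_filled <- EBImage::imageData(
    EBImage::fillHull(EBImage::Image((mask_g | mask_r) * 1))) > 0
  outline <- mask_edge(union_filled)
  near_r <- dilate_disc(mask_r, meet_dist)
  near_g <- dilate_disc(mask_g, meet_dist)
  cand <- ((e_g & near_r) | (e_r & near_g)) & !dilate_disc(outline, rim_dilate)
  if (!any(cand)) {
    warning("domains are not adjacent; empty boundary")
    return(cand)
  }
  thin_cpp(cand)
}

#' Boundary length in pixels
#'
#' The length of a single-pixel-wide skeleton is its pixel count -- the
#' convention kept throughout this pipeline (a 45-degree diagonal of 100
#' pixels has length 100, not 141; the normalization by colony radius and
#' all comparisons use the same convention).
#'
#' @param skeleton logical matrix.
#' @return Integer pixel count (0 for an empty skeleton).
#' @export
boundary_length <- function(skeleton) {
  sum(skeleton > 0)
}

#' Normalized boundary length
#'
#' Boundary skeleton length divided by colony radius (both in pixels),
#' a dimensionless, scale-invariant measure of interdomain mixing.
#'
#' @param length_px skeleton pixel count.
#' @param colony_radius_px equivalent-circle colony radius in pixels (> 0).
#' @return Scalar ratio.
#' @export
normalized_boundary_length <- function(length_px, colony_radius_px) {
  stopifnot(colony_radius_px > 0)
  length_px / colony_radius_px
}

#' Fractal dimension by Euclidean distance mapping
#'
#' Computes the Euclidean distance transform from the skeleton and, for a
#' log-spaced grid of scales `r`, the area `A(r)` of pixels within
#' distance `r`; the effective length `L(r) = A(r) / (2 r)` scales as
#' `r^(1 - D)` for a fractal curve, so `D = 1 - slope` of the least-squares
#' fit of `log L(r)` against `log r`.  The result is clamped to `[1, 2]`
#' with a warning if the fit falls outside.
#'
#' @param skeleton non-empty logical matrix.
#' @param scale_min,scale_max smallest and largest scale in pixels;
#'   `scale_max = NULL` defaults to a quarter of the skeleton's bounding
#'   half-span (at least `4 * scale_min`).
#' @param n_scales number of scales (>= 3).
#' @return Scalar fractal dimension estimate in `[1, 2]`.
#' @export
fractal_dimension_edm <- function(skeleton, scale_min = 2, scale_max = NULL,
                                  n_scales = 8) {
  if (!any(skeleton > 0)) stop("empty skeleton")
  if (n_scales < 3) stop("need at least 3 scales")
  if (is.null(scale_max)) {
    ij <- which(skeleton > 0, arr.ind = TRUE)
    span <- max(diff(range(ij[, 1])), diff(range(ij[, 2])))
    # stay inside the raster: the distance field is clipped at the borders
    scale_max <- min(max(span / 4, 4 * scale_min), min(dim(skeleton)) / 4)
  }
  stopifnot(scale_min >= 1, scale_max > scale_min)
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image((!skeleton) * 1)))
  # integer scales and band width 2r + 1: a digital straight line then gives
  # L(r) exactly constant (the band contains 2r + 1 pixel rows)
  rs <- unique(round(exp(seq(log(scale_min), log(scale_max),
                             length.out = n_scales))))
  if (length(rs) < 3) stop("need at least 3 distinct scales")
  Lr <- vapply(rs, function(r) sum(d <= r) / (2 * r + 1), numeric(1))
  fit <- lm(log(Lr) ~ log(rs))
  D <- 1 - unname(coef(fit)[2])
  if (D < 1 || D > 2) {
    warning(sprintf("fractal dimension estimate %.3f outside [1, 2]; clamped", D))
    D <- min(max(D, 1), 2)
  }
  D
}

#' Full interdomain boundary analysis of a two-channel image
#'
#' Runs segmentation, boundary extraction, length measurement,
#' normalization by colony radius, and fractal dimension estimation.
#'
#' @param image list with `channel_g`, `channel_r` matrices and optional
#'   `pixel_size` (um/px, default 1).
#' @param smooth_sigma segmentation smoothing sigma (px).
#' @param rim_dilate outline-removal dilation radius (px).
#' @param n_scales scales for the fractal fit.
#' @return An object of class `boundary_result`: skeleton, `length_px`,
#'   `length_um`, `colony_radius_px`, `normalized_length`,
#'   `fractal_dimension`.
#' @export
analyze_boundary <- function(image, smooth_sigma = 2, rim_dilate = 3,
                             n_scales = 8) {
  px <- if (is.null(image$pixel_size)) 1 else image$pixel_size
  masks <- segment_domains(image, smooth_sigma)
  skel <- extract_boundary(masks$mask_g, masks$mask_r, rim_dilate)
  len <- boundary_length(skel)
  radius <- colony_radius(masks$mask_g | masks$mask_r)
  fd <- if (len > 0) {
    suppressWarnings(
      fractal_dimension_edm(skel, scale_max = max(radius / 4, 8.01),
                            n_scales = n_scales))
  } else NA_real_
  structure(list(skeleton = skel, length_px = len, length_um = len * px,
                 colony_radius_px = radius,
                 normalized_length = normalized_boundary_length(len, radius),
                 fractal_dimension = fd,
                 masks = masks, pixel_size = px),
            class = "boundary_result")
}

#' @export
print.boundary_result <- function(x, ...) {
  cat(sprintf(paste0("<boundary_result> length %d px (%.1f um), colony radius",
                     " %.1f px\n  normalized length %.3f, fractal dimension %.3f\n"),
              x$length_px, x$length_um, x$colony_radius_px,
              x$normalized_length, x$fractal_dimension))
  invisible(x)
}

#' Rasterize a two-domain colony snapshot into a two-channel image
#'
#' Renders green- and red-labelled cells into separate channels (with PSF
#' blur and optional noise), the simulation-side source for the boundary
#' pipeline.
#'
#' @param colony a [colony] (or snapshot cell table in `$cells`).
#' @param pixel_size um per pixel.
#' @param psf_sigma Gaussian blur sigma (px).
#' @param noise_sd additive Gaussian noise SD (fraction of max intensity).
#' @param seed noise RNG seed.
#' @param pad margin (um).
#' @return List `(channel_g, channel_r, pixel_size)`.
#' @export
render_two_channel <- function(colony, pixel_size = 0.1, psf_sigma = 2,
                               noise_sd = 0, seed = 1, pad = 3) {
  cl <- if (inherits(colony, "colony")) colony$cells else colony$cells
  ext <- max(cl$length / 2 + cl$radius) + pad
  x0 <- min(cl$x) - ext; x1 <- max(cl$x) + ext
  y0 <- min(cl$y) - ext; y1 <- max(cl$y) + ext
  nc <- as.integer(ceiling((x1 - x0) / pixel_size))
  nr <- as.integer(ceiling((y1 - y0) / pixel_size))
  set.seed(derive_seed(seed, "render2ch"))
  k <- if (psf_sigma > 0) gaussian_kernel(psf_sigma) else NULL
  chan <- function(sel) {
    cc <- cl[sel, , drop = FALSE]
    img <- rasterize_cells_cpp(cc$x, cc$y, cc$dx, cc$dy, cc$length, cc$radius,
                               cc$brightness, x0, y0, pixel_size, nr, nc)$intensity
    if (!is.null(k)) img <- sep_filter2_cpp(img, k, k)
    if (noise_sd > 0) img <- pmax(img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc), 0)
    img
  }
  list(channel_g = chan(cl$domain_label == "green"),
       channel_r = chan(cl$domain_label != "green"),
       pixel_size = pixel_size)
}
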