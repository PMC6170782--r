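# Shared fixture builders (all fixtures are generated in code).

# a colony from explicit cell poses (non-growing unless stated)
make_colony <- function(x, y, dx = 1, dy = 0, length = 2, radius = 0.5,
                        adhesin = 0, label = "green", growing = FALSE,
                        growth_rate = 0, division_length = Inf,
                        params = physics_params()) {
  n <- length(x)
  cells <- colonymix:::new_cells(seq_len(n), x, y,
                                 rep_len(dx, n), rep_len(dy, n),
                                 rep_len(length, n), rep_len(radius, n),
                                 rep_len(growth_rate, n),
                                 rep_len(division_length, n),
                                 rep_len(label, n), rep_len(adhesin, n),
                                 rep_len(growing, n))
  new_colony(cells, params)
}

# brute-force all-pairs contact oracle (mirrors the contact definition)
contacts_oracle <- function(colony, margin = colony$params$contact_margin) {
  cl <- colony$cells
  out <- list()
  n <- nrow(cl)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cp <- segment_closest_points(c(cl$x[i], cl$y[i]), c(cl$dx[i], cl$dy[i]),
                                   cl$length[i],
                                   c(cl$x[j], cl$y[j]), c(cl$dx[j], cl$dy[j]),
                                   cl$length[j])
      if (cp$distance < cl$radius[i] + cl$radius[j] + margin)
        out[[length(out) + 1]] <- data.frame(cell_a = cl$id[i],
                                             cell_b = cl$id[j],
                                             distance = cp$distance)
    }
  }
  if (length(out) == 0) return(data.frame(cell_a = integer(),
                                          cell_b = integer(),
                                          distance = numeric()))
  do.call(rbind, out)
}

# half-disk two-domain image (green left, red right)
half_disk_image <- function(R = 250, pad = 20, noise_sd = 0,
                            pixel_size = 0.1, seed = 4) {
  n <- 2 * (R + pad)
  Y <- matrix(seq_len(n), n, n)
  X <- matrix(seq_len(n), n, n, byrow = TRUE)
  cx <- n / 2 + 0.5
  disk <- (X - cx)^2 + (Y - cx)^2 <= R^2
  g <- 1.0 * (disk & X <= cx)
  r <- 1.0 * (disk & X > cx)
  if (noise_sd > 0) {
    set.seed(seed)
    g <- g + matrix(rnorm(n * n, 0, noise_sd), n, n)
    r <- r + matrix(rnorm(n * n, 0, noise_sd), n, n)
  }
  list(channel_g = g, channel_r = r, pixel_size = pixel_size,
       mask_g_true = disk & X <= cx, mask_r_true = disk & X > cx, R = R)
}

# concentric two-domain image (green core, red annulus)
ring_image <- function(R_in = 100, R_out = 200, pad = 20) {
  n <- 2 * (R_out + pad)
  Y <- matrix(seq_len(n), n, n)
  X <- matrix(seq_len(n), n, n, byrow = TRUE)
  cx <- n / 2 + 0.5
  d <- sqrt((X - cx)^2 + (Y - cx)^2)
  list(channel_g = 1.0 * (d <= R_in),
       channel_r = 1.0 * (d > R_in & d <= R_out),
       pixel_size = 0.1, R_in = R_in)
}

# Koch snowflake edge (quadratic segment subdivision), rasterized and thinned
koch_skeleton <- function(iter = 4, span = 2187, pad = 200) {
  pts <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE)
  for (it in seq_len(iter)) {
    newp <- list()
    for (i in seq_len(nrow(pts) - 1)) {
      a <- pts[i, ]; b <- pts[i + 1, ]
      d <- (b - a) / 3
      p1 <- a + d
      p3 <- a + 2 * d
      p2 <- p1 + c(d[1] * cos(-pi / 3) - d[2] * sin(-pi / 3),
                   d[1] * sin(-pi / 3) + d[2] * cos(-pi / 3))
      newp[[length(newp) + 1]] <- rbind(a, p1, p2, p3)
    }
    pts <- rbind(do.call(rbind, newp), pts[nrow(pts), ])
  }
  pts <- pts * span
  nx <- span + 2 * pad
  ny <- round(span * 0.30) + 2 * pad
  img <- matrix(FALSE, ny, nx)
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    L <- sqrt(sum((b - a)^2))
    t <- seq(0, 1, length.out = max(2, ceiling(L * 2)))
    xs <- round(a[1] + t * (b[1] - a[1])) + pad
    ys <- round(a[2] + t * (b[2] - a[2])) + pad + round(span * 0.30)
    img[cbind(ys, xs)] <- TRUE
  }
  colonymix:::thin_cpp(img)
}

# textured blob image pair under a known warp (for flow tests);
# frame_b(x) = frame_a(x - d(x))
blob_frame <- function(n = 128, n_blobs = 40, seed = 11) {
  Y <- matrix(seq_len(n), n, n)
  X <- matrix(seq_len(n), n, n, byrow = TRUE)
  img <- matrix(0, n, n)
  set.seed(seed)
  for (i in seq_len(n_blobs)) {
    cx <- runif(1, 0.15 * n, 0.85 * n)
    cy <- runif(1, 0.15 * n, 0.85 * n)
    img <- img + exp(-((X - cx)^2 + (Y - cy)^2) / 40)
  }
  img
}

warp_frame <- function(frame, u, v) {
  n <- nrow(frame)
  Y <- matrix(seq_len(n), n, ncol(frame))
  X <- matrix(seq_len(ncol(frame)), n, ncol(frame), byrow = TRUE)
  colonymix:::warp_bilinear_cpp(frame, Y - v, X - u)
}

# tiny rendered movie reused across flow/scenario tests (cached per session)
tiny_movie <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      res <- run_two_domain(0, n_target = 220, seed = 1, snapshot_every = 1)
      cache <<- render_timelapse(res, pixel_size = 0.1, frame_interval = 10,
                                 seed = 1, frames_every = 4)
    }
    cache
  }
})
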