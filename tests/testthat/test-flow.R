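test_that("flow estimation recovers pure translation and the identity", {
  fa <- blob_frame()
  n <- nrow(fa)
  fb <- warp_frame(fa, matrix(3, n, n), matrix(0, n, n))
  fl <- estimate_flow(fa, fb, flow_params(levels = 3, winsize = 15))
  expect_equal(median(fl$u[fl$mask]), 3, tolerance = 0.2)
  expect_equal(median(fl$v[fl$mask]), 0, tolerance = 0.2)

  fl0 <- estimate_flow(fa, fa, flow_params(levels = 3, winsize = 15))
  expect_lte(median(sqrt(fl0$u[fl0$mask]^2 + fl0$v[fl0$mask]^2)), 0.05)

  expect_error(estimate_flow(fa, fa[1:64, ]), "shapes")
})

test_that("flow error metric behaves as specified", {
  n <- 64
  truth <- list(u = matrix(2, n, n), v = matrix(1, n, n))
  mask <- matrix(TRUE, n, n)
  expect_equal(flow_error(truth, truth, mask), 0)
  scaled <- list(u = truth$u * 1.02, v = truth$v * 1.02)
  expect_equal(flow_error(scaled, truth, mask), 2, tolerance = 1e-6)
  zero <- list(u = truth$u * 0, v = truth$v * 0)
  expect_equal(flow_error(zero, truth, mask), 100, tolerance = 1e-4)
  expect_error(flow_error(truth, truth, mask & FALSE), "empty")
})

test_that("vorticity matches closed forms on analytic fields", {
  n <- 120
  Y <- matrix(seq_len(n), n, n)
  X <- matrix(seq_len(n), n, n, byrow = TRUE)
  mask <- matrix(TRUE, n, n)
  interior <- cbind(FALSE, rbind(FALSE, matrix(TRUE, n - 2, n - 2), FALSE), FALSE)

  om <- 0.05
  w <- vorticity(list(u = -om * (Y - n / 2), v = om * (X - n / 2), mask = mask))
  expect_lt(max(abs(w[interior] - 2 * om)), 1e-6)

  w <- vorticity(list(u = 0.1 * (X - n / 2), v = 0.1 * (Y - n / 2), mask = mask))
  expect_lt(max(abs(w[interior])), 1e-6)

  gam <- 0.2
  w <- vorticity(list(u = gam * Y, v = 0 * X, mask = mask))
  expect_lt(max(abs(w[interior] + gam)), 1e-6)
})

test_that("RMS vorticity is sign-blind and matches constants", {
  n <- 60
  mask <- matrix(TRUE, n, n)
  expect_equal(rms_vorticity(matrix(0.4, n, n), mask), 0.4)
  halves <- matrix(rep(c(0.3, -0.3), each = n * n / 2), n, n)
  expect_equal(rms_vorticity(halves, mask), 0.3)
  # rigid rotation Omega gives RMS 2 * Omega
  Y <- matrix(seq_len(n), n, n); X <- matrix(seq_len(n), n, n, byrow = TRUE)
  w <- vorticity(list(u = -0.05 * (Y - n / 2), v = 0.05 * (X - n / 2), mask = mask))
  expect_equal(rms_vorticity(w, mask), 0.1, tolerance = 1e-3)
  expect_error(rms_vorticity(matrix(1, 2, 2), matrix(FALSE, 2, 2)), "empty")
})

test_that("mean speed averages the velocity magnitude over the mask", {
  n <- 40
  f <- list(u = matrix(3, n, n), v = matrix(4, n, n), mask = matrix(TRUE, n, n))
  expect_equal(mean_speed(f), 5)
  f$u <- f$u * 0; f$v <- f$v * 0
  expect_equal(mean_speed(f), 0)
})

test_that("align_by_area interpolates series onto a common area grid", {
  s1 <- data.frame(area = c(10, 20, 40, 80), value = log(c(10, 20, 40, 80)))
  out1 <- align_by_area(list(s1), n_grid = 10)
  expect_equal(out1[[2]], approx(s1$area, s1$value, out1$area)$y)

  # two samplings of one underlying curve agree after alignment
  f <- function(a) sqrt(a)
  s2 <- data.frame(area = seq(12, 70, by = 4), value = f(seq(12, 70, by = 4)))
  s3 <- data.frame(area = seq(10, 75, by = 7), value = f(seq(10, 75, by = 7)))
  out <- align_by_area(list(a = s2, b = s3), n_grid = 12)
  expect_equal(out$a, out$b, tolerance = 0.05)

  expect_error(align_by_area(list()), "empty")
})

test_that("label advection preserves labels under zero, uniform and rotational fields", {
  n <- 100
  lab <- matrix(0L, n, n)
  lab[31:70, 31:50] <- 1L
  lab[31:70, 51:70] <- 2L
  zero <- list(u = matrix(0, n, n), v = matrix(0, n, n))
  out <- advect_labels(lab, list(zero, zero))
  expect_identical(out[[3]], lab)

  shift <- list(u = matrix(4, n, n), v = matrix(0, n, n))
  out <- advect_labels(lab, list(shift))
  expect_identical(out[[2]][, 5:n], lab[, 1:(n - 4)])

  # quarter rotation in 15-degree frames keeps the straight interface;
  # each frame's displacement is the rigid-rotation field written at the
  # arrival point, d(x) = (I - R^-1)(x - c), which is what inverse mapping
  # consumes exactly
  Y <- matrix(seq_len(n), n, n); X <- matrix(seq_len(n), n, n, byrow = TRUE)
  th <- 15 * pi / 180
  rotf <- list(u = (1 - cos(th)) * (X - 50.5) - sin(th) * (Y - 50.5),
               v = sin(th) * (X - 50.5) + (1 - cos(th)) * (Y - 50.5))
  lab2 <- matrix(0L, n, n)
  d <- sqrt((X - 50.5)^2 + (Y - 50.5)^2)
  lab2[d <= 30 & X <= 50.5] <- 1L
  lab2[d <= 30 & X > 50.5] <- 2L
  nstep <- 6
  out <- advect_labels(lab2, rep(list(rotf), nstep))
  final <- out[[nstep + 1]]
  # after 90 degrees the vertical interface becomes a horizontal one
  iface <- which((final == 1L & rbind(final[-1, ], 0L) == 2L) |
                   (final == 2L & rbind(final[-1, ], 0L) == 1L), arr.ind = TRUE)
  expect_gt(nrow(iface), 40)
  expect_lt(sd(iface[, 1]), 2)           # straight within 2 px
  # area conservation under the divergence-free field (2% per frame)
  a0 <- sum(lab2 > 0)
  for (k in 2:(nstep + 1))
    expect_lt(abs(sum(out[[k]] > 0) - a0) / a0, 0.02 * (k - 1))
})

test_that("LIC renders streaks along the field and is seed-deterministic", {
  n <- 96
  ac <- function(m, by) {
    if (by == "x") cor(as.vector(m[, -1]), as.vector(m[, -n]))
    else cor(as.vector(m[-1, ]), as.vector(m[-n, ]))
  }
  horiz <- list(u = matrix(1, n, n), v = matrix(0, n, n))
  img <- lic_render(horiz, seed = 5)
  expect_identical(img, lic_render(horiz, seed = 5))
  expect_gt(ac(img, "x"), ac(img, "y") + 0.3)

  zero <- list(u = matrix(0, n, n), v = matrix(0, n, n))
  img0 <- lic_render(zero, seed = 5)
  expect_lt(abs(ac(img0, "x")), 0.1)
  expect_lt(abs(ac(img0, "y")), 0.1)

  # rigid rotation: tangential streaks, i.e. strong angular autocorrelation
  Y <- matrix(seq_len(n), n, n); X <- matrix(seq_len(n), n, n, byrow = TRUE)
  rot <- list(u = -(Y - n / 2), v = X - n / 2)
  imgr <- lic_render(rot, seed = 5)
  # compare correlation along circles vs along radii at radius ~ n/4
  th <- seq(0, 2 * pi, length.out = 200)
  ring1 <- imgr[cbind(round(n / 2 + 24 * sin(th)), round(n / 2 + 24 * cos(th)))]
  ray <- imgr[cbind(round(n / 2 + (5:40) * sin(1)), round(n / 2 + (5:40) * cos(1)))]
  expect_gt(cor(ring1[-1], ring1[-length(ring1)]),
            cor(ray[-1], ray[-length(ray)]) + 0.2)
})

test_that("flow calibration ranks parameter sets deterministically with a sane best", {
  tl <- tiny_movie()
  grid <- list(flow_params(levels = 4, winsize = 21, iterations = 3),
               flow_params(levels = 4, winsize = 31, iterations = 3),
               flow_params(levels = 2, winsize = 5, iterations = 1,
                           poly_n = 5, poly_sigma = 1.1))
  cal <- calibrate_flow(tl, grid, pairs = c(length(tl$truth) - 3, length(tl$truth) - 1))
  cal2 <- calibrate_flow(tl, grid, pairs = c(length(tl$truth) - 3, length(tl$truth) - 1))
  expect_identical(cal$report, cal2$report)
  expect_equal(cal$best_error, min(cal$report$error))
  # the degenerate tiny-window set must not win
  degenerate <- cal$report[cal$report$winsize == 5, "error"]
  expect_gt(degenerate, cal$best_error)
  expect_error(calibrate_flow(tl, list()), "empty")
})
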