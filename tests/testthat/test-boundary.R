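test_that("segmentation recovers known half-disk geometry, with and without noise", {
  img <- half_disk_image(R = 150)
  masks <- segment_domains(img)
  jac <- function(a, b) sum(a & b) / sum(a | b)
  expect_gte(jac(masks$mask_g, img$mask_g_true), 0.98)
  expect_gte(jac(masks$mask_r, img$mask_r_true), 0.98)

  imgn <- half_disk_image(R = 150, noise_sd = 0.05)
  masksn <- segment_domains(imgn)
  expect_gte(jac(masksn$mask_g, img$mask_g_true), 0.98)
  expect_gte(jac(masksn$mask_r, img$mask_r_true), 0.98)

  blank <- img
  blank$channel_r <- blank$channel_r * 0
  expect_error(segment_domains(blank), "channel_r")
})

test_that("boundary extraction recovers a straight diameter interface", {
  img <- half_disk_image(R = 200)
  masks <- segment_domains(img)
  skel <- extract_boundary(masks$mask_g, masks$mask_r)
  len <- boundary_length(skel)
  expect_gt(len, 2 * 200 - 30)   # rim trimming shortens both ends slightly
  expect_lt(len, 2 * 200 + 8)
  # skeleton is one pixel wide: thinning is idempotent
  expect_identical(colonymix:::thin_cpp(skel), skel)
})

test_that("boundary extraction recovers a circular core-annulus interface", {
  img <- ring_image(R_in = 100, R_out = 200)
  masks <- segment_domains(img)
  skel <- extract_boundary(masks$mask_g, masks$mask_r)
  # under the pixel-count convention an ideal thin digital circle counts
  # 8 R / sqrt(2) pixels (the chessboard perimeter), not 2 pi R
  expect_equal(boundary_length(skel), 8 * 100 / sqrt(2), tolerance = 0.05)
  # every skeleton pixel has exactly two 8-neighbours on a closed curve
  nb <- colonymix:::box_filter_cpp(skel * 1, 3) * 9 - skel
  expect_true(all(round(nb[skel]) == 2))
})

test_that("non-touching domains give an empty skeleton with a warning", {
  n <- 200
  g <- matrix(0, n, n); g[40:70, 40:70] <- 1
  r <- matrix(0, n, n); r[130:160, 130:160] <- 1
  masks <- segment_domains(list(channel_g = g, channel_r = r),
                           smooth_sigma = 0)
  expect_warning(skel <- extract_boundary(masks$mask_g, masks$mask_r),
                 "not adjacent")
  expect_equal(boundary_length(skel), 0)
})

test_that("boundary length is the pixel count, by convention", {
  m <- matrix(FALSE, 50, 120)
  m[25, 11:110] <- TRUE
  expect_equal(boundary_length(m), 100)
  expect_equal(boundary_length(m & FALSE), 0)
  # a 100-px 45-degree diagonal counts 100 pixels, not sqrt(2) * 100
  d <- matrix(FALSE, 120, 120)
  d[cbind(11:110, 11:110)] <- TRUE
  expect_equal(boundary_length(d), 100)
})

test_that("normalized boundary length behaves and is scale invariant", {
  expect_equal(normalized_boundary_length(100, 50), 2)
  expect_equal(normalized_boundary_length(0, 50), 0)
  expect_error(normalized_boundary_length(10, 0))

  nb <- function(R) analyze_boundary(half_disk_image(R = R))$normalized_length
  base <- nb(250)
  expect_equal(base, 2, tolerance = 0.1)
  expect_equal(nb(500) / base, 1, tolerance = 0.02)
})

test_that("rotating the diameter fixture changes its count exactly as the pixel metric predicts", {
  # pixel counting is a chessboard length: a straight segment of Euclidean
  # length L at angle theta counts L * max(|cos|, |sin|) pixels, so a 30
  # degree rotation of the diameter must scale the count by cos(30)
  img <- half_disk_image(R = 200)
  len_of <- function(im) {
    masks <- segment_domains(im)
    boundary_length(extract_boundary(masks$mask_g, masks$mask_r))
  }
  rot <- function(ch) EBImage::imageData(EBImage::rotate(
    EBImage::Image(ch), 30, bg.col = 0, output.dim = dim(ch) + 160))
  img30 <- list(channel_g = rot(img$channel_g), channel_r = rot(img$channel_r))
  expect_equal(len_of(img), 2 * 200, tolerance = 0.05)
  expect_equal(len_of(img30) / len_of(img), cos(30 * pi / 180), tolerance = 0.05)
})

test_that("EDM fractal dimension recovers rectifiable and fractal references", {
  # straight line across the full raster width
  line <- matrix(FALSE, 200, 1000)
  line[100, ] <- TRUE
  expect_equal(fractal_dimension_edm(line), 1, tolerance = 0.05)

  # circle (rectifiable closed curve)
  n <- 600
  Y <- matrix(seq_len(n), n, n); X <- matrix(seq_len(n), n, n, byrow = TRUE)
  circ <- colonymix:::thin_cpp(abs(sqrt((X - 300.5)^2 + (Y - 300.5)^2) - 200) < 0.6)
  expect_equal(suppressWarnings(fractal_dimension_edm(circ)), 1,
               tolerance = 0.05)

  # Koch curve, 4 subdivision rounds: analytic dimension log 4 / log 3;
  # measured inside the generator's scaling window (segment length .. span/8)
  koch <- koch_skeleton(iter = 4, span = 2187)
  D <- fractal_dimension_edm(koch, scale_min = 27, scale_max = 273)
  expect_equal(D, log(4) / log(3), tolerance = 0.08)

  expect_error(fractal_dimension_edm(line, n_scales = 2), "3 scales")
  expect_error(fractal_dimension_edm(line & FALSE), "empty")
})

test_that("image-path boundary length is cross-validated by the contact-count estimate", {
  # simulation-side estimate: interdomain contact count x mean spacing of
  # interface contacts (nearest-neighbour distance of contact midpoints).
  # The two paths measure the same interface differently: single-cell
  # fingers contribute skeleton on both flanks but each contact only once,
  # so agreement is order-of-magnitude with consistent ranking, not exact.
  sim_estimate <- function(co) {
    ct <- detect_contacts(co)
    lab <- setNames(co$cells$domain_label, co$cells$id)
    inter <- lab[as.character(ct$cell_a)] != lab[as.character(ct$cell_b)]
    mx <- (ct$ax + ct$bx)[inter] / 2
    my <- (ct$ay + ct$by)[inter] / 2
    dd <- as.matrix(dist(cbind(mx, my)))
    diag(dd) <- Inf
    sum(inter) * mean(apply(dd, 1, min))
  }
  lens <- sapply(c(14, 16), function(s) {
    res <- run_two_domain(2, n_target = 400, seed = s)
    img <- render_two_channel(res$colony, pixel_size = 0.1, psf_sigma = 2,
                              seed = 2)
    br <- analyze_boundary(img)
    expect_true(br$fractal_dimension >= 1 && br$fractal_dimension <= 2)
    c(image = br$length_um, sim = sim_estimate(res$colony))
  })
  ratio <- lens["image", ] / lens["sim", ]
  expect_true(all(ratio > 0.5 & ratio < 2))
})
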