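forces_at <- function(colony, vx = NULL, vy = NULL, om = NULL,
                      adhesion_on = TRUE) {
  cl <- colony$cells
  n <- nrow(cl)
  if (is.null(vx)) vx <- numeric(n)
  if (is.null(vy)) vy <- numeric(n)
  if (is.null(om)) om <- numeric(n)
  p <- colony$params
  colonymix:::compute_forces_cpp(cl$x, cl$y, cl$dx, cl$dy, cl$length,
                                 cl$radius, cl$adhesin, vx, vy, om,
                                 p$k_contact, p$gamma, p$contact_margin,
                                 adhesion_on)
}

test_that("growth elongates exponentially and respects the growing flag", {
  co <- make_colony(0, 0, growing = TRUE, growth_rate = log(2))
  co$cells$length <- 2
  expect_equal(grow_cells(co, 1)$cells$length, 4)

  co$cells$growing <- FALSE
  expect_equal(grow_cells(co, 1)$cells$length, 2)

  co$cells$growing <- TRUE
  co$cells$growth_rate <- 0
  expect_equal(grow_cells(co, 1)$cells$length, 2)
})

test_that("division bisects the parent capsule into equal tangent daughters", {
  p <- physics_params()
  co <- make_colony(0, 0, growing = TRUE, growth_rate = p$mean_growth_rate,
                    division_length = 3, length = 4, params = p)
  set.seed(1)
  co2 <- divide_cells(co)
  cl <- co2$cells
  expect_equal(nrow(cl), 2)
  # equal sizes tiling the parent: axis L/2 - r, centres at (L + 2r)/4
  expect_equal(cl$length, c(1.5, 1.5))
  expect_equal(sort(cl$x), c(-1.25, 1.25))
  expect_equal(cl$y, c(0, 0), tolerance = 0.02)  # orientation jitter only
  # facing caps tangent: no overlap introduced by division
  ct <- detect_contacts(co2, margin = 0)
  if (nrow(ct) > 0) expect_lte(max(ct$overlap), 1e-6)
  # inheritance
  expect_equal(cl$domain_label, c("green", "green"))
  expect_true(all(cl$id > 1))

  # below threshold -> unchanged
  co$cells$length <- 2.5
  expect_equal(nrow(divide_cells(co)$cells), 1)
})

test_that("N parents above threshold produce exactly 2N daughters with fresh ids", {
  p <- physics_params()
  co <- make_colony(x = c(0, 10, 20), y = 0, growing = TRUE,
                    growth_rate = 1, division_length = 3, length = 3.5,
                    params = p)
  set.seed(2)
  co2 <- divide_cells(co)
  expect_equal(nrow(co2$cells), 6)
  expect_false(anyDuplicated(co2$cells$id) > 0)
})

test_that("repulsion is Hookean in the overlap and vanishes without overlap", {
  p <- physics_params(k_contact = 100)
  co <- make_colony(x = c(0, 0), y = c(0, 0.9), params = p)
  f <- forces_at(co)
  expect_equal(abs(f$fy), c(10, 10))           # k * overlap = 100 * 0.1
  expect_equal(f$fy[1], -f$fy[2])
  expect_equal(f$fx, c(0, 0))

  co <- make_colony(x = c(0, 0), y = c(0, 1.02), params = p)  # contact, no overlap
  f <- forces_at(co)
  expect_equal(f$fy, c(0, 0))
  expect_equal(f$n_contacts, 1)
})

test_that("a symmetric three-cell sandwich leaves the middle cell force-free", {
  co <- make_colony(x = c(0, 0, 0), y = c(-0.9, 0, 0.9))
  f <- forces_at(co)
  expect_equal(f$fx[2], 0, tolerance = 1e-12)
  expect_equal(f$fy[2], 0, tolerance = 1e-12)
})

test_that("internal forces obey Newton's third law on random dense packings", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 40
    co <- make_colony(x = runif(n, 0, 12), y = runif(n, 0, 12),
                      dx = rnorm(n), dy = rnorm(n),
                      length = runif(n, 1, 3), adhesin = runif(n, 0, 5))
    f <- forces_at(co, vx = rnorm(n), vy = rnorm(n), om = rnorm(n, 0, 0.5))
    expect_lt(abs(sum(f$fx)), 1e-10)
    expect_lt(abs(sum(f$fy)), 1e-10)
  }
})

test_that("adhesion drags only transverse slip and dissipates relative motion", {
  p <- physics_params()
  co <- make_colony(x = c(0, 0), y = c(0, 0.95), adhesin = 2, params = p)
  # purely normal approach: no adhesion force beyond repulsion
  f0 <- forces_at(co, adhesion_on = FALSE)
  fn <- forces_at(co, vy = c(0.5, -0.5))
  expect_equal(fn$fx, f0$fx)
  expect_equal(fn$fy, f0$fy)

  # tangential slip at unit relative speed, k_pair 2: drag magnitude 2
  ft <- forces_at(co, vx = c(0.5, -0.5))
  expect_equal(ft$fx, c(-2, 2))  # drags each cell toward the other's motion
  # dissipativity: the force on b opposes the relative velocity v_b - v_a
  expect_lte(ft$fx[2] * (-1), 0)

  # k_pair = 0: no adhesion force regardless of motion
  co0 <- make_colony(x = c(0, 0), y = c(0, 0.95), adhesin = 0, params = p)
  fz <- forces_at(co0, vx = c(1, -1))
  expect_equal(fz$fx, c(0, 0))
})

test_that("relaxation resolves overlap symmetrically and only transversely differs with adhesion", {
  p <- physics_params()
  co <- make_colony(x = c(0, 0), y = c(-0.4, 0.4), params = p)
  r <- relax_colony(co)
  ct <- detect_contacts(r, margin = 0)
  expect_lte(max(ct$overlap, 0), p$overlap_tol)
  expect_equal(r$last$disp_y[1], -r$last$disp_y[2], tolerance = 1e-12)

  # isolated cell: zero displacement
  co1 <- make_colony(0, 0, params = p)
  r1 <- relax_colony(co1)
  expect_equal(r1$last$disp_x, 0)
  expect_equal(r1$last$disp_y, 0)

  # adhesion must not change the final normal separation
  mk <- function(adh) make_colony(x = c(0, 0), y = c(-0.4, 0.4),
                                  adhesin = adh, params = p)
  sep0 <- diff(relax_colony(mk(0))$cells$y)
  sep10 <- diff(relax_colony(mk(10))$cells$y)
  expect_equal(sep0, sep10, tolerance = 1e-6)
})

test_that("zero adhesion strength is bit-identical to the adhesion-free code path", {
  run <- function(adhesion_on) {
    set.seed(123)
    p <- physics_params(adhesion_default = 0)
    co <- colony_two_founders(p)
    for (i in 1:30) co <- step_colony(co, adhesion_on = adhesion_on)
    co$cells
  }
  expect_identical(run(TRUE), run(FALSE))
})

test_that("stepping is deterministic given the seed", {
  run <- function() {
    set.seed(99)
    co <- colony_two_founders(physics_params(adhesion_default = 1))
    for (i in 1:25) co <- step_colony(co)
    co$cells
  }
  expect_identical(run(), run())
})

test_that("repeated stepping yields exponential proliferation at the expected rate", {
  # daughters are born at division_length/2 - radius, so one generation is
  # ln(3)/growth_rate with the default geometry; the population rate after
  # the founder transient must match ln(2)/t_gen
  set.seed(5)
  p <- physics_params()
  co <- colony_founder(p)
  ns <- ts <- numeric(0)
  for (i in 1:220) {
    co <- step_colony(co)
    ns <- c(ns, nrow(co$cells))
    ts <- c(ts, co$time)
  }
  w <- ts > 4
  fitted_rate <- unname(coef(lm(log(ns[w]) ~ ts[w]))[2])
  t_gen <- log(3) / p$mean_growth_rate
  expect_equal(fitted_rate, log(2) / t_gen, tolerance = 0.15)
  expect_true(all(diff(ns) >= 0))
})

test_that("external forces produce overdamped motion and validate ids", {
  # gamma * (length + 2 r) = 1 => velocity equals force
  p <- physics_params(gamma = 0.5)
  co <- make_colony(0, 0, length = 1, params = p)
  co <- apply_external_force(co, data.frame(id = 1L, fx = 1, fy = 0))
  r <- relax_colony(co)
  expect_equal(r$last$disp_x / r$last$elapsed, 1, tolerance = 1e-9)
  expect_equal(r$last$disp_y, 0)

  # equal and opposite forces on a rigidly touching pair: centroid stays
  co2 <- make_colony(x = c(0, 0), y = c(0, 1), adhesin = 0, params = p)
  co2 <- apply_external_force(co2, data.frame(id = c(1L, 2L),
                                              fx = c(1, -1), fy = c(0, 0)))
  r2 <- relax_colony(co2)
  expect_equal(mean(r2$last$disp_x), 0, tolerance = 1e-12)

  # zero map is identity; unknown id errors by name
  expect_identical(apply_external_force(co2, data.frame(id = integer(),
                                                        fx = numeric(),
                                                        fy = numeric())),
                   co2)
  expect_error(apply_external_force(co2, data.frame(id = 7L, fx = 1, fy = 0)),
               "7")
})

test_that("a colony grown from one founder keeps a connected contact network", {
  set.seed(31)
  co <- colony_founder(physics_params())
  for (i in 1:170) co <- step_colony(co)
  ct <- detect_contacts(co)
  n <- nrow(co$cells)
  expect_gt(n, 50)
  # breadth-first search over the contact graph
  adj <- split(c(match(ct$cell_b, co$cells$id), match(ct$cell_a, co$cells$id)),
               c(match(ct$cell_a, co$cells$id), match(ct$cell_b, co$cells$id)))
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[as.character(v)]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  expect_true(all(seen))
})
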