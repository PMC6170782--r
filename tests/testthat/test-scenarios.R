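test_that("microcolony scenario handles the single-cell edge case", {
  res <- run_microcolony(0, n_target = 1, seed = 1)
  expect_equal(nrow(res$colony$cells), 1)
  expect_equal(res$colony$cells$x, 0)        # no contacts, no displacement
  expect_s3_class(res, "scenario_result")
})

test_that("two-domain initial state has one interdomain contact and full mixing ratio", {
  co <- colony_two_founders(physics_params())
  ct <- detect_contacts(co)
  expect_equal(nrow(co$cells), 2)
  expect_equal(nrow(ct), 1)
  expect_equal(interdomain_contact_ratio(co), 1)
  expect_setequal(co$cells$domain_label, c("green", "red"))
})

test_that("single-label colonies keep interdomain ratio zero throughout", {
  set.seed(2)
  co <- colony_two_founders(physics_params())
  co$cells$domain_label <- "green"
  for (i in 1:60) {
    co <- step_colony(co)
    if (i %% 20 == 0) expect_equal(interdomain_contact_ratio(co), 0)
  }
})

test_that("two-domain lineage labels always trace back to the two founders", {
  res <- run_two_domain(1, n_target = 120, seed = 3)
  expect_setequal(unique(res$colony$cells$domain_label), c("green", "red"))
  expect_true(all(res$metrics$interdomain_ratio >= 0 &
                    res$metrics$interdomain_ratio <= 1))
})

test_that("scenario metrics are reproducible for identical seed and parameters", {
  a <- run_two_domain(0.5, n_target = 150, seed = 7)
  b <- run_two_domain(0.5, n_target = 150, seed = 7)
  expect_identical(a$metrics, b$metrics)
  c <- run_two_domain(0.5, n_target = 150, seed = 8)
  expect_false(identical(a$metrics, c$metrics))
})

test_that("chain experiment: free ends slide off, adhesion couples the chain", {
  tab <- run_chain(n_cells = 10, adhesion_values = c(0, 1, 3),
                   displacement_target = 2)
  interior <- subset(tab, cell >= 2 & cell <= 9)
  # (a) near-zero interior displacement without adhesion
  expect_lt(max(subset(interior, adhesion == 0)$displacement), 0.05)
  # ends reached the target
  ends <- subset(tab, cell %in% c(1, 10))
  expect_true(all(ends$displacement >= 2 - 1e-6))
  # (b) interior displacement non-decreasing in adhesion, per cell
  for (cc in 2:9) {
    d <- subset(tab, cell == cc)
    d <- d[order(d$adhesion), ]
    expect_true(all(diff(d$displacement) >= -1e-3))
  }
  # (c) displacement decays with distance from the nearest forced end
  for (a in unique(tab$adhesion)) {
    d <- subset(tab, adhesion == a)
    expect_true(all(diff(d$displacement[1:5]) <= 1e-3))      # cells 1..5
    expect_true(all(diff(d$displacement[6:10]) >= -1e-3))    # cells 6..10
  }
  # displacement_target unreachable -> error
  expect_error(run_chain(n_cells = 5, adhesion_values = 0,
                         displacement_target = 2, force_magnitude = 0.01,
                         max_steps = 5L),
               "unreachable")
})

test_that("rendering a stationary cell gives identical frames and zero truth", {
  cells <- colonymix:::new_cells(1L, 0, 0, 1, 0, 2, 0.5, 0, Inf,
                                 "green", 0, FALSE)
  snaps <- list(list(time = 0, step = 0L, cells = cells),
                list(time = 1, step = 1L, cells = cells))
  tl <- render_timelapse(snaps, noise_sd = 0)
  expect_identical(tl$frames[[1]], tl$frames[[2]])
  tr <- tl$truth[[1]]
  expect_equal(max(abs(tr$u[tr$mask])), 0)
  expect_equal(max(abs(tr$v[tr$mask])), 0)
})

test_that("rigid translation yields a constant ground-truth field", {
  cells <- colonymix:::new_cells(1:2, c(0, 1), c(0, 1.2), 1, 0, 2, 0.5,
                                 0, Inf, "green", 0, FALSE)
  moved <- cells
  moved$x <- moved$x + 0.3                 # 3 px at 0.1 um/px
  moved$acc_dx <- 0.3
  snaps <- list(list(time = 0, step = 0L, cells = cells),
                list(time = 1, step = 1L, cells = moved))
  tl <- render_timelapse(snaps, pixel_size = 0.1, noise_sd = 0)
  tr <- tl$truth[[1]]
  expect_equal(max(abs(tr$u[tr$mask] - 3)), 0, tolerance = 1e-9)
  expect_equal(max(abs(tr$v[tr$mask])), 0, tolerance = 1e-9)
})

test_that("rendered foreground area grows monotonically with the colony", {
  tl <- tiny_movie()
  areas <- vapply(tl$masks, sum, numeric(1))
  expect_true(all(diff(areas) > 0))
  # labels cover the first frame's footprint with the two founder domains
  expect_setequal(unique(as.vector(tl$labels0[tl$masks[[1]]])), c(1L, 2L))
  expect_error(render_timelapse(list()), "empty")
})
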