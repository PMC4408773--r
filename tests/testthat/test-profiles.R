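test_that("sliding-filter profile equals the brute-force oracle", {
  set.seed(13)
  tb <- runif(80, -180, 180)
  fb <- runif(3000, -180, 180)
  pr <- turn_rate_profile(tb, fb, dt_s = 0.0625)
  want <- profile_oracle(tb, fb, 0.0625)
  expect_equal(pr$rate_per_min, want, tolerance = 1e-12)
  # circular wrap: the profile at -180 equals the profile at +180
  expect_identical(pr$rate_per_min[pr$bearing_deg == -180],
                   pr$rate_per_min[pr$bearing_deg == 180])
  expect_true(all(pr$rate_per_min >= 0, na.rm = TRUE))
})

test_that("turning-angle profile averages within circular windows", {
  set.seed(14)
  tb <- runif(60, -180, 180)
  ang <- runif(60, -120, 120)
  ap <- turning_angle_profile(tb, ang)
  g <- ap$bearing_deg
  want <- vapply(g, function(b) {
    sel <- abs(wrap_angle(tb - b)) <= 30
    if (any(sel)) mean(ang[sel]) else NA_real_
  }, 0)
  expect_equal(ap$mean_angle_deg, want, tolerance = 1e-12)
  expect_true(all(abs(ap$mean_angle_deg) <= 180, na.rm = TRUE))
})

test_that("rate map equals a per-cell double-loop recomputation", {
  set.seed(15)
  tb <- runif(40, -180, 180); td <- runif(40, 10, 60)
  fb <- runif(800, -180, 180); fd <- runif(800, 10, 60)
  m <- turn_rate_map(tb, td, fb, fd, dt_s = 0.0625,
                     bearing_step_deg = 20, distance_step_mm = 10)
  want <- rate_map_oracle(tb, td, fb, fd, 0.0625,
                          m$bearing_grid_deg, m$distance_grid_mm)
  expect_equal(m$rate_per_min, want, tolerance = 1e-12)
  # a single event contributes to every cell whose box covers it
  m1 <- turn_rate_map(10, 50, fb, fd, 0.0625,
                      bearing_step_deg = 20, distance_step_mm = 10)
  covered <- outer(abs(wrap_angle(m1$bearing_grid_deg - 10)) <= 30,
                   abs(m1$distance_grid_mm - 50) <= 15, "&")
  expect_identical(unname(m1$n_turns > 0), unname(covered))
})

test_that("mirror flip negates turning-angle maps but not rate maps", {
  set.seed(16)
  tb <- runif(50, -180, 180); td <- runif(50, 10, 60)
  ang <- runif(50, -120, 120)
  fb <- runif(1000, -180, 180); fd <- runif(1000, 10, 60)
  m <- turn_rate_map(tb, td, fb, fd, 0.0625)
  m_f <- turn_rate_map(-tb, td, -fb, fd, 0.0625)
  expect_equal(m_f$rate_per_min[rev(seq_along(m$bearing_grid_deg)), ],
               m$rate_per_min, tolerance = 1e-12)
  am <- turning_angle_map(tb, td, ang)
  am_f <- turning_angle_map(-tb, td, -ang)
  expect_equal(am_f$mean_angle_deg[rev(seq_along(am$bearing_grid_deg)), ],
               -am$mean_angle_deg, tolerance = 1e-12)
  # the raw event bank is retained for the simulator
  expect_equal(nrow(am$bank), 50)
})

test_that("proportion-toward map pools within time/distance boxes", {
  tt <- c(10, 20, 100); dd <- c(30, 32, 60); toward <- c(TRUE, FALSE, TRUE)
  pm <- proportion_toward_map(tt, dd, toward)
  i <- which(pm$time_grid_s == 15); j <- which(pm$distance_grid_mm == 30)
  expect_equal(pm$proportion[i, j], 0.5)  # first two turns in this box
  expect_true(all(pm$proportion >= 0 & pm$proportion <= 1, na.rm = TRUE))
  expect_true(any(is.na(pm$proportion)))  # empty boxes flagged undefined
})

test_that("profile estimator is consistent: error shrinks with data size", {
  spec <- parametric_policy_spec(amplitude = 0.4)
  err <- vapply(c(4, 16), function(nl) {
    syn <- generate_dataset(spec, n_dishes = 1, n_larvae = nl,
                            duration_s = 300, seed = 77)
    fit <- fit_chemotaxis(syn$dataset, maps = FALSE)
    est <- recover_policy_parameters(fit)
    abs(est$amplitude - 0.4)
  }, 0)
  expect_lt(err[2], err[1] + 0.05)  # allow sampling slack on the comparison
  expect_lt(err[2], 0.2)
})
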