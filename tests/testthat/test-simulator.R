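test_that("ballistic limit: zero rate and zero noise give straight runs", {
  pol <- tiny_policy(base_per_s = 0)
  cfg <- simulation_config(angular_noise_halfwidth_deg = 0,
                           trial_duration_s = 10, n_animals = 2)
  tr <- simulate_trial(pol, cfg, seed = 1)
  expect_equal(nrow(tr$events), 0L)
  M <- tr$tracks[[1]]
  k <- nrow(M) - 1
  disp <- sqrt((M[k + 1, 4] - M[1, 4])^2 + (M[k + 1, 5] - M[1, 5])^2)
  expect_equal(disp, k * cfg$dt_s * pol$run_speed_mm_s, tolerance = 1e-9)
})

test_that("a 60-degree turn at 53.7 deg/s lasts exactly 18 steps", {
  pol <- tiny_policy(angles = 60, base_per_s = 0.5)
  cfg <- simulation_config(angular_noise_halfwidth_deg = 0,
                           trial_duration_s = 60, n_animals = 1)
  tr <- simulate_trial(pol, cfg, seed = 7)
  expect_gt(nrow(tr$events), 0)
  dur <- (tr$events$t_end - tr$events$t_start) / cfg$dt_s
  expect_true(all(abs(dur - ceiling((60 / 53.7) / 0.0625)) < 1e-9))
  expect_true(all(tr$events$realized_angle_deg == 60))
})

test_that("turn counts match the dead-time-corrected renewal oracle", {
  # constant rate r = 0.1/s; each turn occupies |angle|/53.7 s of dead
  # time, so events arrive at rate 1/(1/r + mean dead time)
  pol <- tiny_policy(angles = c(30, -30), base_per_s = 0.1)
  cfg <- simulation_config(angular_noise_halfwidth_deg = 0,
                           trial_duration_s = 300, n_animals = 200)
  tr <- simulate_trial(pol, cfg, seed = 11)
  dead <- ceiling((30 / 53.7) / 0.0625) * 0.0625
  expected <- 300 / (1 / 0.1 + dead) * 200
  se <- sqrt(expected)
  expect_lt(abs(nrow(tr$events) - expected), 4 * se)
})

test_that("geometry is conserved: segment lengths and arena containment", {
  pol <- make_parametric_policy(parametric_policy_spec(amplitude = 0.5,
                                                       toward_bias = 0.7),
                                seed = 2)
  cfg <- simulation_config(trial_duration_s = 300, n_animals = 5)
  tr <- simulate_trial(pol, cfg, seed = 3)
  for (M in tr$tracks) {
    head_len <- sqrt((M[, 2] - M[, 4])^2 + (M[, 3] - M[, 5])^2)
    tail_len <- sqrt((M[, 6] - M[, 4])^2 + (M[, 7] - M[, 5])^2)
    expect_lt(max(abs(head_len - 2.15)), 1e-9)
    expect_lt(max(abs(tail_len - 2.15)), 1e-9)
    expect_lte(max(sqrt(M[, 4]^2 + M[, 5]^2)), 75)
  }
})

test_that("simulation is deterministic given the seed", {
  pol <- tiny_policy()
  cfg <- simulation_config(trial_duration_s = 30, n_animals = 3)
  t1 <- simulate_trial(pol, cfg, seed = 42)
  t2 <- simulate_trial(pol, cfg, seed = 42)
  expect_identical(t1$tracks, t2$tracks)
  expect_identical(t1$events, t2$events)
  t3 <- simulate_trial(pol, cfg, seed = 43)
  expect_false(identical(t1$tracks, t3$tracks))
})

test_that("simulated trials round-trip through the track format", {
  pol <- tiny_policy()
  cfg <- simulation_config(trial_duration_s = 20, n_animals = 3)
  tr <- simulate_trial(pol, cfg, seed = 5)
  ds <- trial_to_dataset(tr)
  f <- tempfile(fileext = ".tsv")
  write_tracks(ds, f)
  ds2 <- read_tracks(f)
  expect_length(ds2$trajectories, 3)
  expect_equal(ds2$trajectories[[1]]$mid_x_mm, ds$trajectories[[1]]$mid_x_mm,
               tolerance = 1e-9)
})

test_that("fragmentation drops boundary and collision frames", {
  cfg <- simulation_config(n_animals = 2, trial_duration_s = 1)
  nf <- 17
  circ <- cbind((0:(nf - 1)) * 0.0625,
                70 * cos(0:(nf - 1) / 10) + 2.15, 70 * sin(0:(nf - 1) / 10),
                70 * cos(0:(nf - 1) / 10), 70 * sin(0:(nf - 1) / 10),
                70 * cos(0:(nf - 1) / 10) - 2.15, 70 * sin(0:(nf - 1) / 10),
                0)
  center <- cbind((0:(nf - 1)) * 0.0625, 2.15, 0, 0, 0, -2.15, 0, 0)
  trial <- structure(list(tracks = list(circ, center), cfg = cfg,
                          mode = cfg$mode), class = "chemotaxis_trial")
  ds <- fragment_tracks(trial)
  ids <- vapply(ds$trajectories, attr, "", "animal_id")
  expect_false(any(grepl("^model1", ids)))   # circling at 70 mm: discarded
  expect_true(any(grepl("^model2", ids)))    # center larva untouched
  expect_equal(nrow(ds$trajectories[[1]]), nf)

  # two larvae within 5 mm lose those frames
  near1 <- center; near2 <- center
  near2[, 4] <- 30; near2[, 2] <- 32.15; near2[, 6] <- 27.85
  near2[5:8, 4] <- 3; near2[5:8, 2] <- 5.15; near2[5:8, 6] <- 0.85
  trial2 <- structure(list(tracks = list(near1, near2), cfg = cfg,
                           mode = cfg$mode), class = "chemotaxis_trial")
  keep <- larvatax:::fragment_mask(trial2)
  expect_true(all(!keep[5:8, 1]) && all(!keep[5:8, 2]))
  expect_true(all(keep[-(5:8), ]))
})

test_that("transition probabilities follow the policy's bearing dependence", {
  pol <- make_parametric_policy(parametric_policy_spec(amplitude = 0.5),
                                seed = 2)
  cfg <- simulation_config(trial_duration_s = 300, n_animals = 40)
  tr <- simulate_trial(pol, cfg, seed = 13)
  # empirical events per run-state exposure, in coarse bearing bins
  bins <- seq(-180, 180, by = 60)
  ev <- tr$events$bearing_init_deg
  exb <- unlist(lapply(tr$tracks, function(M) {
    run <- M[, 8] == 0
    heading <- atan2(M[run, 3] - M[run, 5], M[run, 2] - M[run, 4]) * 180 / pi
    sdir <- atan2(0 - M[run, 5], 45 - M[run, 4]) * 180 / pi
    wrap_angle(sdir - heading)
  }))
  for (k in seq_len(length(bins) - 1)) {
    sel_e <- ev >= bins[k] & ev < bins[k + 1]
    sel_x <- exb >= bins[k] & exb < bins[k + 1]
    exposure <- sum(sel_x) * cfg$dt_s
    mid <- (bins[k] + bins[k + 1]) / 2
    expected <- rate_lookup(pol, mid, 45) * exposure
    expect_lt(abs(sum(sel_e) - expected),
              4 * sqrt(expected) + 0.05 * expected + 3)
  }
})

test_that("experiment-level seeding is reproducible and order-independent", {
  pol <- tiny_policy()
  cfg <- simulation_config(trial_duration_s = 30, n_animals = 3)
  s1 <- simulate_experiment(pol, cfg, n_trials = 5, seed = 8)
  s2 <- simulate_experiment(pol, cfg, n_trials = 5, seed = 8)
  expect_identical(s1$pref, s2$pref)
  # trial 3 alone reproduces element 3 of the batch
  t3 <- simulate_trial(pol, cfg, seed = larvatax:::child_seed(8, 3))
  keep <- larvatax:::fragment_mask(t3, cfg)
  mx <- vapply(t3$tracks, function(M) M[, 4], numeric(nrow(t3$tracks[[1]])))
  expect_equal(larvatax:::pref_from_x(mx[keep]), s1$pref[3])
})
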