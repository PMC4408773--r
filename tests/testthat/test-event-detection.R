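test_that("schmitt trigger follows the hysteresis hand-trace", {
  cfg <- schmitt_config(35, 15, 0)
  iv <- schmitt_detect(c(0, 40, 40, 10, 0), cfg, dt_s = 0.0625)
  expect_equal(nrow(iv), 1L)
  expect_equal(c(iv$i_start, iv$i_end), c(2L, 4L))  # frames 1-3, 0-based
  expect_equal(nrow(schmitt_detect(rep(0, 50), cfg, 0.0625)), 0L)
  # oscillation inside the hysteresis band never arms the trigger
  expect_equal(nrow(schmitt_detect(rep(c(20, 30), 25), cfg, 0.0625)), 0L)
  # negative excursions count via rectification
  iv2 <- schmitt_detect(c(0, -40, -40, -10, 0), cfg, 0.0625)
  expect_equal(nrow(iv2), 1L)
  # events shorter than min_duration_s are discarded
  cfg2 <- schmitt_config(35, 15, 0.25)
  expect_equal(nrow(schmitt_detect(c(0, 40, 10, 0), cfg2, 0.0625)), 0L)
})

test_that("schmitt trigger equals an explicit automaton on random signals", {
  set.seed(42)
  cfg <- schmitt_config(35, 15, 0.25)
  for (k in seq_len(200)) {
    x <- abs(rnorm(60, 0, 30)) * sample(c(1, -1), 60, replace = TRUE)
    got <- schmitt_detect(x, cfg, dt_s = 0.0625)
    want <- schmitt_oracle(x, 35, 15, 0.25, 0.0625)
    expect_identical(got$i_start, want$i_start)
    expect_identical(got$i_end, want$i_end)
  }
})

test_that("turns require reorientation, posture and a >20 degree change", {
  # implanted 60-degree reorientation at 80 deg/s with bent posture
  ramp <- c(rep(0, 40), seq(0, 60, by = 80 * 0.0625), rep(60, 40))
  bend <- ifelse(ramp > 0 & ramp < 60, 40, 0)
  kin <- kin_series(ramp, head_angle_deg = bend)
  tu <- detect_turns(kin)
  expect_equal(nrow(tu), 1L)
  expect_equal(tu$turning_angle_deg, 60, tolerance = 0.01)

  # straight run with a 10-degree wiggle: below every threshold
  t <- seq(0, 10, by = 0.0625)
  kin2 <- kin_series(10 * sin(2 * pi * 0.5 * t), head_angle_deg = 5)
  expect_equal(nrow(detect_turns(kin2)), 0L)

  # 25-degree body swing with a flat head: rejected by the posture gate
  ramp3 <- c(rep(0, 40), seq(0, 25, by = 50 * 0.0625), rep(25, 40))
  kin3 <- kin_series(ramp3, head_angle_deg = 3)
  expect_equal(nrow(detect_turns(kin3)), 0L)

  # same swing with bent posture passes (25 > 20 cutoff)
  kin4 <- kin_series(ramp3, head_angle_deg = ifelse(ramp3 %in% c(0, 25), 0, 30))
  expect_equal(nrow(detect_turns(kin4)), 1L)
})

test_that("turning angle sign and toward classification are consistent", {
  fit <- biased_fit()
  tu <- fit$turns
  expect_gt(nrow(tu), 100)
  expect_true(all(abs(tu$turning_angle_deg) > 20))
  expect_true(all(tu$t_end > tu$t_start))
  # toward_odor equals the strict |after| < |before| predicate, recomputed
  expect_identical(tu$toward_odor,
                   abs(tu$bearing_after_deg) < abs(tu$bearing_before_deg))
})

test_that("detector recovers implanted turns on clean synthetic data", {
  syn <- biased_syn()
  fit <- biased_fit()
  sc <- score_detection(syn$truth, fit$turns)
  expect_gte(sc$sensitivity, 0.95)
  expect_gte(sc$precision, 0.95)
})

test_that("head casts are classified by the flanking window", {
  t <- seq(0, 30, by = 0.0625)
  bump <- function(at) 30 * exp(-((t - at) / 0.3)^2)
  kin <- kin_series(rep(0, length(t)), head_angle_deg = bump(5) + bump(20))
  turns <- data.frame(t_start = 6, t_end = 7)
  casts <- detect_head_casts(kin, turns)
  expect_equal(nrow(casts), 2L)
  expect_true(casts$flanking[1])            # 1 s before the turn
  expect_false(casts$flanking[2])           # 13 s after: outside the window
  expect_equal(casts$flanking_turn[1], 1L)
  expect_gte(max(casts$peak_head_angle_deg), 29)
  # flat head angle: nothing detected
  kin0 <- kin_series(rep(0, 100))
  expect_equal(nrow(detect_head_casts(kin0, turns)), 0L)
})

test_that("runs span turn end to the next turn's first flanking cast", {
  t <- seq(0, 40, by = 0.0625)
  kin <- kin_series(rep(0, length(t)))
  turns <- data.frame(t_start = c(10, 20), t_end = c(11, 22))
  casts <- data.frame(t_start = 18, t_end = 18.5, peak_head_angle_deg = 25,
                      flanking = TRUE, flanking_turn = 2L)
  runs <- segment_runs(turns, casts, kin)
  expect_equal(runs$t_start, c(0, 11, 22))
  expect_equal(runs$t_end, c(10, 18, 40))
  # no turns: one run spanning the whole trajectory
  r0 <- segment_runs(empty <- detect_turns(kin), casts[0, ], kin)
  expect_equal(nrow(r0), 1L)
  expect_equal(c(r0$t_start, r0$t_end), c(0, 40))
  # a turn ending exactly at the trajectory end leaves no final run
  turns_end <- data.frame(t_start = c(10), t_end = c(40))
  r1 <- segment_runs(turns_end, casts[0, ], kin)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$t_end, 10)
})

test_that("distractor wiggles below the cutoff produce no false positives", {
  syn <- cached("wiggle_syn", function() {
    generate_dataset(parametric_policy_spec(), n_dishes = 2, n_larvae = 10,
                     duration_s = 300, seed = 55,
                     distractor_wiggles = TRUE, jitter_mm = 0.02)
  })
  fit <- fit_chemotaxis(syn$dataset, maps = FALSE)
  sc <- score_detection(syn$truth, fit$turns)
  expect_identical(sc$n_detected - sc$n_matched, 0L)  # zero distractor hits
  expect_gte(sc$sensitivity, 0.95)
})
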