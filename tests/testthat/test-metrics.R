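test_that("counted preference matches the defining arithmetic", {
  expect_equal(pref_counted(10, 10, 0), 0)
  expect_equal(pref_counted(20, 0, 0), 1)
  expect_equal(pref_counted(15, 3, 2), 0.6)
  expect_error(pref_counted(0, 0, 0), "undefined")
})

test_that("filmed preference is a midline time split with even tie handling", {
  mk <- function(x) {
    tr <- traj_from_angles(rep(0, length(x)), mid_x = x, mid_y = rep(0, length(x)))
    larva_dataset(list(tr), arena_spec())
  }
  expect_equal(pref_filmed(mk(c(10, 20, 30, 5))), 1)
  expect_equal(pref_filmed(mk(c(10, 20, 30, -5))), 0.5)   # 3:1 time split
  expect_equal(pref_filmed(mk(c(10, -10, 0, 0))), 0)      # midline frames split
  # mirror-flip about the midline negates the score exactly
  x <- c(10, 25, -3, 7, 0, -12)
  expect_equal(pref_filmed(mk(-x)), -pref_filmed(mk(x)))
  expect_true(abs(pref_filmed(mk(x))) <= 1)
})

test_that("run speed is the duration-weighted mean over runs", {
  runs <- data.frame(duration_s = c(10, 10), mean_speed_mm_s = c(1, 2))
  expect_equal(run_speed(runs), 1.5)
  expect_equal(run_speed(runs[1, ]), 1)
  expect_error(run_speed(runs[0, ]), "no runs")
})

test_that("overall turn rate pools counts and durations before dividing", {
  expect_equal(overall_turn_rate(10, 300), 2)
  expect_equal(overall_turn_rate(0, 300), 0)
  expect_equal(overall_turn_rate(c(5, 5), c(100, 200)), 2)  # ratio of sums
  expect_error(overall_turn_rate(3, 0), "zero")
})

test_that("toward/away rates use strict bearing classes", {
  dt <- 0.0625
  frames <- c(rep(45, 800), rep(135, 800))     # equal occupancy per class
  ta <- turn_rate_toward_away(c(10, -80, 100), frames, dt)
  expect_equal(unname(ta["toward"]), 60 * 2 / (800 * dt))
  expect_equal(unname(ta["away"]), 60 * 1 / (800 * dt))
  # |bearing| = 90 exactly belongs to neither class
  ta2 <- turn_rate_toward_away(c(90, -90), frames, dt)
  expect_equal(unname(ta2), c(0, 0))
  # zero occupancy in a class is undefined
  ta3 <- turn_rate_toward_away(c(10), rep(45, 100), dt)
  expect_true(is.na(ta3[["away"]]))
})

test_that("proportion toward implements the strict inequality", {
  tu <- data.frame(bearing_before_deg = c(120, -30),
                   bearing_after_deg = c(40, -100))
  expect_equal(proportion_toward(tu), 0.5)
  tie <- data.frame(bearing_before_deg = 90, bearing_after_deg = -90)
  expect_equal(proportion_toward(tie), 0)     # tie counts as not toward
  expect_error(proportion_toward(tu[0, ]), "no turns")
})

test_that("group comparison applies the Bonferroni bookkeeping", {
  set.seed(9)
  same <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  res <- compare_groups(same)
  expect_equal(res$critical_level, 0.05 / 3)
  expect_false(any(res$pairwise$significant & res$pairwise$p_value > 0.05 / 3))
  shifted <- list(a = rnorm(40), b = rnorm(40) + 1, c = rnorm(40))
  res2 <- compare_groups(shifted)
  expect_lt(res2$omnibus$p_value, 0.001)
  expect_true(res2$pairwise$significant[res2$pairwise$group1 == "a" &
                                        res2$pairwise$group2 == "b"])
  expect_warning(compare_groups(list(a = 1, b = rnorm(5), c = rnorm(5))),
                 "excluding")
})

test_that("density map integrates to the mean tracked animal count", {
  # one stationary animal: 1/900 per mm2 inside its 30 mm square, 0 outside
  tr <- traj_from_angles(rep(0, 32), mid_x = rep(11, 32), mid_y = rep(5, 32))
  ds <- larva_dataset(list(tr), arena_spec())
  dm <- density_map(ds)
  at <- dm$animals_per_mm2[which(dm$x_grid_mm == 11),
                           which(dm$y_grid_mm == 5)]
  expect_equal(at, 1 / 900)
  expect_equal(dm$animals_per_mm2[which(dm$x_grid_mm == -51),
                                  which(dm$y_grid_mm == 1)], 0)
  # doubling the animals doubles the density everywhere
  tr2 <- traj_from_angles(rep(0, 32), mid_x = rep(11, 32), mid_y = rep(5, 32))
  attr(tr2, "animal_id") <- "a2"
  dm2 <- density_map(larva_dataset(list(tr, tr2), arena_spec()))
  expect_equal(dm2$animals_per_mm2, 2 * dm$animals_per_mm2)
  # discrete integral over the arena matches the grid-resolution oracle
  # (a point mass is covered by every cell whose 30 mm box contains it)
  nx <- sum(abs(dm$x_grid_mm - 11) <= 15)
  ny <- sum(abs(dm$y_grid_mm - 5) <= 15)
  integral <- sum(dm2$animals_per_mm2) * 2^2
  expect_equal(integral, 2 * (nx * 2 / 30) * (ny * 2 / 30))
  expect_equal(integral, 2, tolerance = 0.15)
})
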