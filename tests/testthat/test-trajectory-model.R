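test_that("angle_diff wraps into (-180, 180]", {
  expect_equal(angle_diff(170, -170), -20)
  expect_equal(angle_diff(0, 0), 0)
  expect_equal(angle_diff(-90, 90), 180)  # antipodal maps to +180
  expect_equal(angle_diff(10, 350), 20)
  # result is congruent to a - b mod 360 and inside the interval
  set.seed(4)
  a <- runif(200, -720, 720); b <- runif(200, -720, 720)
  d <- angle_diff(a, b)
  expect_true(all(d > -180 & d <= 180))
  expect_true(all(abs((a - b - d) %% 360) < 1e-9 |
                  abs((a - b - d) %% 360 - 360) < 1e-9))
})

test_that("bearing convention: 0 toward source, positive to the left", {
  arena <- arena_spec()
  tr <- traj_from_angles(c(0, 0), mid_x = c(0, 0), mid_y = c(0, 0))
  kin <- derive_kinematics(tr, arena)         # head at (2.15, 0), source (45, 0)
  expect_equal(kin$bearing_deg, c(0, 0))
  arena_left <- arena_spec(odor_source_xy_mm = c(0, 45))
  kin2 <- derive_kinematics(tr, arena_left)   # source straight to the left
  expect_equal(kin2$bearing_deg, c(90, 90))
  expect_equal(kin$distance_mm, c(45, 45))
})

test_that("reorientation speed is the central difference of the tail angle", {
  tr <- traj_from_angles(c(10, 20, 30))
  kin <- derive_kinematics(tr, arena_spec())
  expect_equal(kin$reorientation_speed_deg_s[2], (30 - 10) / (2 * 0.0625))
  # circular continuity: a wrap through 180 does not create a 360 jump
  tr2 <- traj_from_angles(c(175, 180, -175))
  kin2 <- derive_kinematics(tr2, arena_spec())
  expect_equal(kin2$reorientation_speed_deg_s[2], 10 / (2 * 0.0625))
})

test_that("kinematics are invariant under rotation and flip sign under mirror", {
  set.seed(7)
  n <- 40
  tr <- traj_from_angles(cumsum(rnorm(n, 0, 8)),
                         head_angle_deg = rnorm(n, 0, 15),
                         mid_x = cumsum(rnorm(n, 0.05, 0.02)),
                         mid_y = cumsum(rnorm(n, 0, 0.05)))
  kin <- derive_kinematics(tr, arena_spec())

  rot <- function(x, y, a) list(x = x * cos(a) - y * sin(a),
                                x2 = x * sin(a) + y * cos(a))
  a <- 37 * pi / 180
  tr_r <- tr
  for (p in c("head", "mid", "tail")) {
    xs <- tr[[paste0(p, "_x_mm")]]; ys <- tr[[paste0(p, "_y_mm")]]
    tr_r[[paste0(p, "_x_mm")]] <- xs * cos(a) - ys * sin(a)
    tr_r[[paste0(p, "_y_mm")]] <- xs * sin(a) + ys * cos(a)
  }
  src <- c(45 * cos(a), 45 * sin(a))
  kin_r <- derive_kinematics(tr_r, arena_spec(odor_source_xy_mm = src))
  for (col in c("bearing_deg", "head_angle_deg", "distance_mm", "speed_mm_s"))
    expect_equal(kin_r[[col]], kin[[col]], tolerance = 1e-9)

  # mirror about the odor axis (y -> -y): bearings and head angles negate
  tr_m <- tr
  for (p in c("head", "mid", "tail"))
    tr_m[[paste0(p, "_y_mm")]] <- -tr[[paste0(p, "_y_mm")]]
  kin_m <- derive_kinematics(tr_m, arena_spec())
  expect_equal(kin_m$bearing_deg, -kin$bearing_deg, tolerance = 1e-9)
  expect_equal(kin_m$head_angle_deg, -kin$head_angle_deg, tolerance = 1e-9)
  expect_equal(kin_m$distance_mm, kin$distance_mm, tolerance = 1e-9)
})

test_that("track files round-trip and split at gaps", {
  tr <- traj_from_angles(rep(0, 6))
  ds <- larva_dataset(list(tr), arena_spec())
  f <- tempfile(fileext = ".tsv")
  write_tracks(ds, f)
  ds2 <- read_tracks(f)
  expect_length(ds2$trajectories, 1)
  expect_equal(as.data.frame(ds2$trajectories[[1]]), as.data.frame(tr),
               tolerance = 1e-9, ignore_attr = TRUE)

  # a 2 s tracking gap splits the track into 2 fragments
  tr_gap <- tr
  tr_gap$t_s[4:6] <- tr_gap$t_s[4:6] + 2
  write_tracks(larva_dataset(list(tr_gap), arena_spec()), f)
  ds3 <- read_tracks(f)
  expect_length(ds3$trajectories, 2)
  expect_equal(vapply(ds3$trajectories, nrow, 0L), c(3L, 3L))

  # malformed header names the missing column; empty file errors
  bad <- utils::read.delim(f)
  bad$tail_x_mm <- NULL
  f2 <- tempfile(fileext = ".tsv")
  utils::write.table(bad, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_tracks(f2), "tail_x_mm")
  writeLines(paste(larvatax:::TRACK_COLUMNS, collapse = "\t"), f2)
  expect_error(read_tracks(f2), "empty")
})

test_that("rows with missing coordinates are dropped and re-interpolated", {
  tr <- traj_from_angles(rep(0, 5))
  f <- tempfile(fileext = ".tsv")
  write_tracks(larva_dataset(list(tr), arena_spec()), f)
  df <- utils::read.delim(f)
  df$head_x_mm[2] <- NA
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(ds <- read_tracks(f), "1 row")
  got <- ds$trajectories[[1]]
  # the one-frame hole is inside the gap tolerance: the track is not
  # split, and resampling onto the frame grid fills it by interpolation
  expect_equal(nrow(got), 5L)
  expect_equal(got$head_x_mm[2], mean(df$head_x_mm[c(1, 3)]))
})

test_that("arena invariants are enforced", {
  expect_error(arena_spec(odor_source_xy_mm = c(80, 0)), "inside")
  expect_error(arena_spec(tracking_cutoff_radius_mm = 80), "cutoff")
  f <- tempfile(fileext = ".yaml")
  write_arena(arena_spec(radius_mm = 60, tracking_cutoff_radius_mm = 50,
                         odor_source_xy_mm = c(30, 0)), f)
  a <- read_arena(f)
  expect_equal(a$radius_mm, 60)
  expect_equal(a$odor_source_xy_mm, c(30, 0))
})
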