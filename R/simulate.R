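#' Simulation configuration for the two-state Markov model
#'
#' Defaults reproduce the study conditions: 16 Hz time step, two 2.15 mm
#' body segments (grand-average larva of 4.3 mm), head angular speed
#' 53.7 deg/s during turns, run-state angular noise uniform on
#' [-1.8, +1.8] degrees per step, 13 animals per 5-minute trial in a
#' 150 mm diameter arena, 1000 trials per condition, turning-angle
#' subsampling windows of +/-30 degrees and +/-15 mm, randomized-direction
#' distances drawn from [0, 100] mm, and track fragmentation that drops
#' frames beyond 67 mm from the center or within 5 mm of another larva.
#'
#' @param dt_s simulation time step (s).
#' @param segment_length_mm length of each body segment.
#' @param head_angular_speed_deg_s angular speed of the head segment while
#'   turning.
#' @param angular_noise_halfwidth_deg halfwidth of the uniform per-step
#'   heading noise during runs.
#' @param arena an [arena_spec()].
#' @param n_animals larvae per trial.
#' @param trial_duration_s trial length (s).
#' @param n_trials default number of trials per experiment.
#' @param mode one of `"realistic_rate+realistic_dir"`,
#'   `"random_rate+realistic_dir"`, `"realistic_rate+random_dir"`,
#'   `"random_rate+random_dir"`.
#' @param bearing_window_deg,distance_window_mm turning-angle subsample
#'   windows.
#' @param random_dir_distance_range distance range substituted in the
#'   randomized-direction modes.
#' @param collision_cull_mm,boundary_cull_mm fragmentation thresholds.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(dt_s = 0.0625,
                              segment_length_mm = 2.15,
                              head_angular_speed_deg_s = 53.7,
                              angular_noise_halfwidth_deg = 1.8,
                              arena = arena_spec(),
                              n_animals = 13,
                              trial_duration_s = 300,
                              n_trials = 1000,
                              mode = "realistic_rate+realistic_dir",
                              bearing_window_deg = 30,
                              distance_window_mm = 15,
                              random_dir_distance_range = c(0, 100),
                              collision_cull_mm = 5,
                              boundary_cull_mm = 67) {
  mode <- match.arg(mode, sim_modes())
  stopifnot(dt_s > 0, segment_length_mm > 0, head_angular_speed_deg_s > 0,
            angular_noise_halfwidth_deg >= 0, inherits(arena, "arena_spec"),
            n_animals >= 1, trial_duration_s > 0, n_trials >= 1,
            bearing_window_deg > 0, distance_window_mm > 0,
            collision_cull_mm >= 0, boundary_cull_mm > 0)
  structure(list(dt_s = dt_s, segment_length_mm = segment_length_mm,
                 head_angular_speed_deg_s = head_angular_speed_deg_s,
                 angular_noise_halfwidth_deg = angular_noise_halfwidth_deg,
                 arena = arena, n_animals = n_animals,
                 trial_duration_s = trial_duration_s, n_trials = n_trials,
                 mode = mode, bearing_window_deg = bearing_window_deg,
                 distance_window_mm = distance_window_mm,
                 random_dir_distance_range = random_dir_distance_range,
                 collision_cull_mm = collision_cull_mm,
                 boundary_cull_mm = boundary_cull_mm),
            class = "simulation_config")
}

sim_modes <- function() {
  c("realistic_rate+realistic_dir", "random_rate+realistic_dir",
    "realistic_rate+random_dir", "random_rate+random_dir")
}

mode_flags <- function(mode) {
  list(random_rate = grepl("^random_rate", mode),
       random_dir = grepl("random_dir$", mode))
}

# deterministic, order-independent child-seed derivation (counter scheme);
# values stay below 2^31 - 1
child_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + as.double(i) * 16807 + 1) %%
               2147483646) + 1L
}

#' Simulate one trial of model larvae
#'
#' Runs `cfg$n_animals` independent model larvae for
#' `cfg$trial_duration_s` seconds. Initial midpoints are uniform in the
#' starting zone (or drawn with replacement from `start_positions`);
#' initial headings are uniform in (-180, 180]. All randomness goes
#' through R's RNG, so a prior `set.seed()` (or the `seed` argument)
#' makes the trial reproducible.
#'
#' @param policy a [behavioral_policy()].
#' @param cfg a [simulation_config()].
#' @param seed optional integer seed.
#' @param mode simulation mode, defaulting to `cfg$mode`.
#' @param start_positions optional matrix/data frame of empirical start
#'   midpoints (columns x, y in mm).
#' @return object of class `chemotaxis_trial`: list with `tracks` (one
#'   (n_frames x 8) matrix per larva: t, head x/y, mid x/y, tail x/y,
#'   state), `events` (turn log with initiation bearing/distance and
#'   drawn/realized angles), `fallback_counts`, `n_rate_clipped`, `cfg`,
#'   `mode`.
#' @export
simulate_trial <- function(policy, cfg = simulation_config(), seed = NULL,
                           mode = cfg$mode, start_positions = NULL) {
  stopifnot(inherits(policy, "behavioral_policy"),
            inherits(cfg, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  mode <- match.arg(mode, sim_modes())
  fl <- mode_flags(mode)
  n <- cfg$n_animals
  if (is.null(start_positions)) {
    sm <- cbind(stats::runif(n, -cfg$arena$start_zone_depth_mm / 2,
                             cfg$arena$start_zone_depth_mm / 2),
                stats::runif(n, -cfg$arena$start_zone_width_mm / 2,
                             cfg$arena$start_zone_width_mm / 2))
  } else {
    start_positions <- as.matrix(start_positions)[, 1:2, drop = FALSE]
    sm <- start_positions[sample.int(nrow(start_positions), n,
                                     replace = TRUE), , drop = FALSE]
  }
  headings <- stats::runif(n, -180, 180)
  n_steps <- round(cfg$trial_duration_s / cfg$dt_s)

  par <- policy$kind == "parametric"
  res <- .sim_larvae(
    n_steps, cfg$dt_s, cfg$segment_length_mm, policy$run_speed_mm_s,
    cfg$head_angular_speed_deg_s, cfg$angular_noise_halfwidth_deg,
    cfg$arena$radius_mm, sm, headings,
    cfg$arena$odor_source_xy_mm[1], cfg$arena$odor_source_xy_mm[2],
    if (par) 0L else 1L,
    if (par) policy$base_rate_per_s else 0,
    if (par) policy$amplitude else 0,
    if (par) policy$distance_gain_slope else 0,
    if (par) policy$distance_ref_mm else 45,
    if (par) numeric(0) else policy$rate_map$bearing_grid_deg,
    if (par) numeric(0) else policy$rate_map$distance_grid_mm,
    if (par) matrix(0, 1, 1) else policy$rate_map$rate_per_min / 60,
    policy$mean_rate_per_s,
    policy$bank$bearing_before_deg, policy$bank$distance_mm,
    policy$bank$turning_angle_deg,
    fl$random_rate, fl$random_dir,
    cfg$bearing_window_deg, cfg$distance_window_mm,
    cfg$random_dir_distance_range[1], cfg$random_dir_distance_range[2])

  structure(list(tracks = res$tracks, events = res$events,
                 fallback_counts = res$fallback_counts,
                 n_rate_clipped = res$n_rate_clipped,
                 cfg = cfg, mode = mode),
            class = "chemotaxis_trial")
}

#' Convert a simulated trial to a tracking dataset
#'
#' Re-expresses a trial in the track-TSV-compatible trajectory container
#' so simulated data flow through the same analysis as experimental
#' tracks.
#'
#' @param trial a `chemotaxis_trial`.
#' @param dish_id dish label for the trial.
#' @return a [larva_dataset()].
#' @export
trial_to_dataset <- function(trial, dish_id = "sim1") {
  trajectories <- lapply(seq_along(trial$tracks), function(a) {
    M <- trial$tracks[[a]]
    new_trajectory(data.frame(t_s = M[, 1],
                              head_x_mm = M[, 2], head_y_mm = M[, 3],
                              mid_x_mm = M[, 4], mid_y_mm = M[, 5],
                              tail_x_mm = M[, 6], tail_y_mm = M[, 7]),
                   dish_id, paste0("model", a), trial$cfg$dt_s)
  })
  larva_dataset(trajectories, trial$cfg$arena,
                group_label = paste0("simulated:", trial$mode))
}

# per-larva logical keep masks implementing the fragmentation criteria
fragment_mask <- function(trial, cfg = trial$cfg) {
  tracks <- trial$tracks
  n <- length(tracks)
  nf <- nrow(tracks[[1]])
  mx <- vapply(tracks, function(M) M[, 4], numeric(nf))
  my <- vapply(tracks, function(M) M[, 5], numeric(nf))
  keep <- mx^2 + my^2 <= cfg$boundary_cull_mm^2
  if (n > 1 && cfg$collision_cull_mm > 0) {
    lim2 <- cfg$collision_cull_mm^2
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      close_ <- (mx[, i] - mx[, j])^2 + (my[, i] - my[, j])^2 < lim2
      keep[close_, i] <- FALSE
      keep[close_, j] <- FALSE
    }
  }
  keep
}

#' Fragment simulated tracks like the experimental data
#'
#' Discards every frame at which a larva's midpoint is farther than
#' `boundary_cull_mm` from the arena center, or within `collision_cull_mm`
#' of another larva's midpoint (unresolved tracking during collisions).
#' Surviving contiguous episodes become independent trajectory fragments.
#'
#' @param trial a `chemotaxis_trial` from [simulate_trial()].
#' @param cfg fragmentation settings (defaults to the trial's config).
#' @param dish_id dish label.
#' @return a [larva_dataset()] of fragments (errors if nothing survives).
#' @export
fragment_tracks <- function(trial, cfg = trial$cfg, dish_id = "sim1") {
  keep <- fragment_mask(trial, cfg)
  trajectories <- list()
  for (a in seq_along(trial$tracks)) {
    M <- trial$tracks[[a]]
    r <- rle(keep[, a])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    frag <- 0L
    for (k in seq_along(r$values)) {
      if (!r$values[k] || r$lengths[k] < 2L) next
      frag <- frag + 1L
      idx <- starts[k]:ends[k]
      trajectories[[length(trajectories) + 1L]] <- new_trajectory(
        data.frame(t_s = M[idx, 1],
                   head_x_mm = M[idx, 2], head_y_mm = M[idx, 3],
                   mid_x_mm = M[idx, 4], mid_y_mm = M[idx, 5],
                   tail_x_mm = M[idx, 6], tail_y_mm = M[idx, 7]),
        dish_id, sprintf("model%d#%d", a, frag), trial$cfg$dt_s)
    }
  }
  if (!length(trajectories))
    stop("fragmentation discarded all simulated frames")
  larva_dataset(trajectories, trial$cfg$arena,
                group_label = paste0("simulated:", trial$mode))
}

#' Simulate an experiment: many trials, one preference score each
#'
#' Runs `n_trials` independent trials (child seeds derived from the
#' master seed by a deterministic counter scheme, so trials are
#' reproducible and order-independent), fragments each trial's tracks as
#' in the experimental pipeline, and summarizes each trial by its filmed
#' preference score.
#'
#' @param policy a [behavioral_policy()].
#' @param cfg a [simulation_config()].
#' @param n_trials number of trials (default `cfg$n_trials`).
#' @param seed master seed (required).
#' @param mode simulation mode (default `cfg$mode`).
#' @param start_positions optional empirical start positions.
#' @return object of class `chemotaxis_simulation`: `pref` (per-trial
#'   scores), `median_pref`, `quantiles`, `mode`, `n_trials`,
#'   `fallback_counts`, `n_rate_clipped`.
#' @export
simulate_experiment <- function(policy, cfg = simulation_config(),
                                n_trials = cfg$n_trials, seed,
                                mode = cfg$mode, start_positions = NULL) {
  stopifnot(!missing(seed))
  prefs <- numeric(n_trials)
  fallback <- integer(4)
  clipped <- 0L
  for (i in seq_len(n_trials)) {
    trial <- simulate_trial(policy, cfg, seed = child_seed(seed, i),
                            mode = mode, start_positions = start_positions)
    keep <- fragment_mask(trial, cfg)
    mx <- vapply(trial$tracks, function(M) M[, 4],
                 numeric(nrow(trial$tracks[[1]])))
    x <- mx[keep]
    prefs[i] <- if (length(x)) pref_from_x(x) else NA_real_
    fallback <- fallback + trial$fallback_counts
    clipped <- clipped + trial$n_rate_clipped
  }
  structure(list(pref = prefs,
                 median_pref = stats::median(prefs, na.rm = TRUE),
                 quantiles = stats::quantile(prefs, c(.05, .25, .5, .75, .95),
                                             na.rm = TRUE),
                 mode = mode, n_trials = n_trials,
                 fallback_counts = fallback, n_rate_clipped = clipped,
                 seed = seed),
            class = "chemotaxis_simulation")
}

#' @export
print.chemotaxis_simulation <- function(x, ...) {
  cat(sprintf("Simulated chemotaxis experiment (%s)\n", x$mode))
  cat(sprintf("  %d trials; median filmed preference %.3f\n",
              x$n_trials, x$median_pref))
  q <- x$quantiles
  cat(sprintf("  quartiles [%.3f, %.3f]; 90%% interval [%.3f, %.3f]\n",
              q[["25%"]], q[["75%"]], q[["5%"]], q[["95%"]]))
  if (x$n_rate_clipped > 0)
    cat(sprintf("  note: %d rate*dt values clipped to 1\n", x$n_rate_clipped))
  invisible(x)
}

#' Simulate method for behavioral policies
#'
#' `simulate()` on a policy runs [simulate_experiment()]; `nsim` is the
#' number of trials.
#'
#' @param object a [behavioral_policy()].
#' @param nsim number of trials.
#' @param seed master seed (required).
#' @param cfg a [simulation_config()].
#' @param mode simulation mode.
#' @param ... passed to [simulate_experiment()].
#' @return a `chemotaxis_simulation`.
#' @export
simulate.behavioral_policy <- function(object, nsim = 100, seed = NULL,
                                       cfg = simulation_config(),
                                       mode = cfg$mode, ...) {
  if (is.null(seed)) stop("an explicit seed is required")
  simulate_experiment(object, cfg, n_trials = nsim, seed = seed,
                      mode = mode, ...)
}
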