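#' Fit the chemotaxis behavioral description to a tracking dataset
#'
#' The central estimator of the package. For every trajectory it derives
#' the kinematic series, detects turns (Schmitt trigger on reorientation
#' speed, posture gate, 20-degree orientation-change cutoff), head casts
#' and runs, then computes the per-dish measures (filmed preference, run
#' speed, overall turn rate, toward/away turn rates, proportion of turns
#' toward the odor) and the pooled bearing- and distance-resolved
#' profiles and maps. The fitted object carries everything needed to
#' build a [behavioral_policy()] and drive the Markov simulator.
#'
#' Per-dish quantities use each dish's own events and tracked time
#' (N = dishes); profiles and maps pool the data from all dishes.
#'
#' @param dataset a [larva_dataset()].
#' @param turn_cfg a [turn_config()].
#' @param cast_cfg a [schmitt_config()] for head casts (default high 20,
#'   low 10 degrees).
#' @param maps compute the 2D maps as well (default TRUE; profiles are
#'   always computed).
#' @return object of class `chemotaxis_fit` with components `per_dish`,
#'   `turns`, `casts`, `runs`, `frames`, `rate_profile`, `angle_profile`,
#'   `rate_map`, `angle_map`, `toward_map`, `arena`, `config`.
#' @seealso [build_policy()], [recover_policy_parameters()],
#'   [simulate.chemotaxis_fit()]
#' @export
fit_chemotaxis <- function(dataset, turn_cfg = turn_config(),
                           cast_cfg = schmitt_config(20, 10, 0),
                           maps = TRUE) {
  stopifnot(inherits(dataset, "larva_dataset"))
  turns <- list(); casts <- list(); runs <- list(); frames <- list()
  for (tr in dataset$trajectories) {
    kin <- derive_kinematics(tr, dataset$arena)
    tu <- detect_turns(kin, turn_cfg)
    ca <- detect_head_casts(kin, tu, cast_cfg)
    ru <- segment_runs(tu, ca, kin)
    lab <- function(df) {
      if (nrow(df)) {
        df$dish_id <- attr(kin, "dish_id")
        df$animal_id <- attr(kin, "animal_id")
      }
      df
    }
    turns[[length(turns) + 1L]] <- lab(tu)
    casts[[length(casts) + 1L]] <- lab(ca)
    runs[[length(runs) + 1L]] <- lab(ru)
    frames[[length(frames) + 1L]] <- data.frame(
      dish_id = attr(kin, "dish_id"), t_s = kin$t_s,
      bearing_deg = kin$bearing_deg, distance_mm = kin$distance_mm,
      speed_mm_s = kin$speed_mm_s, mid_x_mm = kin$mid_x_mm,
      mid_y_mm = kin$mid_y_mm)
  }
  bind <- function(l) if (any(vapply(l, nrow, 0L) > 0)) do.call(rbind, l) else l[[1L]]
  turns <- bind(turns); casts <- bind(casts); runs <- bind(runs)
  frames <- do.call(rbind, frames)
  dt <- attr(dataset$trajectories[[1L]], "frame_dt_s")

  dishes <- sort(unique(frames$dish_id))
  per_dish <- do.call(rbind, lapply(dishes, function(d) {
    fr <- frames[frames$dish_id == d, ]
    tu <- if (nrow(turns)) turns[turns$dish_id == d, ] else turns
    ru <- if (nrow(runs)) runs[runs$dish_id == d, ] else runs
    tt <- nrow(fr) * dt
    ta <- turn_rate_toward_away(tu$bearing_before_deg, fr$bearing_deg, dt)
    data.frame(dish_id = d,
               pref_filmed = pref_from_x(fr$mid_x_mm),
               run_speed_mm_s = if (nrow(ru)) run_speed(ru) else NA_real_,
               turn_rate_per_min = 60 * nrow(tu) / tt,
               rate_toward_per_min = ta[["toward"]],
               rate_away_per_min = ta[["away"]],
               prop_toward = if (nrow(tu)) proportion_toward(tu) else NA_real_,
               n_turns = nrow(tu), tracked_time_s = tt)
  }))

  rate_profile <- turn_rate_profile(turns$bearing_before_deg,
                                    frames$bearing_deg, dt)
  angle_profile <- turning_angle_profile(turns$bearing_before_deg,
                                         turns$turning_angle_deg)
  rate_map <- angle_map <- toward_map <- NULL
  if (maps) {
    rate_map <- turn_rate_map(turns$bearing_before_deg, turns$distance_mm,
                              frames$bearing_deg, frames$distance_mm, dt)
    angle_map <- turning_angle_map(turns$bearing_before_deg,
                                   turns$distance_mm,
                                   turns$turning_angle_deg)
    toward_map <- proportion_toward_map(turns$t_start, turns$distance_mm,
                                        turns$toward_odor)
  }
  structure(list(per_dish = per_dish, turns = turns, casts = casts,
                 runs = runs, frames = frames,
                 rate_profile = rate_profile, angle_profile = angle_profile,
                 rate_map = rate_map, angle_map = angle_map,
                 toward_map = toward_map,
                 arena = dataset$arena, group_label = dataset$group_label,
                 frame_dt_s = dt,
                 config = list(turn = turn_cfg, cast = cast_cfg)),
            class = "chemotaxis_fit")
}

#' @export
print.chemotaxis_fit <- function(x, ...) {
  cat("Chemotaxis fit")
  if (nzchar(x$group_label)) cat(" [", x$group_label, "]", sep = "")
  cat("\n")
  cat(sprintf("  %d dish(es), %d turns, %d head casts, %d runs, %.0f s tracked\n",
              nrow(x$per_dish), nrow(x$turns), nrow(x$casts), nrow(x$runs),
              sum(x$per_dish$tracked_time_s)))
  cat(sprintf("  median filmed preference %.3f; median run speed %.2f mm/s\n",
              stats::median(x$per_dish$pref_filmed),
              stats::median(x$per_dish$run_speed_mm_s, na.rm = TRUE)))
  cat(sprintf("  overall turn rate %.2f/min (toward %.2f, away %.2f)\n",
              overall_turn_rate(sum(x$per_dish$n_turns),
                                sum(x$per_dish$tracked_time_s)),
              stats::median(x$per_dish$rate_toward_per_min, na.rm = TRUE),
              stats::median(x$per_dish$rate_away_per_min, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.chemotaxis_fit <- function(object, ...) {
  out <- list(per_dish = object$per_dish, coef = coef(object),
              group_label = object$group_label)
  class(out) <- "summary.chemotaxis_fit"
  out
}

#' @export
print.summary.chemotaxis_fit <- function(x, ...) {
  cat("Per-dish measures:\n")
  print(x$per_dish, row.names = FALSE, digits = 3)
  cat("\nPooled / median coefficients:\n")
  print(round(x$coef, 3))
  invisible(x)
}

#' @export
coef.chemotaxis_fit <- function(object, ...) {
  pd <- object$per_dish
  c(pref_filmed = stats::median(pd$pref_filmed),
    run_speed_mm_s = stats::median(pd$run_speed_mm_s, na.rm = TRUE),
    turn_rate_per_min = overall_turn_rate(sum(pd$n_turns),
                                          sum(pd$tracked_time_s)),
    rate_toward_per_min = stats::median(pd$rate_toward_per_min, na.rm = TRUE),
    rate_away_per_min = stats::median(pd$rate_away_per_min, na.rm = TRUE),
    prop_toward = stats::median(pd$prop_toward, na.rm = TRUE))
}

#' Predict the pooled turn rate at given bearings
#'
#' Linear interpolation of the fitted bearing-resolved turn-rate profile.
#'
#' @param object a `chemotaxis_fit`.
#' @param bearing_deg bearings in degrees (wrapped into (-180, 180]).
#' @param ... unused.
#' @return turn rates in turns/min.
#' @export
predict.chemotaxis_fit <- function(object, bearing_deg = seq(-180, 180), ...) {
  pr <- object$rate_profile
  stats::approx(pr$bearing_deg, pr$rate_per_min,
                xout = wrap_angle(bearing_deg), rule = 2)$y
}

#' @export
plot.chemotaxis_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  pr <- x$rate_profile
  graphics::plot(pr$bearing_deg, pr$rate_per_min, type = "l",
                 xlab = "bearing (deg)", ylab = "turn rate (1/min)",
                 main = "Turn rate vs bearing")
  graphics::abline(v = 0, lty = 3)
  ap <- x$angle_profile
  graphics::plot(ap$bearing_deg, ap$mean_angle_deg, type = "l",
                 xlab = "bearing (deg)", ylab = "mean turning angle (deg)",
                 main = "Turning angle vs bearing")
  graphics::abline(h = 0, v = 0, lty = 3)
  graphics::boxplot(x$per_dish$pref_filmed, ylab = "filmed preference",
                    main = "Preference per dish", ylim = c(-1, 1))
  graphics::abline(h = 0, lty = 3)
  graphics::hist(x$turns$turning_angle_deg, breaks = 30,
                 xlab = "turning angle (deg)", main = "Turning angles")
  invisible(x)
}

#' Simulate from a fitted chemotaxis model
#'
#' Builds the empirical behavioral policy from the fit and runs the
#' two-state Markov simulator.
#'
#' @param object a `chemotaxis_fit`.
#' @param nsim number of trials.
#' @param seed master seed (required).
#' @param cfg a [simulation_config()].
#' @param mode simulation mode.
#' @param ... passed to [simulate_experiment()].
#' @return a `chemotaxis_simulation`.
#' @export
simulate.chemotaxis_fit <- function(object, nsim = 100, seed = NULL,
                                    cfg = simulation_config(),
                                    mode = cfg$mode, ...) {
  if (is.null(seed)) stop("an explicit seed is required")
  simulate_experiment(build_policy(object), cfg, n_trials = nsim,
                      seed = seed, mode = mode, ...)
}

# attenuation of a cosine under the +/-30 degree boxcar filter
BOXCAR_COS_GAIN <- sin(pi / 6) / (pi / 6)

#' Recover parametric policy parameters from a fit
#'
#' Estimates the low-dimensional policy parameters from the fitted
#' pooled statistics: the rate-modulation amplitude `a` by least-squares
#' fit of `base * (1 - a cos(bearing))` to the bearing-resolved rate
#' profile (correcting the amplitude for the known attenuation of a
#' cosine under the +/-30 degree sliding filter), the toward-bias `p` as
#' the fraction of turns whose direction sign points toward the source
#' (sign of the turning angle equal to the sign of the pre-turn
#' bearing), and the toward/away rate ratio as the mean profile rate
#' over |bearing| < 90 divided by the mean over |bearing| > 90 (this
#' ratio is occupancy-independent because each profile point is already
#' a rate).
#'
#' @param fit a `chemotaxis_fit`.
#' @return list: `base_rate_per_min`, `amplitude`, `toward_bias`,
#'   `rate_ratio_toward_away`, `n_turns`.
#' @export
recover_policy_parameters <- function(fit) {
  pr <- fit$rate_profile
  sel <- pr$bearing_deg > -180 & !pr$undefined  # drop duplicated wrap point
  cb <- cos(pr$bearing_deg[sel] * pi / 180)
  co <- stats::coef(stats::lm(pr$rate_per_min[sel] ~ cb))
  base <- unname(co[1])
  amp <- unname(-co[2]) / base / BOXCAR_COS_GAIN
  tw <- abs(pr$bearing_deg) < 90 & !pr$undefined
  aw <- abs(pr$bearing_deg) > 90 & !pr$undefined
  ratio <- mean(pr$rate_per_min[tw]) / mean(pr$rate_per_min[aw])
  tu <- fit$turns
  ok <- tu$bearing_before_deg != 0
  p_hat <- mean(sign(tu$turning_angle_deg[ok]) ==
                sign(tu$bearing_before_deg[ok]))
  list(base_rate_per_min = base, amplitude = amp, toward_bias = p_hat,
       rate_ratio_toward_away = ratio, n_turns = nrow(tu))
}
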