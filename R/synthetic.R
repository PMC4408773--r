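#' Parametric policy family with closed-form ground truth
#'
#' A deliberately low-dimensional behavioral policy for validation: the
#' turn rate is `base * (1 - a * cos(bearing))` (a > 0 lowers the rate
#' when heading toward the source, the modulation seen in real larvae),
#' optionally scaled linearly with distance; the turning direction points
#' toward the source with probability `p` (0.5 = unbiased); turning-angle
#' magnitudes are uniform on a range. Every expectation of this family
#' has a brute-force oracle (see [ground_truth_summary()]).
#'
#' @param base_rate_per_min baseline turn rate, turns/min (default 2).
#' @param amplitude rate-modulation amplitude `a` in `[0, 1)`.
#' @param toward_bias probability `p` that a turn is directed toward the
#'   source.
#' @param distance_gain_slope optional linear distance modulation (0 =
#'   none).
#' @param turn_magnitude_range range of |turning angle| in degrees
#'   (default 25 to 120; all above the 20-degree scoring cutoff).
#' @param run_speed_mm_s run speed (default 1).
#' @param noise_halfwidth_deg per-step heading noise halfwidth used when
#'   this spec drives the Markov simulator (default 1.8).
#' @return object of class `parametric_policy_spec`.
#' @export
parametric_policy_spec <- function(base_rate_per_min = 2,
                                   amplitude = 0,
                                   toward_bias = 0.5,
                                   distance_gain_slope = 0,
                                   turn_magnitude_range = c(25, 120),
                                   run_speed_mm_s = 1,
                                   noise_halfwidth_deg = 1.8) {
  stopifnot(base_rate_per_min > 0, amplitude >= 0, amplitude < 1,
            toward_bias >= 0, toward_bias <= 1,
            length(turn_magnitude_range) == 2L,
            turn_magnitude_range[1] > 20,
            diff(turn_magnitude_range) >= 0,
            run_speed_mm_s > 0, noise_halfwidth_deg >= 0)
  structure(list(base_rate_per_min = base_rate_per_min,
                 amplitude = amplitude, toward_bias = toward_bias,
                 distance_gain_slope = distance_gain_slope,
                 turn_magnitude_range = turn_magnitude_range,
                 run_speed_mm_s = run_speed_mm_s,
                 noise_halfwidth_deg = noise_halfwidth_deg),
            class = "parametric_policy_spec")
}

# draw a turn direction sign toward the source with probability p
draw_turn_sign <- function(bearing_deg, p) {
  toward <- sign(bearing_deg)
  if (toward == 0) toward <- sample(c(-1, 1), 1L)
  if (stats::runif(1) < p) toward else -toward
}

#' Materialize a parametric spec as a behavioral policy
#'
#' Builds a [behavioral_policy()] whose rate lookup evaluates the closed
#' form and whose angle bank contains `bank_size` synthetic events:
#' bearings uniform on (-180, 180], distances uniform over the
#' arena-reachable range, magnitudes uniform on the spec's range, and
#' direction signs pointing toward the source with probability
#' `toward_bias`.
#'
#' @param spec a [parametric_policy_spec()].
#' @param bank_size number of bank events (default 4000).
#' @param seed integer seed.
#' @param distance_range_mm range of bank distances (default c(5, 67)).
#' @return a [behavioral_policy()] of kind `"parametric"`.
#' @export
make_parametric_policy <- function(spec, bank_size = 4000, seed = 1,
                                   distance_range_mm = c(5, 67)) {
  stopifnot(inherits(spec, "parametric_policy_spec"), bank_size >= 1)
  set.seed(seed)
  bearing <- stats::runif(bank_size, -180, 180)
  dist <- stats::runif(bank_size, distance_range_mm[1], distance_range_mm[2])
  mag <- stats::runif(bank_size, spec$turn_magnitude_range[1],
                      spec$turn_magnitude_range[2])
  sgn <- vapply(bearing, draw_turn_sign, 0, p = spec$toward_bias)
  behavioral_policy("parametric",
                    bank = data.frame(bearing_before_deg = bearing,
                                      distance_mm = dist,
                                      turning_angle_deg = sgn * mag),
                    mean_rate_per_s = spec$base_rate_per_min / 60,
                    run_speed_mm_s = spec$run_speed_mm_s,
                    base_rate_per_s = spec$base_rate_per_min / 60,
                    amplitude = spec$amplitude,
                    distance_gain_slope = spec$distance_gain_slope)
}

#' Ground-truth expectations for a parametric policy
#'
#' Expectations computed by numeric integration over bearing (uniform
#' bearing occupancy), independent of any simulation: the toward/away
#' turn-rate ratio (rate averaged over |bearing| < 90 vs > 90; the
#' closed form is (1 - 2a/pi)/(1 + 2a/pi); real trajectories occupy
#' bearings non-uniformly, which this oracle deliberately ignores), the
#' expected proportion of turn signs pointing toward the source (= p),
#' and the rate-modulation amplitude itself.
#'
#' @param spec a [parametric_policy_spec()].
#' @return list of class `ground_truth`: `amplitude`, `toward_bias`,
#'   `rate_ratio_toward_away`, `base_rate_per_min`.
#' @export
ground_truth_summary <- function(spec) {
  stopifnot(inherits(spec, "parametric_policy_spec"))
  rate <- function(b) 1 - spec$amplitude * cos(b)
  toward <- stats::integrate(rate, -pi / 2, pi / 2)$value / pi
  away <- (stats::integrate(rate, pi / 2, pi)$value +
           stats::integrate(rate, -pi, -pi / 2)$value) / pi
  structure(list(amplitude = spec$amplitude,
                 toward_bias = spec$toward_bias,
                 rate_ratio_toward_away = toward / away,
                 base_rate_per_min = spec$base_rate_per_min),
            class = "ground_truth")
}

#' Generate a synthetic tracking dataset with known ground truth
#'
#' Synthesizes track-TSV-compatible trajectories from a parametric policy
#' together with a sidecar list of the true turn events, enabling
#' detector sensitivity/precision scoring and full parameter-recovery
#' loops. Unlike the Markov simulator (whose body axis snaps at turn
#' completion, as in the minimal model), the generator reorients the
#' body smoothly at `body_turn_speed_deg_s` with a head-angle excursion
#' leading the turn, so events are physically detectable; runs are
#' straight lines, which keeps every expectation in closed form.
#' Optional positional jitter and sub-threshold head-cast "distractor"
#' wiggles (10-15 degree oscillations, below the 20-degree posture gate
#' and orientation cutoff) stress the detector.
#'
#' Larvae reaching the arena margin make a forced turn back inside.
#' As with the real tracker, frames beyond the arena's tracking cutoff
#' radius (67 mm) are not recorded: tracks are split into fragments at
#' cutoff crossings and events outside the cutoff (including all forced
#' wall turns, flagged `boundary`) are excluded from the scored truth --
#' they are unobservable in the emulated data. Set
#' `apply_tracking_cutoff = FALSE` to keep everything.
#'
#' @param spec a [parametric_policy_spec()].
#' @param n_dishes,n_larvae,duration_s dataset size (defaults 1 dish of
#'   13 larvae, 300 s).
#' @param seed integer seed; the same seed reproduces the dataset
#'   exactly.
#' @param arena an [arena_spec()].
#' @param dt_s frame interval (default 1/16 s).
#' @param body_turn_speed_deg_s body angular speed during turns (default
#'   80).
#' @param jitter_mm s.d. of Gaussian positional jitter added to every
#'   coordinate (default 0).
#' @param distractor_wiggles implant sub-threshold head oscillations
#'   during runs.
#' @param wiggle_amp_range_deg,wiggle_freq_hz distractor amplitude range
#'   and frequency.
#' @param apply_tracking_cutoff emulate the tracker's arena mask
#'   (default TRUE).
#' @return list of class `synthetic_dataset`: `dataset` (a
#'   [larva_dataset()]), `truth` (true turn events: dish, animal,
#'   t_start, t_end, turning angle, pre-turn bearing and distance,
#'   boundary flag), `spec`, `ground_truth`.
#' @export
generate_dataset <- function(spec, n_dishes = 1, n_larvae = 13,
                             duration_s = 300, seed = 1,
                             arena = arena_spec(), dt_s = 0.0625,
                             body_turn_speed_deg_s = 80,
                             jitter_mm = 0, distractor_wiggles = FALSE,
                             wiggle_amp_range_deg = c(10, 15),
                             wiggle_freq_hz = 0.4,
                             apply_tracking_cutoff = TRUE) {
  stopifnot(inherits(spec, "parametric_policy_spec"))
  set.seed(seed)
  trajectories <- list()
  truth <- list()
  for (d in seq_len(n_dishes)) {
    dish <- sprintf("dish%02d", d)
    for (a in seq_len(n_larvae)) {
      animal <- sprintf("larva%02d", a)
      syn <- synth_larva(spec, duration_s, arena, dt_s,
                         body_turn_speed_deg_s, jitter_mm,
                         distractor_wiggles, wiggle_amp_range_deg,
                         wiggle_freq_hz)
      ev <- syn$events
      if (apply_tracking_cutoff) {
        pieces <- apply_cutoff(syn$frames, arena$tracking_cutoff_radius_mm)
        for (k in seq_along(pieces)) {
          id <- if (length(pieces) > 1L) paste0(animal, "#", k) else animal
          trajectories[[length(trajectories) + 1L]] <-
            new_trajectory(pieces[[k]], dish, id, dt_s)
        }
        if (nrow(ev))
          ev <- ev[ev$radius_mm <= arena$tracking_cutoff_radius_mm, ,
                   drop = FALSE]
      } else {
        trajectories[[length(trajectories) + 1L]] <-
          new_trajectory(syn$frames, dish, animal, dt_s)
      }
      if (nrow(ev)) {
        ev$dish_id <- dish
        ev$animal_id <- animal
        truth[[length(truth) + 1L]] <- ev
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(t_start = numeric(0), t_end = numeric(0),
               turning_angle_deg = numeric(0), bearing_before_deg = numeric(0),
               distance_mm = numeric(0), radius_mm = numeric(0),
               boundary = logical(0),
               dish_id = character(0), animal_id = character(0))
  structure(list(dataset = larva_dataset(trajectories, arena,
                                         group_label = "synthetic"),
                 truth = truth, spec = spec,
                 ground_truth = ground_truth_summary(spec)),
            class = "synthetic_dataset")
}

# one larva: alternate straight runs (turn times by thinning against the
# bearing-dependent rate) with smooth pivot turns; returns frame table
# and true event list
synth_larva <- function(spec, duration_s, arena, dt_s, omega_body,
                        jitter_mm, wiggles, wamp_range, wfreq) {
  L <- 2.15
  v <- spec$run_speed_mm_s
  sx <- arena$odor_source_xy_mm[1]; sy <- arena$odor_source_xy_mm[2]
  r_margin <- arena$radius_mm - 2 * L  # keep head well inside
  rate_of <- function(bearing, dist) {
    g <- pmax(0, 1 + spec$distance_gain_slope * (dist - 45) / 45)
    pmax(0, spec$base_rate_per_min / 60 *
           (1 - spec$amplitude * cos(bearing * pi / 180)) * g)
  }
  r_max <- spec$base_rate_per_min / 60 * (1 + spec$amplitude) *
    max(1, 1 + spec$distance_gain_slope * (arena$radius_mm - 45) / 45)

  px <- stats::runif(1, -arena$start_zone_depth_mm / 2,
                     arena$start_zone_depth_mm / 2)
  py <- stats::runif(1, -arena$start_zone_width_mm / 2,
                     arena$start_zone_width_mm / 2)
  th <- stats::runif(1, -180, 180)

  segs <- list()   # type, t0, t1, x0, y0, th0, phi
  events <- list()
  t <- 0
  while (t < duration_s) {
    # --- run: straight line until a thinned turn event or the border
    u <- c(cos(th * pi / 180), sin(th * pi / 180))
    bq <- sum(2 * v * u * c(px, py))
    cq <- px^2 + py^2 - r_margin^2
    disc <- bq^2 - 4 * v^2 * cq
    t_border <- if (disc <= 0) Inf else (-bq + sqrt(disc)) / (2 * v^2)
    t_border <- max(t_border, 0)
    t_turn <- Inf
    tc <- 0
    repeat {
      tc <- tc + stats::rexp(1, r_max)
      if (tc >= min(t_border, duration_s - t)) break
      qx <- px + v * tc * u[1]; qy <- py + v * tc * u[2]
      b <- angle_diff(segment_angle(qx, qy, sx, sy), th)
      dist <- sqrt((sx - qx)^2 + (sy - qy)^2)
      if (stats::runif(1) < rate_of(b, dist) / r_max) { t_turn <- tc; break }
    }
    run_end <- min(t_turn, t_border, duration_s - t)
    segs[[length(segs) + 1L]] <- list(type = "run", t0 = t, t1 = t + run_end,
                                      x0 = px, y0 = py, th0 = th, phi = 0)
    px <- px + v * run_end * u[1]; py <- py + v * run_end * u[2]
    t <- t + run_end
    if (t >= duration_s) break

    # --- turn: smooth pivot about the midpoint
    boundary <- !is.finite(t_turn) || t_border <= t_turn
    b0 <- angle_diff(segment_angle(px, py, sx, sy), th)
    dist0 <- sqrt((sx - px)^2 + (sy - py)^2)
    sgn <- draw_turn_sign(b0, spec$toward_bias)
    mag <- stats::runif(1, spec$turn_magnitude_range[1],
                        spec$turn_magnitude_range[2])
    if (boundary) {
      drawn <- boundary_turn(px, py, th, sgn, spec$turn_magnitude_range)
      sgn <- sign(drawn); mag <- abs(drawn)
    }
    phi <- sgn * mag
    t_dur <- abs(phi) / omega_body
    t_dur <- min(t_dur, duration_s - t)
    segs[[length(segs) + 1L]] <- list(type = "turn", t0 = t, t1 = t + t_dur,
                                      x0 = px, y0 = py, th0 = th, phi = phi)
    events[[length(events) + 1L]] <- data.frame(
      t_start = t, t_end = t + t_dur, turning_angle_deg = phi,
      bearing_before_deg = b0, distance_mm = dist0,
      radius_mm = sqrt(px^2 + py^2), boundary = boundary)
    th <- wrap_angle(th + sign(phi) * omega_body * t_dur)
    t <- t + t_dur
  }

  frames <- eval_segments(segs, duration_s, dt_s, L, v, wiggles,
                          wamp_range, wfreq)
  if (jitter_mm > 0) {
    nc <- c("head_x_mm", "head_y_mm", "mid_x_mm", "mid_y_mm",
            "tail_x_mm", "tail_y_mm")
    for (col in nc)
      frames[[col]] <- frames[[col]] + stats::rnorm(nrow(frames), 0, jitter_mm)
  }
  list(frames = frames,
       events = if (length(events)) do.call(rbind, events) else
         data.frame(t_start = numeric(0), t_end = numeric(0),
                    turning_angle_deg = numeric(0),
                    bearing_before_deg = numeric(0),
                    distance_mm = numeric(0), radius_mm = numeric(0),
                    boundary = logical(0)))
}

# emulate the tracker's arena mask: keep only frames with midpoint radius
# inside the cutoff and split the remainder into contiguous fragments
apply_cutoff <- function(frames, cutoff_mm) {
  keep <- frames$mid_x_mm^2 + frames$mid_y_mm^2 <= cutoff_mm^2
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pieces <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < 2L) next
    pieces[[length(pieces) + 1L]] <- frames[starts[k]:ends[k], , drop = FALSE]
  }
  pieces
}

# choose a boundary-turn angle whose new heading points back inside:
# keep the preferred sign if any magnitude achieves it, else flip
boundary_turn <- function(px, py, th, sgn, mag_range) {
  inward <- function(phi) {
    u <- c(cos((th + phi) * pi / 180), sin((th + phi) * pi / 180))
    sum(u * c(px, py)) < 0
  }
  for (s in c(sgn, -sgn)) {
    for (k in seq_len(20)) {
      mag <- stats::runif(1, mag_range[1], mag_range[2])
      if (inward(s * mag)) return(s * mag)
    }
  }
  # point straight back at the center
  angle_diff(segment_angle(px, py, 0, 0), th)
}

# evaluate the piecewise-analytic posture on the uniform frame grid
eval_segments <- function(segs, duration_s, dt_s, L, v, wiggles,
                          wamp_range, wfreq) {
  tt <- seq(0, duration_s, by = dt_s)
  t0s <- vapply(segs, `[[`, 0, "t0")
  idx <- findInterval(tt, t0s, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  th <- numeric(length(tt)); x <- numeric(length(tt)); y <- numeric(length(tt))
  ha <- numeric(length(tt))
  for (k in seq_along(segs)) {
    s <- segs[[k]]
    sel <- idx == k
    if (!any(sel)) next
    rel <- tt[sel] - s$t0
    if (s$type == "run") {
      th[sel] <- s$th0
      x[sel] <- s$x0 + cos(s$th0 * pi / 180) * rel * v
      y[sel] <- s$y0 + sin(s$th0 * pi / 180) * rel * v
      ha[sel] <- 0
    } else {
      prog <- if (s$t1 > s$t0) rel / (s$t1 - s$t0) else 1
      th[sel] <- s$th0 + s$phi * prog
      x[sel] <- s$x0; y[sel] <- s$y0
      peak <- sign(s$phi) * min(abs(s$phi), 60)
      ha[sel] <- peak * sin(pi * pmin(prog, 1))
    }
  }
  if (wiggles) {
    amp <- stats::runif(1, wamp_range[1], wamp_range[2])
    phase <- stats::runif(1, 0, 2 * pi)
    run_sel <- vapply(segs, `[[`, "", "type")[idx] == "run"
    ha[run_sel] <- ha[run_sel] +
      amp * sin(2 * pi * wfreq * tt[run_sel] + phase)
  }
  data.frame(t_s = tt,
             head_x_mm = x + L * cos((th + ha) * pi / 180),
             head_y_mm = y + L * sin((th + ha) * pi / 180),
             mid_x_mm = x, mid_y_mm = y,
             tail_x_mm = x - L * cos(th * pi / 180),
             tail_y_mm = y - L * sin(th * pi / 180))
}

#' Score detector output against ground truth
#'
#' Greedy 1:1 matching of detected turns to true events: a detected turn
#' matches a true event if its start falls within
#' [true start - tol, true end + tol]. Returns sensitivity (matched true
#' events / all true events) and precision (matched detections / all
#' detections).
#'
#' @param truth true-event data frame (needs `t_start`, `t_end`, and
#'   `dish_id`/`animal_id` when `detected` carries them).
#' @param detected detected-turn data frame (`t_start`, optionally
#'   dish/animal columns).
#' @param tol_s matching tolerance in seconds (default 0.5).
#' @return list: `sensitivity`, `precision`, `n_true`, `n_detected`,
#'   `n_matched`.
#' @export
score_detection <- function(truth, detected, tol_s = 0.5) {
  keyed <- all(c("dish_id", "animal_id") %in% names(truth)) &&
    all(c("dish_id", "animal_id") %in% names(detected))
  base_id <- function(x) sub("#[0-9]+$", "", x)  # drop fragment suffix
  tkey <- if (keyed) paste(truth$dish_id, base_id(truth$animal_id)) else
    rep("", nrow(truth))
  dkey <- if (keyed) paste(detected$dish_id, base_id(detected$animal_id)) else
    rep("", nrow(detected))
  matched_true <- logical(nrow(truth))
  matched_det <- logical(nrow(detected))
  for (i in order(detected$t_start)) {
    cand <- which(!matched_true & tkey == dkey[i] &
                  detected$t_start[i] >= truth$t_start - tol_s &
                  detected$t_start[i] <= truth$t_end + tol_s)
    if (length(cand)) {
      j <- cand[which.min(abs(truth$t_start[cand] - detected$t_start[i]))]
      matched_true[j] <- TRUE
      matched_det[i] <- TRUE
    }
  }
  list(sensitivity = if (nrow(truth)) mean(matched_true) else NA_real_,
       precision = if (nrow(detected)) mean(matched_det) else NA_real_,
       n_true = nrow(truth), n_detected = nrow(detected),
       n_matched = sum(matched_det))
}
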