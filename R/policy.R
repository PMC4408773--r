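#' Behavioral policy: turn-rate lookup plus turning-angle bank
#'
#' A policy is the sensory-motor description the simulator runs on: a
#' turn rate (per second) as a function of the signed bearing to the odor
#' source and the distance from it, a bank of observed turning-angle
#' events `(bearing_before, distance, turning_angle)` for conditional
#' sampling, a scalar mean rate used as fallback (and as the rate in the
#' randomized-rate mode), and the run speed. Two kinds exist: `parametric`
#' (closed-form rate, built by [make_parametric_policy()]) and `empirical`
#' (nearest-cell lookup into a [turn_rate_map()], built by
#' [build_policy()]).
#'
#' @param kind `"parametric"` or `"empirical"`.
#' @param bank data frame with `bearing_before_deg`, `distance_mm`,
#'   `turning_angle_deg`.
#' @param mean_rate_per_s scalar fallback turn rate (per second).
#' @param run_speed_mm_s scalar run speed.
#' @param base_rate_per_s,amplitude,distance_gain_slope,distance_ref_mm
#'   parametric-rate parameters: rate(bearing, d) =
#'   base * (1 - amplitude * cos(bearing)) * max(0, 1 + slope * (d - ref) / ref).
#' @param rate_map a [turn_rate_map()] (empirical kind).
#' @return object of class `behavioral_policy`.
#' @export
behavioral_policy <- function(kind, bank, mean_rate_per_s, run_speed_mm_s,
                              base_rate_per_s = NULL, amplitude = 0,
                              distance_gain_slope = 0, distance_ref_mm = 45,
                              rate_map = NULL) {
  kind <- match.arg(kind, c("parametric", "empirical"))
  stopifnot(is.data.frame(bank), nrow(bank) > 0,
            all(c("bearing_before_deg", "distance_mm", "turning_angle_deg")
                %in% names(bank)),
            mean_rate_per_s >= 0, run_speed_mm_s > 0)
  if (kind == "parametric") stopifnot(is.numeric(base_rate_per_s))
  if (kind == "empirical") stopifnot(inherits(rate_map, "turn_rate_map"))
  structure(list(kind = kind, bank = bank,
                 mean_rate_per_s = mean_rate_per_s,
                 run_speed_mm_s = run_speed_mm_s,
                 base_rate_per_s = base_rate_per_s,
                 amplitude = amplitude,
                 distance_gain_slope = distance_gain_slope,
                 distance_ref_mm = distance_ref_mm,
                 rate_map = rate_map),
            class = "behavioral_policy")
}

#' @export
print.behavioral_policy <- function(x, ...) {
  cat(sprintf("Behavioral policy (%s)\n", x$kind))
  if (x$kind == "parametric")
    cat(sprintf("  rate: %.3f/min * (1 - %.2f cos(bearing))\n",
                60 * x$base_rate_per_s, x$amplitude))
  else
    cat(sprintf("  rate: %d x %d (bearing x distance) lookup grid\n",
                length(x$rate_map$bearing_grid_deg),
                length(x$rate_map$distance_grid_mm)))
  cat(sprintf("  mean rate %.3f/min; run speed %.2f mm/s; bank of %d turning angles\n",
              60 * x$mean_rate_per_s, x$run_speed_mm_s, nrow(x$bank)))
  invisible(x)
}

#' Evaluate a policy's turn rate
#'
#' Vectorized turn-rate lookup. Parametric policies evaluate the closed
#' form; empirical policies use nearest-cell lookup in the rate map, with
#' undefined (no-occupancy) cells falling back to the policy's mean rate.
#'
#' @param policy a [behavioral_policy()].
#' @param bearing_deg,distance_mm query points (recycled).
#' @return turn rate in events per second.
#' @export
rate_lookup <- function(policy, bearing_deg, distance_mm) {
  n <- max(length(bearing_deg), length(distance_mm))
  bearing_deg <- rep_len(bearing_deg, n)
  distance_mm <- rep_len(distance_mm, n)
  if (policy$kind == "parametric") {
    g <- pmax(0, 1 + policy$distance_gain_slope *
                   (distance_mm - policy$distance_ref_mm) / policy$distance_ref_mm)
    return(pmax(0, policy$base_rate_per_s *
                   (1 - policy$amplitude * cos(bearing_deg * pi / 180)) * g))
  }
  m <- policy$rate_map
  bi <- nearest_index(m$bearing_grid_deg, wrap_angle(bearing_deg))
  di <- nearest_index(m$distance_grid_mm, distance_mm)
  r <- m$rate_per_min[cbind(bi, di)] / 60
  r[is.na(r)] <- policy$mean_rate_per_s
  r
}

nearest_index <- function(grid, x) {
  i <- findInterval(x, grid, all.inside = TRUE)
  lower <- abs(x - grid[i]) <= abs(grid[pmin(i + 1L, length(grid))] - x)
  ifelse(lower, i, pmin(i + 1L, length(grid)))
}

#' Build an empirical policy from fitted analysis outputs
#'
#' Packages a fitted turn-rate map, the turning-angle event bank, the
#' pooled mean turn rate and the group's median run speed into a
#' [behavioral_policy()] the simulator can run.
#'
#' @param x a `chemotaxis_fit` (see [fit_chemotaxis()]), or a
#'   [turn_rate_map()].
#' @param bank event bank (required when `x` is a map).
#' @param run_speed_mm_s run speed (median across dishes when `x` is a
#'   fit).
#' @param mean_rate_per_s fallback rate; defaults to the pooled overall
#'   rate.
#' @param ... unused.
#' @return a [behavioral_policy()].
#' @export
build_policy <- function(x, bank = NULL, run_speed_mm_s = NULL,
                         mean_rate_per_s = NULL, ...) {
  if (inherits(x, "chemotaxis_fit")) {
    bank <- x$angle_map$bank
    run_speed_mm_s <- stats::median(x$per_dish$run_speed_mm_s, na.rm = TRUE)
    mean_rate_per_s <- overall_turn_rate(nrow(x$turns),
                                         sum(x$per_dish$tracked_time_s)) / 60
    x <- x$rate_map
  }
  stopifnot(inherits(x, "turn_rate_map"), !is.null(bank))
  if (is.null(mean_rate_per_s)) {
    w <- x$occupancy_s
    mean_rate_per_s <- sum(x$n_turns) / sum(w)  # occupancy-weighted
  }
  behavioral_policy("empirical", bank = bank,
                    mean_rate_per_s = mean_rate_per_s,
                    run_speed_mm_s = run_speed_mm_s,
                    rate_map = x)
}

#' Sample a turning angle from a policy's event bank
#'
#' Draws uniformly from the bank events whose pre-turn bearing lies
#' within +/-`bearing_window_deg` (circularly) of the current bearing and
#' whose distance lies within +/-`distance_window_mm` of the current
#' distance. With `random_dir = TRUE` the current bearing and distance
#' are first replaced by uniform draws from [-180, 180] degrees and from
#' `random_dir_distance_range`. If the subsample is empty the distance
#' window doubles once, then the distance constraint is dropped
#' (bearing-only), then the full bank is used; the fallback level used is
#' recorded in the `fallback` attribute (0 = none .. 3 = full bank).
#'
#' @param policy a [behavioral_policy()].
#' @param bearing_deg,distance_mm current state of the larva.
#' @param bearing_window_deg,distance_window_mm subsample windows
#'   (defaults 30 degrees, 15 mm).
#' @param random_dir randomized-direction mode flag.
#' @param random_dir_distance_range range of the substituted distance.
#' @return one signed turning angle (degrees) with attribute `fallback`.
#' @export
sample_turning_angle <- function(policy, bearing_deg, distance_mm,
                                 bearing_window_deg = 30,
                                 distance_window_mm = 15,
                                 random_dir = FALSE,
                                 random_dir_distance_range = c(0, 100)) {
  if (random_dir) {
    bearing_deg <- stats::runif(1, -180, 180)
    distance_mm <- stats::runif(1, random_dir_distance_range[1],
                                random_dir_distance_range[2])
  }
  bank <- policy$bank
  in_b <- circ_dist(bank$bearing_before_deg, bearing_deg) <= bearing_window_deg
  in_d <- abs(bank$distance_mm - distance_mm) <= distance_window_mm
  sel <- which(in_b & in_d); fallback <- 0L
  if (!length(sel)) {
    in_d2 <- abs(bank$distance_mm - distance_mm) <= 2 * distance_window_mm
    sel <- which(in_b & in_d2); fallback <- 1L
  }
  if (!length(sel)) { sel <- which(in_b); fallback <- 2L }
  if (!length(sel)) { sel <- seq_len(nrow(bank)); fallback <- 3L }
  ang <- bank$turning_angle_deg[sel[sample.int(length(sel), 1L)]]
  attr(ang, "fallback") <- fallback
  ang
}
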