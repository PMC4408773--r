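#' Counted odor preference score
#'
#' End-point preference from animal counts: the number of animals on the
#' odor side minus the number on the no-odor side, divided by the total
#' (including animals in the neutral middle stripe). Ranges over [-1, 1].
#'
#' @param n_odor,n_no_odor,n_middle nonnegative counts.
#' @return numeric preference in [-1, 1].
#' @examples
#' pref_counted(15, 3, 2)  # 0.6
#' @export
pref_counted <- function(n_odor, n_no_odor, n_middle = 0) {
  stopifnot(n_odor >= 0, n_no_odor >= 0, n_middle >= 0)
  total <- n_odor + n_no_odor + n_middle
  if (total <= 0) stop("undefined preference: no animals counted")
  (n_odor - n_no_odor) / total
}

#' Filmed odor preference score
#'
#' Time-based preference for one dish: the tracked time spent on the odor
#' half of the arena (midpoint x > 0) minus the time on the no-odor half,
#' divided by the total tracked time. Frames exactly on the midline are
#' split evenly between the two sides. No neutral stripe is applied; the
#' split is a pure midline split.
#'
#' @param dataset a [larva_dataset()] (one dish), or any object with
#'   trajectories carrying `mid_x_mm`.
#' @return numeric preference in [-1, 1].
#' @export
pref_filmed <- function(dataset) {
  x <- unlist(lapply(dataset$trajectories, function(tr) tr$mid_x_mm),
              use.names = FALSE)
  pref_from_x(x)
}

# preference from a vector of midpoint x positions (equal-time frames)
pref_from_x <- function(x) {
  n <- length(x)
  if (n == 0L) stop("undefined preference: zero tracked time")
  (sum(x > 0) - sum(x < 0)) / n
}

#' Duration-weighted mean run speed for one dish
#'
#' Average midpoint speed during runs, weighting each run by its duration
#' (equivalently, averaging over run frames), in mm/s.
#'
#' @param runs data frame of run segments with `duration_s` and
#'   `mean_speed_mm_s` (from [segment_runs()], possibly row-bound across
#'   animals of a dish).
#' @return mm/s.
#' @export
run_speed <- function(runs) {
  if (is.null(runs) || nrow(runs) == 0L) stop("undefined run speed: no runs")
  sum(runs$mean_speed_mm_s * runs$duration_s) / sum(runs$duration_s)
}

#' Overall turn rate, in turns per minute
#'
#' Number of turns divided by the total tracked duration; when pooling,
#' counts and durations are summed before dividing (a ratio of sums, not
#' a mean of ratios).
#'
#' @param turn_count total number of turns (summed over what is pooled).
#' @param tracked_time_s total tracked time in seconds.
#' @return turns/min.
#' @examples
#' overall_turn_rate(10, 300)  # 2 turns/min
#' @export
overall_turn_rate <- function(turn_count, tracked_time_s) {
  if (sum(tracked_time_s) <= 0) stop("undefined turn rate: zero tracked time")
  60 * sum(turn_count) / sum(tracked_time_s)
}

#' Turn rates toward and away from the odor source
#'
#' Turn rate computed separately for bearings toward the source (absolute
#' bearing < 90 degrees) and away from it (absolute bearing > 90),
#' using as denominators the tracked time spent at bearings of each class.
#' Turns and frames at exactly |bearing| = 90 belong to neither class.
#'
#' @param turn_bearings_deg signed pre-turn bearings of the turns.
#' @param frame_bearings_deg signed bearings of all tracked frames.
#' @param dt_s frame interval in seconds.
#' @return named numeric vector `c(toward =, away =)` in turns/min (NA
#'   where a class has zero occupancy).
#' @export
turn_rate_toward_away <- function(turn_bearings_deg, frame_bearings_deg, dt_s) {
  rate_of <- function(sel_turn, sel_frame) {
    occ <- sum(sel_frame) * dt_s
    if (occ <= 0) return(NA_real_)
    60 * sum(sel_turn) / occ
  }
  c(toward = rate_of(abs(turn_bearings_deg) < 90,
                     abs(frame_bearings_deg) < 90),
    away = rate_of(abs(turn_bearings_deg) > 90,
                   abs(frame_bearings_deg) > 90))
}

#' Proportion of turns directed toward the odor
#'
#' A turn counts as toward the odor iff the absolute bearing after the
#' turn is strictly smaller than the absolute bearing before it; ties
#' count as not toward.
#'
#' @param turns data frame with `bearing_before_deg` and
#'   `bearing_after_deg` (or a logical `toward_odor` column, used as is).
#' @return fraction in [0, 1].
#' @export
proportion_toward <- function(turns) {
  if (is.null(turns) || nrow(turns) == 0L)
    stop("undefined proportion: no turns")
  toward <- if (!is.null(turns$toward_odor)) turns$toward_odor
            else abs(turns$bearing_after_deg) < abs(turns$bearing_before_deg)
  mean(toward)
}

#' Nonparametric group comparison with Bonferroni correction
#'
#' Convenience wrapper for comparing a per-dish measure across
#' experimental groups: a Kruskal-Wallis omnibus test followed by pairwise
#' Mann-Whitney U tests, with the critical level divided by the number of
#' pairwise tests. The tests themselves delegate to
#' [stats::kruskal.test()] and [stats::wilcox.test()]; only the correction
#' bookkeeping is local.
#'
#' @param values_by_group named list of numeric vectors, one per group.
#' @param alpha experiment-wide error rate (default 0.05).
#' @return list with `omnibus` (statistic, p-value), `pairwise` data frame
#'   (group pair, W statistic, p-value, Bonferroni-adjusted critical
#'   level, significance flag) and `critical_level`.
#' @export
compare_groups <- function(values_by_group, alpha = 0.05) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2L)
  if (is.null(names(values_by_group)))
    names(values_by_group) <- paste0("group", seq_along(values_by_group))
  small <- vapply(values_by_group, length, 0L) < 2L
  if (any(small)) {
    warning("excluding group(s) with < 2 values: ",
            paste(names(values_by_group)[small], collapse = ", "))
    values_by_group <- values_by_group[!small]
  }
  if (length(values_by_group) < 2L) stop("need at least 2 usable groups")
  g <- factor(rep(names(values_by_group),
                  vapply(values_by_group, length, 0L)),
              levels = names(values_by_group))
  v <- unlist(values_by_group, use.names = FALSE)
  kw <- stats::kruskal.test(v, g)
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  crit <- alpha / length(pairs)
  pw <- do.call(rbind, lapply(pairs, function(p) {
    wt <- suppressWarnings(stats::wilcox.test(values_by_group[[p[1]]],
                                              values_by_group[[p[2]]]))
    data.frame(group1 = p[1], group2 = p[2],
               W = unname(wt$statistic), p_value = wt$p.value,
               critical_level = crit,
               significant = wt$p.value < crit)
  }))
  list(omnibus = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p_value = kw$p.value),
       pairwise = pw, critical_level = crit)
}
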