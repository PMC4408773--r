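#' Schmitt-trigger configuration
#'
#' Hysteresis detector settings: an event opens when the rectified signal
#' reaches `high` and closes at the first subsequent frame at or below
#' `low`; events shorter than `min_duration_s` are discarded.
#'
#' @param high,low thresholds in signal units, `high > low >= 0`.
#' @param min_duration_s minimum event duration in seconds.
#' @return an object of class `schmitt_config`.
#' @export
schmitt_config <- function(high, low, min_duration_s = 0) {
  stopifnot(is.numeric(high), is.numeric(low), high > low, low >= 0,
            min_duration_s >= 0)
  structure(list(high = high, low = low, min_duration_s = min_duration_s),
            class = "schmitt_config")
}

#' Detect events in a signal with Schmitt-trigger hysteresis
#'
#' Scans the rectified signal `|x|` with a two-threshold hysteresis: an
#' interval opens at the first frame where `|x| >= high` and closes at the
#' first subsequent frame where `|x| <= low` (an interval still open at
#' the end of the signal is closed there). Intervals shorter than
#' `min_duration_s` are dropped. The hysteresis band suppresses chatter
#' from signals hovering around a single threshold.
#'
#' @param signal numeric vector, uniformly sampled.
#' @param cfg a [schmitt_config()].
#' @param dt_s sampling interval in seconds.
#' @param t0_s time of the first sample.
#' @return data frame with columns `i_start`, `i_end` (frame indices,
#'   1-based, inclusive) and `t_start`, `t_end` (seconds).
#' @export
schmitt_detect <- function(signal, cfg, dt_s, t0_s = 0) {
  stopifnot(inherits(cfg, "schmitt_config"), dt_s > 0)
  x <- abs(signal)
  n <- length(x)
  hi <- x >= cfg$high
  lo <- x <= cfg$low
  starts <- integer(0)
  ends <- integer(0)
  i <- 1L
  while (i <= n) {
    s_rel <- match(TRUE, hi[i:n])
    if (is.na(s_rel)) break
    s <- i + s_rel - 1L
    if (s >= n) {
      e <- n
    } else {
      e_rel <- match(TRUE, lo[(s + 1L):n])
      e <- if (is.na(e_rel)) n else s + e_rel
    }
    starts <- c(starts, s)
    ends <- c(ends, e)
    i <- e + 1L
  }
  keep <- (ends - starts) * dt_s >= cfg$min_duration_s
  data.frame(i_start = starts[keep], i_end = ends[keep],
             t_start = t0_s + (starts[keep] - 1L) * dt_s,
             t_end = t0_s + (ends[keep] - 1L) * dt_s)
}

#' Turn-detection configuration
#'
#' Turns are detected primarily from the reorientation speed (body-axis
#' angular velocity) via a Schmitt trigger, then gated on posture (the
#' larva must bend: max |head angle| during the event) and on the net
#' body-orientation change, which must exceed 20 degrees -- smaller events
#' show no directional bias and are not scored as turns. The Schmitt and
#' posture thresholds are empirical surrogates exposed as configuration;
#' the 20 degree orientation-change cutoff is fixed by the method.
#'
#' @param reorientation [schmitt_config()] for |reorientation speed| in
#'   deg/s (defaults: high 35, low 15, min duration 0.25 s).
#' @param posture_gate_deg minimum peak |head angle| within a candidate
#'   event (default 20).
#' @param min_orientation_change_deg net body-orientation change cutoff
#'   (default 20; the method's defining threshold).
#' @param margin_s offset delta used to measure orientation and bearing
#'   just outside the event (default 0.25 s), avoiding within-turn
#'   transients.
#' @param merge_gap_s candidate intervals closer than this are merged
#'   (default 0.25 s).
#' @return an object of class `turn_config`.
#' @export
turn_config <- function(reorientation = schmitt_config(35, 15, 0.25),
                        posture_gate_deg = 20,
                        min_orientation_change_deg = 20,
                        margin_s = 0.25,
                        merge_gap_s = 0.25) {
  stopifnot(inherits(reorientation, "schmitt_config"),
            posture_gate_deg > 0, min_orientation_change_deg > 0,
            margin_s >= 0, merge_gap_s >= 0)
  structure(list(reorientation = reorientation,
                 posture_gate_deg = posture_gate_deg,
                 min_orientation_change_deg = min_orientation_change_deg,
                 margin_s = margin_s,
                 merge_gap_s = merge_gap_s),
            class = "turn_config")
}

#' Detect turns in a kinematic series
#'
#' Candidate intervals come from [schmitt_detect()] on the absolute
#' reorientation speed; candidates separated by less than `merge_gap_s`
#' are merged. A candidate is kept iff (i) the peak |head angle| within it
#' reaches the posture gate and (ii) the net change of the body-axis angle
#' measured `margin_s` outside the interval exceeds
#' `min_orientation_change_deg`. The turning angle is the signed
#' (counterclockwise-positive) body-orientation difference across the
#' turn; bearings before/after are read `margin_s` outside the event
#' (clipped to the trajectory); `toward_odor` is the strict criterion
#' |bearing after| < |bearing before|.
#'
#' @param kin a `kinematic_series` from [derive_kinematics()].
#' @param cfg a [turn_config()].
#' @return data frame of turns with columns `t_start`, `t_end`,
#'   `bearing_before_deg`, `bearing_after_deg`, `distance_mm`,
#'   `turning_angle_deg`, `toward_odor`.
#' @export
detect_turns <- function(kin, cfg = turn_config()) {
  dt <- attr(kin, "frame_dt_s")
  n <- nrow(kin)
  cand <- schmitt_detect(kin$reorientation_speed_deg_s, cfg$reorientation,
                         dt_s = dt, t0_s = kin$t_s[1L])
  cand <- merge_intervals(cand, cfg$merge_gap_s)
  if (nrow(cand) == 0L) return(empty_turns())

  off <- max(0L, round(cfg$margin_s / dt))
  keep <- logical(nrow(cand))
  out <- vector("list", nrow(cand))
  for (k in seq_len(nrow(cand))) {
    s <- cand$i_start[k]; e <- cand$i_end[k]
    ib <- max(1L, s - off)
    ia <- min(n, e + off)
    peak_bend <- max(abs(kin$head_angle_deg[s:e]))
    turn_angle <- angle_diff(kin$tail_angle_deg[ia], kin$tail_angle_deg[ib])
    if (peak_bend >= cfg$posture_gate_deg &&
        abs(turn_angle) > cfg$min_orientation_change_deg) {
      keep[k] <- TRUE
      bb <- kin$bearing_deg[ib]
      ba <- kin$bearing_deg[ia]
      out[[k]] <- data.frame(
        t_start = cand$t_start[k], t_end = cand$t_end[k],
        bearing_before_deg = bb, bearing_after_deg = ba,
        distance_mm = kin$distance_mm[s],
        turning_angle_deg = turn_angle,
        toward_odor = abs(ba) < abs(bb))
    }
  }
  if (!any(keep)) return(empty_turns())
  do.call(rbind, out[keep])
}

empty_turns <- function() {
  data.frame(t_start = numeric(0), t_end = numeric(0),
             bearing_before_deg = numeric(0), bearing_after_deg = numeric(0),
             distance_mm = numeric(0), turning_angle_deg = numeric(0),
             toward_odor = logical(0))
}

merge_intervals <- function(iv, gap_s) {
  if (nrow(iv) < 2L) return(iv)
  merged <- iv[1L, , drop = FALSE]
  for (k in 2L:nrow(iv)) {
    last <- nrow(merged)
    if (iv$t_start[k] - merged$t_end[last] < gap_s) {
      merged$t_end[last] <- iv$t_end[k]
      merged$i_end[last] <- iv$i_end[k]
    } else {
      merged <- rbind(merged, iv[k, , drop = FALSE])
    }
  }
  merged
}

#' Detect head casts and classify them as flanking or in-run
#'
#' Head casts are lateral head sweeps detected from |head angle| with a
#' second Schmitt trigger (defaults: high 20 deg, low 10 deg). A cast is
#' "flanking" a turn if it starts within the window from 5 s before the
#' turn's start to 0.5 s after the turn's end; casts can also occur during
#' runs, in which case they flank no turn.
#'
#' @param kin a `kinematic_series`.
#' @param turns data frame from [detect_turns()].
#' @param cast_cfg a [schmitt_config()] on |head angle| in degrees.
#' @param window_before_s,window_after_s flanking window relative to a
#'   turn (defaults 5 and 0.5 s).
#' @return data frame with `t_start`, `t_end`, `peak_head_angle_deg`,
#'   `flanking` (logical) and `flanking_turn` (row index into `turns`, NA
#'   if none).
#' @export
detect_head_casts <- function(kin, turns,
                              cast_cfg = schmitt_config(20, 10, 0),
                              window_before_s = 5, window_after_s = 0.5) {
  dt <- attr(kin, "frame_dt_s")
  iv <- schmitt_detect(kin$head_angle_deg, cast_cfg, dt_s = dt,
                       t0_s = kin$t_s[1L])
  if (nrow(iv) == 0L)
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      peak_head_angle_deg = numeric(0),
                      flanking = logical(0), flanking_turn = integer(0)))
  peak <- vapply(seq_len(nrow(iv)), function(k) {
    seg <- kin$head_angle_deg[iv$i_start[k]:iv$i_end[k]]
    seg[which.max(abs(seg))]
  }, 0)
  flank_idx <- rep(NA_integer_, nrow(iv))
  if (nrow(turns) > 0L) {
    for (k in seq_len(nrow(iv))) {
      hit <- which(iv$t_start[k] >= turns$t_start - window_before_s &
                   iv$t_start[k] <= turns$t_end + window_after_s)
      if (length(hit)) flank_idx[k] <- hit[1L]
    }
  }
  data.frame(t_start = iv$t_start, t_end = iv$t_end,
             peak_head_angle_deg = peak,
             flanking = !is.na(flank_idx), flanking_turn = flank_idx)
}

#' Segment runs between turns
#'
#' A run spans from a turn's end (or the trajectory start) to the start of
#' the earliest flanking head cast of the following turn; if that turn has
#' no flanking cast the run ends at the turn's start, and the final run
#' ends at the trajectory end. Runs of non-positive duration are dropped.
#' The mean midpoint speed over each run is recorded.
#'
#' @param turns data frame from [detect_turns()].
#' @param casts data frame from [detect_head_casts()].
#' @param kin the `kinematic_series` the events were detected on.
#' @return data frame with `t_start`, `t_end`, `duration_s`,
#'   `mean_speed_mm_s`.
#' @export
segment_runs <- function(turns, casts, kin) {
  t0 <- kin$t_s[1L]
  t1 <- kin$t_s[nrow(kin)]
  starts <- c(t0, turns$t_end)
  out <- list()
  for (k in seq_along(starts)) {
    rs <- starts[k]
    nxt <- if (nrow(turns)) which(turns$t_start > rs) else integer(0)
    if (length(nxt)) {
      j <- nxt[1L]
      fl <- casts$t_start[!is.na(casts$flanking_turn) &
                          casts$flanking_turn == j &
                          casts$t_start >= rs]
      re <- if (length(fl)) min(fl) else turns$t_start[j]
    } else {
      re <- t1
    }
    if (re > rs) {
      sel <- kin$t_s >= rs & kin$t_s <= re
      out[[length(out) + 1L]] <- data.frame(
        t_start = rs, t_end = re, duration_s = re - rs,
        mean_speed_mm_s = mean(kin$speed_mm_s[sel]))
    }
  }
  if (!length(out))
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration_s = numeric(0), mean_speed_mm_s = numeric(0)))
  do.call(rbind, out)
}

#' Write detected events as a TSV table
#'
#' Emits the combined event table (`kind` in turn/cast/run) in a flat
#' tab-separated format.
#'
#' @param events list with components `turns`, `casts`, `runs` as returned
#'   by [fit_chemotaxis()] (per-dish/animal columns included).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  pick <- function(df, kind) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    data.frame(dish_id = df$dish_id %||% NA, animal_id = df$animal_id %||% NA,
               kind = kind,
               t_start = df$t_start, t_end = df$t_end,
               bearing_before = df$bearing_before_deg %||% NA,
               bearing_after = df$bearing_after_deg %||% NA,
               distance_mm = df$distance_mm %||% NA,
               turning_angle = df$turning_angle_deg %||% NA,
               toward = df$toward_odor %||% NA)
  }
  out <- rbind(pick(events$turns, "turn"), pick(events$casts, "cast"),
               pick(events$runs, "run"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
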