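#' Bearing-resolved turn-rate profile
#'
#' Pooled turn rate as a function of the signed bearing to the odor
#' source, on a 1-degree grid over [-180, 180] with a circular sliding
#' window of +/-30 degrees: at each grid point the rate is 60 times the
#' number of turns whose pre-turn bearing falls in the window, divided by
#' the occupancy (seconds of tracked time spent at bearings in the
#' window). Grid points with zero occupancy are NA and flagged in the
#' `undefined` column. The window is inclusive at both edges and wraps
#' circularly, so the values at -180 and +180 coincide.
#'
#' @param turn_bearings_deg signed pre-turn bearings of pooled turns.
#' @param frame_bearings_deg signed bearings of pooled tracked frames
#'   (defines occupancy).
#' @param dt_s frame interval of the occupancy frames, seconds.
#' @param halfwidth_deg sliding-filter halfwidth (default 30).
#' @param step_deg grid step (default 1).
#' @return data frame of class `turn_rate_profile`: `bearing_deg`,
#'   `rate_per_min`, `n_turns`, `occupancy_s`, `undefined`.
#' @export
turn_rate_profile <- function(turn_bearings_deg, frame_bearings_deg, dt_s,
                              halfwidth_deg = 30, step_deg = 1) {
  grid <- seq(-180, 180, by = step_deg)
  counts <- .circ_window_sum(grid, as.numeric(turn_bearings_deg),
                             rep(1, length(turn_bearings_deg)), halfwidth_deg)
  occ <- .circ_window_sum(grid, as.numeric(frame_bearings_deg),
                          rep(dt_s, length(frame_bearings_deg)), halfwidth_deg)
  rate <- ifelse(occ > 0, 60 * counts / occ, NA_real_)
  structure(data.frame(bearing_deg = grid, rate_per_min = rate,
                       n_turns = counts, occupancy_s = occ,
                       undefined = occ <= 0),
            class = c("turn_rate_profile", "data.frame"),
            halfwidth_deg = halfwidth_deg)
}

#' Bearing-resolved mean turning-angle profile
#'
#' Mean signed turning angle as a function of the pre-turn bearing, same
#' grid and circular sliding filter as [turn_rate_profile()]. Windows
#' containing no turns are NA.
#'
#' @param turn_bearings_deg signed pre-turn bearings of pooled turns.
#' @param turning_angles_deg signed turning angles of the same turns.
#' @param halfwidth_deg,step_deg filter geometry (defaults 30 and 1).
#' @return data frame of class `turning_angle_profile`: `bearing_deg`,
#'   `mean_angle_deg`, `n_turns`, `undefined`.
#' @export
turning_angle_profile <- function(turn_bearings_deg, turning_angles_deg,
                                  halfwidth_deg = 30, step_deg = 1) {
  stopifnot(length(turn_bearings_deg) == length(turning_angles_deg))
  grid <- seq(-180, 180, by = step_deg)
  counts <- .circ_window_sum(grid, as.numeric(turn_bearings_deg),
                             rep(1, length(turn_bearings_deg)), halfwidth_deg)
  sums <- .circ_window_sum(grid, as.numeric(turn_bearings_deg),
                           as.numeric(turning_angles_deg), halfwidth_deg)
  structure(data.frame(bearing_deg = grid,
                       mean_angle_deg = ifelse(counts > 0, sums / counts,
                                               NA_real_),
                       n_turns = counts, undefined = counts <= 0),
            class = c("turning_angle_profile", "data.frame"),
            halfwidth_deg = halfwidth_deg)
}

# distance grid covering the data range at the given step
distance_grid <- function(d, step) {
  if (!length(d)) return(numeric(0))
  seq(floor(min(d) / step) * step, ceiling(max(d) / step) * step, by = step)
}

#' Turn-rate map over bearing and distance
#'
#' Pooled turn rate on a (bearing x distance) grid (steps 2 degrees and
#' 2 mm) with a sliding box filter of +/-30 degrees and +/-15 mm. The
#' bearing dimension is circular; the distance dimension is truncated at
#' the data range. Cells with zero occupancy are NA; the occupancy layer
#' is returned so no-data cells are distinguishable from zero rates.
#'
#' @param turn_bearings_deg,turn_distances_mm pre-turn bearing and
#'   distance of pooled turns.
#' @param frame_bearings_deg,frame_distances_mm bearing and distance of
#'   pooled tracked frames.
#' @param dt_s frame interval, seconds.
#' @param bearing_halfwidth_deg,distance_halfwidth_mm box-filter
#'   halfwidths (defaults 30 and 15).
#' @param bearing_step_deg,distance_step_mm grid steps (defaults 2 and 2).
#' @return list of class `turn_rate_map`: `bearing_grid_deg`,
#'   `distance_grid_mm`, matrices `rate_per_min`, `n_turns`,
#'   `occupancy_s`.
#' @export
turn_rate_map <- function(turn_bearings_deg, turn_distances_mm,
                          frame_bearings_deg, frame_distances_mm, dt_s,
                          bearing_halfwidth_deg = 30,
                          distance_halfwidth_mm = 15,
                          bearing_step_deg = 2, distance_step_mm = 2) {
  bgrid <- seq(-180, 180, by = bearing_step_deg)
  dgrid <- distance_grid(frame_distances_mm, distance_step_mm)
  counts <- .box_window_sum(bgrid, dgrid,
                            as.numeric(turn_bearings_deg),
                            as.numeric(turn_distances_mm),
                            rep(1, length(turn_bearings_deg)),
                            bearing_halfwidth_deg, distance_halfwidth_mm, TRUE)
  occ <- .box_window_sum(bgrid, dgrid,
                         as.numeric(frame_bearings_deg),
                         as.numeric(frame_distances_mm),
                         rep(dt_s, length(frame_bearings_deg)),
                         bearing_halfwidth_deg, distance_halfwidth_mm, TRUE)
  rate <- ifelse(occ > 0, 60 * counts / occ, NA_real_)
  dim(rate) <- dim(occ)
  structure(list(bearing_grid_deg = bgrid, distance_grid_mm = dgrid,
                 rate_per_min = rate, n_turns = counts, occupancy_s = occ),
            class = "turn_rate_map")
}

#' Turning-angle map over bearing and distance
#'
#' Mean signed turning angle on the (bearing x distance) grid with the
#' same box filter as [turn_rate_map()]. The raw event bank (pre-turn
#' bearing, distance, turning angle) is retained in the result, since the
#' simulator samples turning angles conditionally from it.
#'
#' @inheritParams turn_rate_map
#' @param turning_angles_deg signed turning angles of the pooled turns.
#' @return list of class `turning_angle_map`: grids, matrices
#'   `mean_angle_deg`, `n_turns`, and the `bank` data frame.
#' @export
turning_angle_map <- function(turn_bearings_deg, turn_distances_mm,
                              turning_angles_deg,
                              bearing_halfwidth_deg = 30,
                              distance_halfwidth_mm = 15,
                              bearing_step_deg = 2, distance_step_mm = 2) {
  bgrid <- seq(-180, 180, by = bearing_step_deg)
  dgrid <- distance_grid(turn_distances_mm, distance_step_mm)
  counts <- .box_window_sum(bgrid, dgrid,
                            as.numeric(turn_bearings_deg),
                            as.numeric(turn_distances_mm),
                            rep(1, length(turn_bearings_deg)),
                            bearing_halfwidth_deg, distance_halfwidth_mm, TRUE)
  sums <- .box_window_sum(bgrid, dgrid,
                          as.numeric(turn_bearings_deg),
                          as.numeric(turn_distances_mm),
                          as.numeric(turning_angles_deg),
                          bearing_halfwidth_deg, distance_halfwidth_mm, TRUE)
  mean_angle <- ifelse(counts > 0, sums / counts, NA_real_)
  dim(mean_angle) <- dim(counts)
  structure(list(bearing_grid_deg = bgrid, distance_grid_mm = dgrid,
                 mean_angle_deg = mean_angle, n_turns = counts,
                 bank = data.frame(bearing_before_deg = turn_bearings_deg,
                                   distance_mm = turn_distances_mm,
                                   turning_angle_deg = turning_angles_deg)),
            class = "turning_angle_map")
}

#' Proportion of turns toward the odor over distance and time
#'
#' Pooled proportion of toward-turns on a (time x distance) grid, box
#' filter of +/-22.5 s and +/-10 mm, steps 7.5 s and 2.5 mm; both
#' dimensions are linear and truncated at the data range.
#'
#' @param turn_times_s turn start times.
#' @param turn_distances_mm pre-turn distances to the source.
#' @param toward logical vector, toward-odor classification per turn.
#' @param time_halfwidth_s,distance_halfwidth_mm filter halfwidths
#'   (defaults 22.5 and 10).
#' @param time_step_s,distance_step_mm grid steps (defaults 7.5 and 2.5).
#' @return list of class `proportion_toward_map`: `time_grid_s`,
#'   `distance_grid_mm`, matrices `proportion`, `n_turns`.
#' @export
proportion_toward_map <- function(turn_times_s, turn_distances_mm, toward,
                                  time_halfwidth_s = 22.5,
                                  distance_halfwidth_mm = 10,
                                  time_step_s = 7.5, distance_step_mm = 2.5) {
  tgrid <- distance_grid(turn_times_s, time_step_s)
  dgrid <- distance_grid(turn_distances_mm, distance_step_mm)
  counts <- .box_window_sum(tgrid, dgrid, as.numeric(turn_times_s),
                            as.numeric(turn_distances_mm),
                            rep(1, length(turn_times_s)),
                            time_halfwidth_s, distance_halfwidth_mm, FALSE)
  hits <- .box_window_sum(tgrid, dgrid, as.numeric(turn_times_s),
                          as.numeric(turn_distances_mm),
                          as.numeric(toward),
                          time_halfwidth_s, distance_halfwidth_mm, FALSE)
  prop <- ifelse(counts > 0, hits / counts, NA_real_)
  dim(prop) <- dim(counts)
  structure(list(time_grid_s = tgrid, distance_grid_mm = dgrid,
                 proportion = prop, n_turns = counts),
            class = "proportion_toward_map")
}

#' Larval density map
#'
#' Time-averaged number of animals per square millimetre on a 2 mm
#' spatial grid, smoothed with a sliding square filter of 30 mm side
#' length: each cell reports the mean number of animals found within the
#' 30 mm square centered on it, divided by the square's area.
#'
#' @param dataset a [larva_dataset()].
#' @param filter_side_mm side length of the square filter (default 30).
#' @param step_mm grid step (default 2).
#' @return list of class `density_map`: `x_grid_mm`, `y_grid_mm`, matrix
#'   `animals_per_mm2`.
#' @export
density_map <- function(dataset, filter_side_mm = 30, step_mm = 2) {
  arena <- dataset$arena
  xs <- unlist(lapply(dataset$trajectories, function(tr) tr$mid_x_mm),
               use.names = FALSE)
  ys <- unlist(lapply(dataset$trajectories, function(tr) tr$mid_y_mm),
               use.names = FALSE)
  ts <- unlist(lapply(dataset$trajectories, function(tr) tr$t_s),
               use.names = FALSE)
  if (!length(xs)) stop("no tracked frames")
  duration_frames <- length(unique(ts))
  grid <- seq(-arena$radius_mm, arena$radius_mm, by = step_mm)
  hw <- filter_side_mm / 2
  counts <- .box_window_sum(grid, grid, xs, ys, rep(1, length(xs)),
                            hw, hw, FALSE)
  dens <- counts / duration_frames / filter_side_mm^2
  dim(dens) <- dim(counts)
  structure(list(x_grid_mm = grid, y_grid_mm = grid,
                 animals_per_mm2 = dens,
                 n_timepoints = duration_frames),
            class = "density_map")
}
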