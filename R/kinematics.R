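#' Derive per-frame kinematic series from a trajectory
#'
#' Computes, for every frame of one larva, the body-axis (tail-to-midpoint)
#' orientation, the heading (midpoint-to-head orientation), the signed head
#' angle between the two segments, the reorientation speed (time derivative
#' of the circularly unwrapped body-axis angle; head casts therefore do not
#' register as reorientation), the signed bearing to the odor source, the
#' distance from the midpoint to the source, and the midpoint speed.
#'
#' Sign conventions: angles are counterclockwise-positive; the bearing is
#' the angle from the heading to the source direction in (-180, 180], so
#' 0 means heading straight at the source and positive bearings put the
#' source on the larva's left. Derivatives use central differences with
#' one-sided differences at the first and last frame.
#'
#' Frames with a degenerate body or head segment (coincident points) are
#' interpolated from neighbouring frames; if more than 1% of frames are
#' degenerate a warning is raised, and an all-degenerate trajectory is an
#' error.
#'
#' @param traj one trajectory from a [larva_dataset()].
#' @param arena an [arena_spec()].
#' @return a data frame of class `kinematic_series` with columns `t_s`,
#'   `tail_angle_deg`, `heading_deg`, `head_angle_deg`,
#'   `reorientation_speed_deg_s`, `bearing_deg`, `distance_mm`,
#'   `speed_mm_s`, `mid_x_mm`, `mid_y_mm`.
#' @export
derive_kinematics <- function(traj, arena = arena_spec()) {
  n <- nrow(traj)
  stopifnot(n >= 2L)
  dt <- attr(traj, "frame_dt_s")
  if (is.null(dt)) dt <- stats::median(diff(traj$t_s))

  tail_ang <- segment_angle(traj$tail_x_mm, traj$tail_y_mm,
                            traj$mid_x_mm, traj$mid_y_mm)
  head_ang_abs <- segment_angle(traj$mid_x_mm, traj$mid_y_mm,
                                traj$head_x_mm, traj$head_y_mm)
  deg_tail <- traj$mid_x_mm == traj$tail_x_mm & traj$mid_y_mm == traj$tail_y_mm
  deg_head <- traj$head_x_mm == traj$mid_x_mm & traj$head_y_mm == traj$mid_y_mm
  degen <- deg_tail | deg_head
  if (all(degen)) stop("unusable trajectory: all frames degenerate")
  if (mean(degen) > 0.01)
    warning(sprintf("%.1f%% of frames have degenerate segments", 100 * mean(degen)))
  tail_ang <- fill_angles(tail_ang, degen = deg_tail, t = traj$t_s)
  head_ang_abs <- fill_angles(head_ang_abs, degen = deg_head, t = traj$t_s)

  head_angle <- angle_diff(head_ang_abs, tail_ang)
  tail_unwrapped <- unwrap_angle(tail_ang)
  reo <- central_diff(tail_unwrapped, dt)

  sx <- arena$odor_source_xy_mm[1L]
  sy <- arena$odor_source_xy_mm[2L]
  source_dir <- segment_angle(traj$mid_x_mm, traj$mid_y_mm, sx, sy)
  bearing <- angle_diff(source_dir, head_ang_abs)
  distance <- sqrt((sx - traj$mid_x_mm)^2 + (sy - traj$mid_y_mm)^2)
  speed <- sqrt(central_diff(traj$mid_x_mm, dt)^2 +
                central_diff(traj$mid_y_mm, dt)^2)

  out <- data.frame(t_s = traj$t_s,
                    tail_angle_deg = wrap_angle(tail_ang),
                    heading_deg = wrap_angle(head_ang_abs),
                    head_angle_deg = head_angle,
                    reorientation_speed_deg_s = reo,
                    bearing_deg = bearing,
                    distance_mm = distance,
                    speed_mm_s = speed,
                    mid_x_mm = traj$mid_x_mm,
                    mid_y_mm = traj$mid_y_mm)
  attr(out, "dish_id") <- attr(traj, "dish_id")
  attr(out, "animal_id") <- attr(traj, "animal_id")
  attr(out, "frame_dt_s") <- dt
  class(out) <- c("kinematic_series", "data.frame")
  out
}

# replace degenerate angle samples by interpolation on the unwrapped
# series of valid neighbours (nearest valid value at the ends)
fill_angles <- function(ang, degen, t) {
  if (!any(degen)) return(ang)
  ok <- which(!degen)
  uw <- unwrap_angle(ang[ok])
  filled <- stats::approx(t[ok], uw, xout = t, rule = 2)$y
  ang[degen] <- wrap_angle(filled[degen])
  ang
}

# note: heading is taken from the mid->head segment; bearing uses the
# midpoint as the larva's position reference
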