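#' Signed smallest difference between two angles
#'
#' Computes `a - b` modulo 360 and maps the result into the half-open
#' interval (-180, 180], so that e.g. `angle_diff(170, -170)` is -20 and
#' the antipodal case maps to +180. This is the primitive behind every
#' angular statistic in the package (bearings, head angles, turning
#' angles).
#'
#' @param a_deg,b_deg numeric vectors of angles in degrees (recycled).
#' @return numeric vector of signed differences in (-180, 180].
#' @examples
#' angle_diff(170, -170)   # -20
#' angle_diff(-90, 90)     # 180 (boundary maps to +180)
#' @export
angle_diff <- function(a_deg, b_deg) {
  wrap_angle(a_deg - b_deg)
}

#' Wrap angles into (-180, 180]
#'
#' @param x_deg numeric vector of angles in degrees.
#' @return angles mapped into (-180, 180].
#' @export
wrap_angle <- function(x_deg) {
  y <- (x_deg + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Unwrap a circular angle series
#'
#' Removes +/-360 degree jumps so the series can be differentiated.
#' Successive differences are taken on the circle (via [angle_diff()]) and
#' re-accumulated from the first value.
#'
#' @param theta_deg numeric vector of angles in degrees.
#' @return numeric vector, continuous (not wrapped).
#' @export
unwrap_angle <- function(theta_deg) {
  n <- length(theta_deg)
  if (n < 2L) return(theta_deg)
  theta_deg[1L] + cumsum(c(0, angle_diff(theta_deg[-1L], theta_deg[-n])))
}

#' Absolute circular distance between angles, in [0, 180]
#' @param a_deg,b_deg angles in degrees.
#' @return nonnegative circular distances.
#' @export
circ_dist <- function(a_deg, b_deg) {
  abs(angle_diff(a_deg, b_deg))
}

# orientation (deg) of the vector from (x0,y0) to (x1,y1)
segment_angle <- function(x0, y0, x1, y1) {
  atan2(y1 - y0, x1 - x0) * 180 / pi
}

# derivative of `x` by central differences on a uniform grid, one-sided at
# the ends; `x` must already be unwrapped if angular
central_diff <- function(x, dt) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  d <- numeric(n)
  d[1L] <- (x[2L] - x[1L]) / dt
  d[n] <- (x[n] - x[n - 1L]) / dt
  if (n > 2L) d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  d
}
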