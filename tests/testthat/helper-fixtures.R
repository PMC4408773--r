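# Fixture builders shared across test files. Heavier synthetic datasets
# are generated once per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, make) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- make()
  .fixture_cache[[name]]
}

# moderately sized dataset from the toward-biased policy used by several
# test files (4 dishes x 13 larvae x 300 s)
biased_syn <- function() {
  cached("biased_syn", function() {
    generate_dataset(parametric_policy_spec(amplitude = 0.5,
                                            toward_bias = 0.7),
                     n_dishes = 4, n_larvae = 13, duration_s = 300,
                     seed = 101)
  })
}

biased_fit <- function() {
  cached("biased_fit", function() fit_chemotaxis(biased_syn()$dataset))
}

# build a trajectory data frame from explicit per-frame body angles:
# the midpoint walks along +x, tail/head placed from the given angles
traj_from_angles <- function(tail_angle_deg, head_angle_deg = 0,
                             dt_s = 0.0625, dish = "d1", animal = "a1",
                             mid_x = NULL, mid_y = NULL, L = 2.15) {
  n <- length(tail_angle_deg)
  head_angle_deg <- rep_len(head_angle_deg, n)
  if (is.null(mid_x)) mid_x <- seq(0, by = 0.0625, length.out = n)
  if (is.null(mid_y)) mid_y <- rep(0, n)
  th <- tail_angle_deg * pi / 180
  ha <- (tail_angle_deg + head_angle_deg) * pi / 180
  df <- data.frame(t_s = (seq_len(n) - 1L) * dt_s,
                   head_x_mm = mid_x + L * cos(ha),
                   head_y_mm = mid_y + L * sin(ha),
                   mid_x_mm = mid_x, mid_y_mm = mid_y,
                   tail_x_mm = mid_x - L * cos(th),
                   tail_y_mm = mid_y - L * sin(th))
  attr(df, "dish_id") <- dish
  attr(df, "animal_id") <- animal
  attr(df, "frame_dt_s") <- dt_s
  df
}

# hand-built kinematic series for detector unit tests
kin_series <- function(tail_angle_deg, head_angle_deg = 0,
                       bearing_deg = 0, distance_mm = 45, dt_s = 0.0625) {
  n <- length(tail_angle_deg)
  uw <- unwrap_angle(tail_angle_deg)
  d <- numeric(n)
  if (n >= 2) {
    d[1] <- (uw[2] - uw[1]) / dt_s
    d[n] <- (uw[n] - uw[n - 1]) / dt_s
    if (n > 2) d[2:(n - 1)] <- (uw[3:n] - uw[1:(n - 2)]) / (2 * dt_s)
  }
  out <- data.frame(t_s = (seq_len(n) - 1L) * dt_s,
                    tail_angle_deg = wrap_angle(tail_angle_deg),
                    heading_deg = wrap_angle(tail_angle_deg +
                                             rep_len(head_angle_deg, n)),
                    head_angle_deg = rep_len(head_angle_deg, n),
                    reorientation_speed_deg_s = d,
                    bearing_deg = rep_len(bearing_deg, n),
                    distance_mm = rep_len(distance_mm, n),
                    speed_mm_s = rep_len(1, n),
                    mid_x_mm = rep_len(0, n), mid_y_mm = rep_len(0, n))
  attr(out, "dish_id") <- "d1"
  attr(out, "animal_id") <- "a1"
  attr(out, "frame_dt_s") <- dt_s
  class(out) <- c("kinematic_series", "data.frame")
  out
}

tiny_policy <- function(angles = c(-60, 40, 90), base_per_s = 2 / 60,
                        run_speed = 1) {
  behavioral_policy("parametric",
                    bank = data.frame(bearing_before_deg =
                                        rep_len(c(0, 90, 180), length(angles)),
                                      distance_mm = rep_len(45, length(angles)),
                                      turning_angle_deg = angles),
                    mean_rate_per_s = base_per_s,
                    run_speed_mm_s = run_speed,
                    base_rate_per_s = base_per_s)
}
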