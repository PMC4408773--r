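# Independent oracles used to cross-check the package's implementations.
# These are deliberately naive (explicit per-frame automaton, double loops
# over events) and share no code with the implementation paths they check.

# explicit two-state hysteresis automaton, stepped frame by frame
schmitt_oracle <- function(signal, high, low, min_duration_s, dt_s) {
  x <- abs(signal)
  n <- length(x)
  armed <- FALSE
  s <- integer(0); e <- integer(0); open <- NA_integer_
  for (i in seq_len(n)) {
    if (!armed && x[i] >= high) {
      armed <- TRUE; open <- i
    } else if (armed && x[i] <= low) {
      armed <- FALSE
      s <- c(s, open); e <- c(e, i)
    }
  }
  if (armed) { s <- c(s, open); e <- c(e, n) }
  keep <- (e - s) * dt_s >= min_duration_s
  data.frame(i_start = s[keep], i_end = e[keep])
}

# brute-force circular sliding-window rate profile
profile_oracle <- function(turn_b, frame_b, dt_s, hw = 30, step = 1) {
  grid <- seq(-180, 180, by = step)
  vapply(grid, function(g) {
    nt <- sum(abs(wrap_angle(turn_b - g)) <= hw)
    occ <- sum(rep(dt_s, length(frame_b))[abs(wrap_angle(frame_b - g)) <= hw])
    if (occ > 0) 60 * nt / occ else NA_real_
  }, 0)
}

# brute-force 2D box-filter rate map (bearing circular, distance linear)
rate_map_oracle <- function(turn_b, turn_d, frame_b, frame_d, dt_s,
                            bgrid, dgrid, hwb = 30, hwd = 15) {
  out <- matrix(NA_real_, length(bgrid), length(dgrid))
  for (i in seq_along(bgrid)) for (j in seq_along(dgrid)) {
    nt <- 0
    for (k in seq_along(turn_b))
      if (abs(wrap_angle(turn_b[k] - bgrid[i])) <= hwb &&
          abs(turn_d[k] - dgrid[j]) <= hwd) nt <- nt + 1
    occ <- 0
    for (k in seq_along(frame_b))
      if (abs(wrap_angle(frame_b[k] - bgrid[i])) <= hwb &&
          abs(frame_d[k] - dgrid[j]) <= hwd) occ <- occ + dt_s
    if (occ > 0) out[i, j] <- 60 * nt / occ
  }
  out
}
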