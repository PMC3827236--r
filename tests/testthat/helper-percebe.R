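# shared fixtures, all built in code

# a profile record with constant velocities everywhere
constant_series <- function(u = 0, v = 0, days = 70,
                            start = "2009-07-01 00:00:00") {
  start <- as.POSIXct(start, tz = "UTC")
  time <- seq(start, start + days * 86400, by = 1800)
  n <- length(time)
  velocity_profiles(time, matrix(u, n, 10), matrix(v, n, 10))
}

# season-mean length scales of the high- and low-upwelling study summers
scales_2009 <- list(LA_x = -56.12, LS_x = 42.790, LA_y = -67.79, LS_y = 46.645)
scales_2011 <- list(LA_x = 12.95, LS_x = 24.294, LA_y = 31.61, LS_y = 28.478)

# one-release-event schedule (only stage durations and layers matter)
single_event_schedule <- function(at = "2009-07-01 00:00:00") {
  larval_schedule(at, at)
}

# theoretical expected total-variation distance between a multinomial
# sample of size n and its generating cell probabilities
tv_expected <- function(kernel, n) {
  0.5 * sqrt(2 / (pi * n)) * sum(sqrt(kernel$prob * (1 - kernel$prob)))
}
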