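# profile ingestion and stage-structured dispersal length scales

test_that("CSV round trip preserves the record apart from the surface copy", {
  s <- gen_currents(regime_2009(), "2009-07-01", "2009-07-03", seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles_csv(s, path)
  back <- load_profiles(path)
  expect_equal(back$time, s$time)
  expect_equal(back$u[, 2:10], s$u[, 2:10], tolerance = 1e-9,
               ignore_attr = TRUE)
  # surface cell is the 2-4 m cell repeated
  expect_equal(back$u[, 1], s$u[, 2], tolerance = 1e-9)
  expect_equal(back$v[, 1], s$v[, 2], tolerance = 1e-9)
})

test_that("a missing 0-2 m cell is filled from the 2-4 m measurement", {
  time <- seq(as.POSIXct("2009-07-01", tz = "UTC"), by = 1800, length.out = 8)
  df <- expand.grid(timestamp = format(time, "%Y-%m-%d %H:%M:%S"),
                    depth_cell_top_m = seq(2, 18, by = 2))  # no 0-2 m rows
  df$u_cm_s <- ifelse(df$depth_cell_top_m == 2, 5, 1)
  df$v_cm_s <- ifelse(df$depth_cell_top_m == 2, -3, 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  s <- load_profiles(path)
  expect_equal(s$u[, 1], rep(5, 8))
  expect_equal(s$v[, 1], rep(-3, 8))
})

test_that("short gaps are linearly interpolated, long gaps stay masked", {
  s <- constant_series(u = 2, v = 0, days = 3)
  n <- length(s$time)
  s$u[, 5] <- seq(0, 10, length.out = n)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles_csv(s, path)
  df <- read.csv(path)
  full <- df
  # a 1-h gap (2 samples) in the 8-10 m cell
  drop1 <- which(df$depth_cell_top_m == 8)[10:11]
  # a 12-h gap (24 samples), beyond the 3-h interpolation limit
  drop2 <- which(df$depth_cell_top_m == 12)[40:63]
  df$u_cm_s[c(drop1, drop2)] <- NA
  df$v_cm_s[c(drop1, drop2)] <- NA
  write.csv(df, path, row.names = FALSE)
  s2 <- load_profiles(path)
  # linear interpolant of the neighbours restores the linear ramp exactly
  expect_equal(s2$u[10:11, 5], s$u[10:11, 5], tolerance = 1e-9)
  expect_true(all(is.na(s2$u[40:63, 7])))
  expect_true(all(!s2$gap_mask[40:63]))
  expect_true(s2$gap_mask[10])
})

test_that("heavily masked records warn and non-uniform cadence is rejected", {
  s <- constant_series(days = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles_csv(s, path)
  df <- read.csv(path)
  df$u_cm_s[df$depth_cell_top_m == 10][1:50] <- NA  # > 20% of 97 samples
  write.csv(df, path, row.names = FALSE)
  expect_warning(load_profiles(path), "masked")

  df2 <- read.csv(path)
  df2 <- df2[df2$timestamp != df2$timestamp[11], ]  # remove one time step
  write.csv(df2, path, row.names = FALSE)
  expect_error(load_profiles(path), "non-uniform cadence")
})

test_that("constant currents give the closed-form advective scale and zero spread", {
  # 1 cm/s over 60 days is 51.84 km exactly (unit audit)
  s <- constant_series(u = -1, v = 0)
  ev <- event_length_scales(s, "2009-07-01 00:00:00",
                            single_event_schedule())
  expect_equal(ev$LA_x, -51.84, tolerance = 1e-12)
  expect_equal(ev$LA_y, 0)
  expect_equal(ev$LS_x, 0)
  expect_equal(ev$LS_y, 0)

  z <- constant_series(u = 0, v = 0)
  ev0 <- event_length_scales(z, "2009-07-01 00:00:00",
                             single_event_schedule())
  expect_equal(unlist(ev0[c("LA_x", "LA_y", "LS_x", "LS_y")]),
               c(LA_x = 0, LA_y = 0, LS_x = 0, LS_y = 0))
})

test_that("a +/- 9.04 cm/s alternating current reproduces the stochastic scale formula", {
  s <- constant_series(u = 0, v = 0)
  n <- length(s$time)
  s$u[] <- rep(c(9.04, -9.04), length.out = n)   # sample SD ~ 9.04 in each phase
  ev <- event_length_scales(s, "2009-07-01 00:00:00",
                            single_event_schedule())
  # LS = sigma * sqrt(tau_L * T): 0.0904 m/s over 60 d with tau_L = 12 h
  expect_equal(ev$LS_x, 0.0904 * sqrt(43200 * 5184000) / 1000,
               tolerance = 1e-3)
  expect_equal(ev$LA_x, 0, tolerance = 0.2)
})

test_that("stage scheduling weights each layer by its stage duration", {
  s <- constant_series(u = 0, v = 0)
  s$v[, 1:5] <- 2     # surface layer (nauplius phase)
  s$v[, 6:10] <- -1   # bottom layer (cyprid phase)
  ev <- event_length_scales(s, "2009-07-01 00:00:00",
                            single_event_schedule())
  expect_equal(ev$LA_y, (2 - 1) * 2592000 / 1e5, tolerance = 1e-9)
})

test_that("the release schedule enumerates one event every 30 min, endpoints inclusive", {
  sched <- larval_schedule("2009-07-01 00:00:00", "2009-10-02 00:00:00")
  expect_length(release_times(sched), 93 * 48 + 1)
})

test_that("season scales collapse to closed-form values as noise vanishes", {
  r <- flow_regime("calm", -1, -0.5, -1, -0.5, 0.05, 0.05, 0.05, 0.05)
  s <- gen_currents(r, "2009-07-01", "2009-09-15", seed = 5,
                    cell_noise_sd = 0)
  sched <- larval_schedule("2009-07-01 00:00:00", "2009-07-05 00:00:00")
  sls <- season_length_scales(s, sched)
  m <- setNames(sls$summary$mean, sls$summary$metric)
  expect_equal(m[["LA_x"]], -51.84, tolerance = 0.02)
  expect_equal(m[["LA_y"]], -25.92, tolerance = 0.02)
  expect_lt(m[["LS_x"]], 0.5)
  expect_true(all(sls$summary$sd < 0.2))
})

test_that("season mean scales from the high-upwelling regime are statistically consistent", {
  r <- regime_2009()
  s <- gen_currents(r, "2009-07-01", "2009-12-01", seed = 7)
  sched <- larval_schedule("2009-07-01 00:00:00", "2009-10-02 00:00:00")
  sls <- season_length_scales(s, sched, year = 2009)
  expect_identical(sls$n_events, 4465L)
  m <- setNames(sls$summary$mean, sls$summary$metric)
  # sampling SE of a season-mean advective scale: T_pld * sigma * sqrt(2
  # tau / T_season), about 38 km at these parameters
  se_la <- 51.84 * r$surface_sd_u * sqrt(2 * 12 / (153 * 24))
  expect_lt(abs(m[["LA_x"]] - (-56.12)), 2 * se_la)
  se_la_y <- 51.84 * r$surface_sd_v * sqrt(2 * 12 / (153 * 24))
  expect_lt(abs(m[["LA_y"]] - (-67.79)), 2 * se_la_y)
  # stochastic scales are tightly estimated within events
  expect_equal(m[["LS_x"]], 42.79, tolerance = 0.10)
  expect_equal(m[["LS_y"]], 46.645, tolerance = 0.10)
})

test_that("length scales are linear in the currents", {
  s <- gen_currents(regime_2011(), "2009-07-01", "2009-09-10", seed = 11)
  ev <- event_length_scales(s, "2009-07-01 00:00:00",
                            single_event_schedule())
  s2 <- s
  s2$u <- -2 * s$u
  s2$v <- -2 * s$v
  ev2 <- event_length_scales(s2, "2009-07-01 00:00:00",
                             single_event_schedule())
  expect_equal(ev2$LA_x, -2 * ev$LA_x, tolerance = 1e-9)
  expect_equal(ev2$LA_y, -2 * ev$LA_y, tolerance = 1e-9)
  expect_equal(ev2$LS_x, 2 * ev$LS_x, tolerance = 1e-9)
  expect_equal(ev2$LS_y, 2 * ev$LS_y, tolerance = 1e-9)
})

test_that("reversing a stationary record leaves season means nearly unchanged", {
  s <- gen_currents(regime_2009(), "2009-07-01", "2009-10-15", seed = 13)
  n <- length(s$time)
  rev_s <- velocity_profiles(s$time, s$u[n:1, ], s$v[n:1, ])
  sched <- larval_schedule("2009-07-01 00:00:00", "2009-08-15 00:00:00")
  a <- season_length_scales(s, sched)$summary
  b <- season_length_scales(rev_s, sched)$summary
  expect_equal(a$mean[1:2], b$mean[1:2], tolerance = 0.2, ignore_attr = TRUE)
  expect_equal(a$mean[3:4], b$mean[3:4], tolerance = 0.05, ignore_attr = TRUE)
})

test_that("uncovered events are excluded rather than truncated", {
  s <- gen_currents(regime_2009(), "2009-07-01", "2009-09-15", seed = 15)
  sched <- larval_schedule("2009-07-01 00:00:00", "2009-07-20 00:00:00")
  sls <- season_length_scales(s, sched)
  # releases after 17 July (76-day record minus 60-day drift) lack coverage
  expect_lt(sls$n_events, nrow(sls$events))
  expect_true(all(is.na(sls$events$LA_x[!sls$events$valid])))
  expect_error(
    season_length_scales(s, larval_schedule("2009-09-10 00:00:00",
                                            "2009-09-14 00:00:00")),
    "no release event")
})

test_that("axis-independence R^2 is 1 for identical axes and 0 for a constant axis", {
  s <- constant_series(days = 4)
  n <- length(s$time)
  s$u[] <- matrix(rnorm(n * 10), n)
  s$v <- s$u
  r2 <- check_axis_independence(s)$r_squared
  expect_equal(r2, rep(1, 10), tolerance = 1e-12)
  s$v[] <- 3
  expect_equal(check_axis_independence(s)$r_squared, rep(0, 10))
})

test_that("season velocity profile averages each depth cell over the window", {
  s <- constant_series(u = -1.5, v = -0.8, days = 10)
  prof <- season_velocity_profile(s, c("2009-07-02", "2009-07-08"))
  expect_equal(prof$u_mean, rep(-1.5, 10))
  expect_equal(prof$v_mean, rep(-0.8, 10))
  expect_error(season_velocity_profile(s, c("2010-01-01", "2010-01-02")),
               "empty window")
})

test_that("the two canonical regimes show the expected vertical flow structure", {
  s09 <- gen_currents(regime_2009(), "2009-07-01", "2009-11-30", seed = 17)
  p09 <- season_velocity_profile(s09, c("2009-07-01", "2009-11-30"))
  expect_true(all(p09$u_mean < 0))   # westward at all depths
  expect_true(all(p09$v_mean < 0))   # onshore at all depths

  s11 <- gen_currents(regime_2011(), "2011-07-01", "2011-11-30", seed = 19)
  p11 <- season_velocity_profile(s11, c("2011-07-01", "2011-11-30"))
  expect_true(all(p11$v_mean[1:5] > 0))    # offshore surface layer
  expect_true(all(p11$v_mean[6:10] < 0))   # onshore bottom layer
})
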