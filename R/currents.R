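# Current-profile ingestion and stage-structured dispersal length scales.
#
# Conventions used throughout: x is alongshore (+east), y is cross-shore
# (+north = offshore); the coast lies along y = 0 with land at y < 0.
# Velocities are cm s^-1, length scales km.

#' Construct a velocity-profile time series
#'
#' Container for a moored current-profiler record: u (eastward) and v
#' (northward) velocities on a uniform 30-minute time base in 10 two-metre
#' depth cells with top depths 0, 2, ..., 18 m.
#'
#' @param time POSIXct vector, uniform cadence.
#' @param u,v Numeric matrices, `length(time)` rows by 10 depth-cell
#'   columns, cm s^-1.
#' @param depth_tops Top depth of each cell, m.
#' @param gap_mask Logical vector marking valid samples; defaults to rows
#'   where all cells are finite.
#' @return An object of class `velocity_profiles`.
#' @export
velocity_profiles <- function(time, u, v, depth_tops = seq(0, 18, by = 2),
                              gap_mask = NULL) {
  u <- as.matrix(u); v <- as.matrix(v)
  n <- length(time)
  if (nrow(u) != n || nrow(v) != n)
    stop("velocity_profiles: u and v must have one row per time step")
  if (ncol(u) != length(depth_tops) || ncol(v) != length(depth_tops))
    stop("velocity_profiles: expected ", length(depth_tops), " depth cells")
  if (n < 2) stop("velocity_profiles: need at least two time steps")
  steps <- diff(as.numeric(time))
  if (max(steps) - min(steps) > 1e-6)
    stop("velocity_profiles: non-uniform cadence")
  if (is.null(gap_mask)) {
    gap_mask <- stats::complete.cases(u) & stats::complete.cases(v)
  }
  if (any(!is.finite(u[gap_mask, ])) || any(!is.finite(v[gap_mask, ])))
    stop("velocity_profiles: non-finite velocities in valid samples")
  structure(list(time = time, depth_tops = depth_tops, u = u, v = v,
                 gap_mask = gap_mask, dt = steps[1]),
            class = "velocity_profiles")
}

#' @export
print.velocity_profiles <- function(x, ...) {
  cat("<velocity_profiles>", length(x$time), "samples at",
      x$dt / 60, "min cadence,", ncol(x$u), "depth cells\n")
  cat("  ", format(x$time[1]), "to", format(x$time[length(x$time)]), "UTC\n")
  cat("  valid samples:", sum(x$gap_mask), sprintf("(%.1f%%)\n",
      100 * mean(x$gap_mask)))
  invisible(x)
}

#' Write a velocity-profile series to long-format CSV
#'
#' Columns: `timestamp` (UTC), `depth_cell_top_m`, `u_cm_s`, `v_cm_s`.
#'
#' @param series A [velocity_profiles()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(series, path) {
  n <- length(series$time); k <- length(series$depth_tops)
  df <- data.frame(
    timestamp = format(rep(series$time, each = k), "%Y-%m-%d %H:%M:%S",
                       tz = "UTC"),
    depth_cell_top_m = rep(series$depth_tops, n),
    u_cm_s = as.vector(t(series$u)),
    v_cm_s = as.vector(t(series$v))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load a velocity-profile series from CSV
#'
#' Reads a long-format profile record (columns `timestamp`,
#' `depth_cell_top_m`, `u_cm_s`, `v_cm_s`) and applies the standard
#' preprocessing for a nearshore ADCP deployment:
#' the instrument cannot measure the top of the water column, so the 0--2 m
#' surface cell is filled by copying the 2--4 m cell; gaps of up to 3 h are
#' filled by linear interpolation in time, while longer gaps remain masked.
#' A warning is raised when more than 20% of the samples stay masked.
#'
#' @param path CSV file path.
#' @return A [velocity_profiles()] object.
#' @export
load_profiles <- function(path) {
  if (!file.exists(path)) stop("load_profiles: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "depth_cell_top_m", "u_cm_s", "v_cm_s")
  if (!all(need %in% names(df)))
    stop("load_profiles: expected columns ", paste(need, collapse = ", "))
  time <- sort(unique(as.POSIXct(df$timestamp, tz = "UTC")))
  steps <- diff(as.numeric(time))
  if (length(unique(steps)) != 1)
    stop("load_profiles: non-uniform cadence in ", path)
  depth_tops <- seq(0, 18, by = 2)
  n <- length(time); k <- length(depth_tops)
  u <- matrix(NA_real_, n, k); v <- matrix(NA_real_, n, k)
  ti <- match(as.numeric(as.POSIXct(df$timestamp, tz = "UTC")), as.numeric(time))
  di <- match(df$depth_cell_top_m, depth_tops)
  keep <- !is.na(ti) & !is.na(di)
  u[cbind(ti[keep], di[keep])] <- df$u_cm_s[keep]
  v[cbind(ti[keep], di[keep])] <- df$v_cm_s[keep]

  # surface extrapolation: the 0-2 m cell repeats the 2-4 m measurement
  u[, 1] <- u[, 2]
  v[, 1] <- v[, 2]

  # interpolate gaps of up to 3 h (6 samples at 30-min cadence)
  max_gap <- floor(3 * 3600 / steps[1])
  fill <- function(m) {
    apply(m, 2, function(col)
      zoo::na.approx(col, x = as.numeric(time), maxgap = max_gap, na.rm = FALSE))
  }
  u <- fill(u); v <- fill(v)

  mask <- stats::complete.cases(u) & stats::complete.cases(v)
  if (mean(!mask) > 0.2)
    warning(sprintf("load_profiles: %.1f%% of samples remain masked",
                    100 * mean(!mask)))
  velocity_profiles(time, u, v, depth_tops = depth_tops, gap_mask = mask)
}

#' Define a larval release schedule
#'
#' Stage-structured transport schedule: larvae are released at a fixed
#' interval throughout the spawning window, drift `nauplius_days` in the
#' surface layer (0--10 m) as nauplii, then sink and drift `cyprid_days`
#' in the bottom layer (10--20 m) as cyprids, for a pelagic larval duration
#' of `nauplius_days + cyprid_days` (60 days by default).
#'
#' @param release_start,release_end First and last release instants
#'   (coerced to POSIXct, UTC); both are included in the schedule.
#' @param release_interval Interval between releases, seconds (default
#'   1800, i.e. one release every 30 minutes).
#' @param nauplius_days Days spent in the surface layer.
#' @param cyprid_days Days spent in the bottom layer.
#' @return An object of class `larval_schedule`.
#' @export
larval_schedule <- function(release_start, release_end,
                            release_interval = 1800,
                            nauplius_days = 30, cyprid_days = 30) {
  release_start <- as.POSIXct(release_start, tz = "UTC")
  release_end <- as.POSIXct(release_end, tz = "UTC")
  if (release_end < release_start)
    stop("larval_schedule: release_end before release_start")
  structure(list(release_start = release_start, release_end = release_end,
                 release_interval = release_interval,
                 nauplius_days = nauplius_days, cyprid_days = cyprid_days,
                 surface_cells = 1:5, bottom_cells = 6:10),
            class = "larval_schedule")
}

#' Enumerate the release instants of a schedule
#'
#' @param schedule A [larval_schedule()].
#' @return POSIXct vector of release times (both endpoints inclusive).
#' @export
release_times <- function(schedule) {
  seq(schedule$release_start, schedule$release_end,
      by = schedule$release_interval)
}

# rolling window mean/sd over fixed-width windows starting at `starts`,
# via cumulative sums; windows containing any NA give NA
.roll_stats <- function(x, w, starts) {
  bad <- !is.finite(x)
  x0 <- ifelse(bad, 0, x)
  cs <- c(0, cumsum(x0))
  cs2 <- c(0, cumsum(x0^2))
  cbad <- c(0, cumsum(bad))
  nbad <- cbad[starts + w] - cbad[starts]
  m <- (cs[starts + w] - cs[starts]) / w
  v <- (cs2[starts + w] - cs2[starts]) / w - m^2
  v <- pmax(v, 0) * w / (w - 1)
  m[nbad > 0] <- NA_real_
  v[nbad > 0] <- NA_real_
  list(mean = m, sd = sqrt(v))
}

# length scales for events starting at sample indices `start_idx`
.event_scales <- function(series, start_idx, schedule, decorrelation_hours) {
  spd <- 86400 / series$dt                      # samples per day
  n_s <- as.integer(round(schedule$nauplius_days * spd))
  n_b <- as.integer(round(schedule$cyprid_days * spd))
  n <- length(series$time)
  T_s <- schedule$nauplius_days * 86400
  T_b <- schedule$cyprid_days * 86400
  tau <- decorrelation_hours * 3600

  covered <- start_idx >= 1 & (start_idx + n_s + n_b - 1) <= n
  la <- matrix(NA_real_, length(start_idx), 2,
               dimnames = list(NULL, c("x", "y")))
  ls <- la
  if (any(covered)) {
    s_idx <- start_idx[covered]
    for (axis in c("x", "y")) {
      m <- if (axis == "x") series$u else series$v
      m[!series$gap_mask, ] <- NA_real_
      surf <- rowMeans(m[, schedule$surface_cells, drop = FALSE])
      bot <- rowMeans(m[, schedule$bottom_cells, drop = FALSE])
      rs <- .roll_stats(surf, n_s, s_idx)
      rb <- .roll_stats(bot, n_b, s_idx + n_s)
      la[covered, axis] <- (rs$mean * T_s + rb$mean * T_b) / 1e5
      ls[covered, axis] <- sqrt(tau * (rs$sd^2 * T_s + rb$sd^2 * T_b)) / 1e5
    }
  }
  data.frame(release_time = series$time[pmin(pmax(start_idx, 1L), n)],
             LA_x = la[, "x"], LA_y = la[, "y"],
             LS_x = ls[, "x"], LS_y = ls[, "y"],
             valid = covered & stats::complete.cases(la) &
               stats::complete.cases(ls))
}

#' Dispersal length scales for a single release event
#'
#' Computes the advective (L_A) and stochastic (L_S) dispersal length
#' scales experienced by a cohort released at `release_time`.  Per stage,
#' the layer velocity is the mean over the layer's five depth cells at each
#' 30-min sample; L_A sums the stage-mean velocities times the stage
#' durations, and L_S combines the within-stage SD of the layer-mean
#' samples with the Lagrangian decorrelation time:
#' `LS = sqrt(tau_L * (sd_surf^2 * T_surf + sd_bot^2 * T_bot))`.
#' Both axes are treated independently; outputs are km.
#'
#' @param series A [velocity_profiles()] record covering the full pelagic
#'   larval duration from `release_time`.
#' @param release_time Release instant (POSIXct or coercible), must fall on
#'   a sample of the record.
#' @param schedule A [larval_schedule()] (its release window is ignored
#'   here; only stage durations and layers are used).
#' @param decorrelation_hours Lagrangian decorrelation time, hours
#'   (default 12, typical of nearshore coastal flow).
#' @return One-row data frame of class `event_length_scales` with columns
#'   `release_time`, `LA_x`, `LA_y`, `LS_x`, `LS_y`, `valid`.
#' @export
event_length_scales <- function(series, release_time,
                                schedule = larval_schedule(release_time,
                                                           release_time),
                                decorrelation_hours = 12) {
  stopifnot(inherits(series, "velocity_profiles"))
  release_time <- as.POSIXct(release_time, tz = "UTC")
  idx <- .time_index(series, release_time)
  out <- .event_scales(series, idx, schedule, decorrelation_hours)
  if (!out$valid[1])
    stop("event_length_scales: record does not cover the pelagic larval ",
         "duration from ", format(release_time))
  class(out) <- c("event_length_scales", "data.frame")
  out
}

.time_index <- function(series, when) {
  idx <- round((as.numeric(when) - as.numeric(series$time[1])) / series$dt) + 1
  on_grid <- abs(as.numeric(when) -
                   (as.numeric(series$time[1]) + (idx - 1) * series$dt)) < 1
  if (any(!on_grid))
    stop("release time not on the record's time grid")
  as.integer(idx)
}

#' Season ensemble of dispersal length scales
#'
#' Enumerates every release of the schedule (one every 30 minutes from the
#' start through the end of the spawning window, both inclusive) and
#' computes per-event length scales.  Events whose 60-day drift is not
#' fully covered by valid samples are flagged invalid and excluded from the
#' summary rather than truncated, since truncation would bias the scales
#' toward early-season conditions.
#'
#' @inheritParams event_length_scales
#' @param year Optional label for the season.
#' @return An object of class `season_length_scales`: a list with `year`,
#'   `events` (per-event data frame), `n_events` (number of valid events)
#'   and `summary` (mean and SD of each scale over valid events).
#' @export
season_length_scales <- function(series, schedule, decorrelation_hours = 12,
                                 year = NULL) {
  stopifnot(inherits(series, "velocity_profiles"),
            inherits(schedule, "larval_schedule"))
  rel <- release_times(schedule)
  idx <- .time_index(series, rel)
  ev <- .event_scales(series, idx, schedule, decorrelation_hours)
  if (!any(ev$valid))
    stop("season_length_scales: no release event is fully covered")
  ok <- ev$valid
  cols <- c("LA_x", "LA_y", "LS_x", "LS_y")
  summ <- data.frame(
    metric = cols,
    mean = vapply(cols, function(cl) mean(ev[[cl]][ok]), numeric(1)),
    sd = vapply(cols, function(cl) stats::sd(ev[[cl]][ok]), numeric(1)),
    row.names = NULL
  )
  structure(list(year = year, events = ev, n_events = sum(ok),
                 summary = summ),
            class = "season_length_scales")
}

#' @export
print.season_length_scales <- function(x, ...) {
  cat("<season_length_scales>", if (!is.null(x$year)) x$year else "",
      "-", x$n_events, "valid events of", nrow(x$events), "\n")
  print(transform(x$summary, mean = round(mean, 2), sd = round(sd, 2)))
  invisible(x)
}

#' Test independence of the alongshore and cross-shore currents
#'
#' Ordinary least-squares R-squared of v on u for each depth cell, the
#' check behind treating the two axes of the dispersal kernel as
#' uncorrelated.  A constant axis gives R-squared 0.
#'
#' @param series A [velocity_profiles()] object with at least 100 valid
#'   samples.
#' @return Data frame with columns `depth_top_m` and `r_squared`.
#' @export
check_axis_independence <- function(series) {
  stopifnot(inherits(series, "velocity_profiles"))
  ok <- series$gap_mask
  if (sum(ok) < 100)
    stop("check_axis_independence: need at least 100 valid samples")
  r2 <- vapply(seq_along(series$depth_tops), function(j) {
    u <- series$u[ok, j]; v <- series$v[ok, j]
    if (stats::sd(u) == 0 || stats::sd(v) == 0) return(0)
    stats::cor(u, v)^2
  }, numeric(1))
  data.frame(depth_top_m = series$depth_tops, r_squared = r2)
}

#' Season-mean velocity profile
#'
#' Mean u and v per 2-m depth cell over a date window, the standard view of
#' the vertical flow structure during the larval season.
#'
#' @param series A [velocity_profiles()] object.
#' @param window Length-2 vector (coercible to POSIXct) giving the
#'   averaging window; samples with `window[1] <= t <= window[2]` are used.
#' @return Data frame with columns `depth_top_m`, `u_mean`, `v_mean`
#'   (cm s^-1).
#' @export
season_velocity_profile <- function(series, window) {
  stopifnot(inherits(series, "velocity_profiles"))
  w <- as.POSIXct(window, tz = "UTC")
  sel <- series$time >= w[1] & series$time <= w[2] & series$gap_mask
  if (!any(sel)) stop("season_velocity_profile: empty window")
  data.frame(depth_top_m = series$depth_tops,
             u_mean = colMeans(series$u[sel, , drop = FALSE]),
             v_mean = colMeans(series$v[sel, , drop = FALSE]))
}
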