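# Synthetic data generators: layered nearshore currents, coastal winds and
# catch/effort tables with known ground truth.  Every generator is seeded and
# bit-reproducible, so each downstream stage can be tested against the
# parameters that produced its input.

#' Define a two-layer nearshore flow regime
#'
#' A flow regime is the ground truth behind [gen_currents()]: mean eastward
#' (`u`) and northward (`v`) velocity plus a fluctuation standard deviation
#' for each of the two depth layers (surface 0--10 m, bottom 10--20 m), and a
#' Lagrangian decorrelation time for the fluctuations.  Velocities are in
#' cm s^-1 with +u east and +v north (offshore); the coast runs along y = 0
#' with land to the south.
#'
#' @param name Label for the regime (e.g. `"2009-like"`).
#' @param surface_mean_u,surface_mean_v Mean velocity of the 0--10 m layer
#'   (cm s^-1).
#' @param bottom_mean_u,bottom_mean_v Mean velocity of the 10--20 m layer
#'   (cm s^-1).
#' @param surface_sd_u,surface_sd_v Standard deviation of the surface-layer
#'   fluctuations on each axis (cm s^-1); must be >= 0.
#' @param bottom_sd_u,bottom_sd_v Same for the bottom layer.
#' @param decorrelation_time Lagrangian decorrelation time of the
#'   fluctuations, in hours (> 0).  12 h is typical of nearshore coastal
#'   flow.
#' @return An object of class `flow_regime` (a named list).
#' @seealso [regime_2009()], [regime_2011()], [regime_from_length_scales()]
#' @export
flow_regime <- function(name,
                        surface_mean_u, surface_mean_v,
                        bottom_mean_u, bottom_mean_v,
                        surface_sd_u, surface_sd_v,
                        bottom_sd_u, bottom_sd_v,
                        decorrelation_time = 12) {
  sds <- c(surface_sd_u, surface_sd_v, bottom_sd_u, bottom_sd_v)
  if (any(sds < 0)) stop("flow_regime: standard deviations must be >= 0")
  if (decorrelation_time <= 0) stop("flow_regime: decorrelation_time must be > 0")
  structure(list(
    name = name,
    surface_mean_u = surface_mean_u, surface_mean_v = surface_mean_v,
    bottom_mean_u = bottom_mean_u, bottom_mean_v = bottom_mean_v,
    surface_sd_u = surface_sd_u, surface_sd_v = surface_sd_v,
    bottom_sd_u = bottom_sd_u, bottom_sd_v = bottom_sd_v,
    decorrelation_time = decorrelation_time
  ), class = "flow_regime")
}

#' @export
print.flow_regime <- function(x, ...) {
  cat("<flow_regime>", x$name, "\n")
  cat(sprintf("  surface (0-10 m): mean (%.3f, %.3f) cm/s, sd (%.3f, %.3f)\n",
              x$surface_mean_u, x$surface_mean_v, x$surface_sd_u, x$surface_sd_v))
  cat(sprintf("  bottom (10-20 m): mean (%.3f, %.3f) cm/s, sd (%.3f, %.3f)\n",
              x$bottom_mean_u, x$bottom_mean_v, x$bottom_sd_u, x$bottom_sd_v))
  cat(sprintf("  decorrelation time: %g h\n", x$decorrelation_time))
  invisible(x)
}

#' Back-compute a stationary flow regime from dispersal length scales
#'
#' Inverts the length-scale relations L_A = u * T and
#' L_S = sigma * sqrt(tau_L * T) to recover the mean velocity and fluctuation
#' standard deviation that, held uniformly over both layers, reproduce a
#' given set of season-mean dispersal length scales over a 60-day pelagic
#' larval duration.
#'
#' @param name Regime label.
#' @param LA_x,LA_y Advective length scales, km (+east/+north).
#' @param LS_x,LS_y Stochastic length scales, km (>= 0).
#' @param pld_days Pelagic larval duration in days (default 60).
#' @param decorrelation_time Decorrelation time, hours (default 12).
#' @return A `flow_regime` with identical surface and bottom parameters.
#' @export
regime_from_length_scales <- function(name, LA_x, LS_x, LA_y, LS_y,
                                      pld_days = 60, decorrelation_time = 12) {
  T_sec <- pld_days * 86400
  tau_sec <- decorrelation_time * 3600
  u <- LA_x * 1e5 / T_sec            # km -> cm, / s  => cm s^-1
  v <- LA_y * 1e5 / T_sec
  su <- LS_x * 1e5 / sqrt(tau_sec * T_sec)
  sv <- LS_y * 1e5 / sqrt(tau_sec * T_sec)
  flow_regime(name,
              surface_mean_u = u, surface_mean_v = v,
              bottom_mean_u = u, bottom_mean_v = v,
              surface_sd_u = su, surface_sd_v = sv,
              bottom_sd_u = su, bottom_sd_v = sv,
              decorrelation_time = decorrelation_time)
}

#' Canonical high-upwelling ("2009-like") flow regime
#'
#' Westward and onshore mean flow throughout the water column, the situation
#' observed during a summer of intense upwelling: surface waters are dragged
#' west by northeasterly winds and an onshore return flow spans the column.
#' Parameters are back-computed from the season-mean dispersal length scales
#' of that summer (alongshore L_A = -56.12 km, L_S = 42.79 km; cross-shore
#' L_A = -67.79 km, L_S = 46.645 km over a 60-d larval duration with a 12-h
#' decorrelation time), giving a mean flow of about (-1.08, -1.31) cm s^-1
#' and fluctuation SDs of about (9.0, 9.9) cm s^-1.
#'
#' @return A `flow_regime`.
#' @export
regime_2009 <- function() {
  regime_from_length_scales("2009-like",
                            LA_x = -56.12, LS_x = 42.790,
                            LA_y = -67.79, LS_y = 46.645)
}

#' Canonical low-upwelling ("2011-like") flow regime
#'
#' Weak eastward alongshore flow with vertically sheared cross-shore
#' circulation: offshore (seaward) transport in the surface layer and a weak
#' onshore flow at depth, the situation of a summer when upwelled water was
#' confined to the bottom layer.  The layer means are chosen so the
#' column-scheduled larvae experience the season-mean length scales of that
#' summer (alongshore L_A = 12.95 km, L_S = 24.294 km; cross-shore
#' L_A = 31.61 km, L_S = 28.478 km): the surface layer moves offshore at
#' 2.0 cm s^-1 and the bottom layer onshore at -0.78 cm s^-1, their
#' stage-weighted mean matching 31.61 km over the 60-d larval duration.
#'
#' @return A `flow_regime`.
#' @export
regime_2011 <- function() {
  base <- regime_from_length_scales("2011-like",
                                    LA_x = 12.95, LS_x = 24.294,
                                    LA_y = 31.61, LS_y = 28.478)
  # split the cross-shore mean into offshore surface / onshore bottom flow
  # while keeping the stage-weighted mean (and hence LA_y) unchanged
  v_mean <- base$surface_mean_v
  base$surface_mean_v <- 2.0
  base$bottom_mean_v <- 2 * v_mean - 2.0
  base
}

#' Generate a synthetic current-profile record
#'
#' Emulates a moored ADCP record: velocities every 30 minutes in 10
#' two-metre depth cells spanning 0--20 m.  Each axis of each layer follows
#' a stationary AR(1) process around the regime mean with lag-1 coefficient
#' `exp(-dt / decorrelation_time)`, so fluctuations decay with the regime's
#' decorrelation time; the five cells of a layer share the layer process
#' plus small independent cell noise.  The u and v processes are generated
#' independently, mirroring the observed near-zero correlation between
#' alongshore and cross-shore currents.
#'
#' @param regime A [flow_regime()].
#' @param start,end Record limits (coerced to POSIXct, UTC); `end` must be
#'   after `start`.
#' @param seed Integer seed; fixing it reproduces the record bit-exactly.
#'   `NULL` uses the current RNG state.
#' @param cell_noise_sd SD of the independent per-cell noise (cm s^-1).
#' @param gap_fraction Optional fraction of samples to blank out in runs
#'   (default 0), for exercising gap handling downstream.
#' @return A [velocity_profiles()] object.
#' @export
gen_currents <- function(regime, start, end, seed = NULL,
                         cell_noise_sd = 0.3, gap_fraction = 0) {
  stopifnot(inherits(regime, "flow_regime"))
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  if (!isTRUE(end > start)) stop("gen_currents: end must be after start")
  if (!is.null(seed)) set.seed(seed)

  dt_sec <- 1800
  time <- seq(start, end, by = dt_sec)
  n <- length(time)
  phi <- exp(-(dt_sec / 3600) / regime$decorrelation_time)

  layer_ar1 <- function(mu, sigma) {
    if (sigma == 0) return(rep(mu, n))
    innov <- stats::rnorm(n, sd = sigma * sqrt(1 - phi^2))
    x0 <- stats::rnorm(1, sd = sigma)
    mu + as.numeric(stats::filter(innov, phi, method = "recursive", init = x0))
  }

  u_surf <- layer_ar1(regime$surface_mean_u, regime$surface_sd_u)
  u_bot  <- layer_ar1(regime$bottom_mean_u, regime$bottom_sd_u)
  v_surf <- layer_ar1(regime$surface_mean_v, regime$surface_sd_v)
  v_bot  <- layer_ar1(regime$bottom_mean_v, regime$bottom_sd_v)

  cell <- function(layer) {
    if (cell_noise_sd == 0) {
      matrix(layer, n, 5)
    } else {
      layer + matrix(stats::rnorm(n * 5, sd = cell_noise_sd), n, 5)
    }
  }
  u <- cbind(cell(u_surf), cell(u_bot))
  v <- cbind(cell(v_surf), cell(v_bot))

  gap_mask <- rep(TRUE, n)
  if (gap_fraction > 0) {
    target <- round(gap_fraction * n)
    blanked <- 0L
    while (blanked < target) {
      len <- stats::rgeom(1, 1 / 6) + 1L
      at <- sample.int(n, 1L)
      idx <- at:min(n, at + len - 1L)
      blanked <- blanked + sum(gap_mask[idx])
      gap_mask[idx] <- FALSE
    }
    u[!gap_mask, ] <- NA_real_
    v[!gap_mask, ] <- NA_real_
  }

  velocity_profiles(time, u, v, gap_mask = gap_mask)
}

#' Generate a synthetic daily coastal wind record
#'
#' Emulates an airport anemometer record as daily wind vectors.  The mean
#' wind blows from `base_direction` (meteorological degrees, default 45 =
#' northeast) with a Gaussian seasonal envelope peaking in summer, plus
#' isotropic noise.  With the default northeasterly direction the summer
#' wind drives westward surface flow and offshore Ekman transport, i.e. a
#' unimodal upwelling-favourable season.  A mid-season reversal (negative
#' envelope, wind from the opposite quadrant) can be injected with
#' `reversal_depth` to emulate a summer whose middle turns
#' downwelling-favourable.
#'
#' @param year Calendar year of the record (one row per day).
#' @param seasonal_amplitude Peak mean wind speed of the seasonal envelope,
#'   km h^-1 (>= 0).
#' @param base_direction Meteorological direction the mean wind blows FROM,
#'   degrees clockwise from north.
#' @param noise_sd SD of the isotropic daily wind-vector noise, km h^-1.
#' @param peak_day Day of year of the envelope maximum.
#' @param peak_width Gaussian width of the envelope, days.
#' @param reversal_depth Depth of the mid-season reversal as a multiple of
#'   the envelope (0 = none; > 1 makes the mid-season mean wind reverse).
#' @param reversal_width Gaussian width of the reversal, days.
#' @param annual_strength Multiplier on the seasonal envelope, used to give
#'   individual years stronger or weaker upwelling seasons.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A data frame with columns `date`, `speed_kmh`, `direction_deg`
#'   (direction the wind blows from).
#' @export
gen_wind <- function(year, seasonal_amplitude = 28, base_direction = 45,
                     noise_sd = 8, peak_day = 196, peak_width = 55,
                     reversal_depth = 0, reversal_width = 30,
                     annual_strength = 1, seed = NULL) {
  if (seasonal_amplitude < 0) stop("gen_wind: seasonal_amplitude must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  doy <- as.integer(format(dates, "%j"))
  n <- length(doy)
  envelope <- exp(-((doy - peak_day) / peak_width)^2) -
    reversal_depth * exp(-((doy - peak_day) / reversal_width)^2)
  amp <- annual_strength * seasonal_amplitude * envelope
  th <- base_direction * pi / 180
  u <- -amp * sin(th) + stats::rnorm(n, sd = noise_sd)
  v <- -amp * cos(th) + stats::rnorm(n, sd = noise_sd)
  speed <- sqrt(u^2 + v^2)
  direction <- (atan2(-u, -v) * 180 / pi) %% 360
  direction[speed == 0] <- 0
  data.frame(date = dates, speed_kmh = speed, direction_deg = direction)
}

#' Generate synthetic upwelling seasons over a span of years
#'
#' Convenience chain for simulation studies: draws a lognormal annual
#' upwelling strength for each year, generates the corresponding wind
#' record with [gen_wind()], computes the daily upwelling index and
#' integrates it over the recruitment season.  The result is an
#' interannually variable series of integrated upwelling index (IUI)
#' values with known generating strengths.
#'
#' @param years Integer vector of calendar years.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param strength_sd SD of `log(annual strength)` (lognormal, median 1).
#' @param ... Further arguments passed to [gen_wind()].
#' @return A data frame with columns `year`, `strength`, `iui`
#'   (km^3 per km of coastline per season).
#' @export
gen_upwelling_seasons <- function(years, seed = NULL, strength_sd = 0.3, ...) {
  if (!is.null(seed)) set.seed(seed)
  strengths <- exp(stats::rnorm(length(years), sd = strength_sd))
  iui <- vapply(seq_along(years), function(i) {
    wind <- gen_wind(years[i], annual_strength = strengths[i], ...)
    dui <- daily_upwelling_index(wind)
    integrated_upwelling_index(dui, year = years[i])$iui
  }, numeric(1))
  data.frame(year = years, strength = strengths, iui = iui)
}

#' Parameters for the synthetic catch-rate generator
#'
#' Ground truth for [gen_catch()]: a linear model in which the catch rate
#' of fishing season i responds to the integrated upwelling index `lag`
#' seasons earlier (the season the recruits were larvae) and to a
#' step change in the daily quota (Total Allowable Catch, TAC).  Defaults
#' follow the fitted fishery model: an IUI effect of 0.24 kg fisher-day^-1
#' per km^3 km^-1 acting at a 4-season lag, a 13-season record starting
#' with the 1998--99 season, and a TAC reduction from the 2004--05 season
#' onward.
#'
#' @param n_seasons Number of fishing seasons (> `lag`).
#' @param first_season_year Calendar year the first fishing season starts.
#' @param intercept Baseline catch rate, kg fisher-day^-1.
#' @param iui_coefficient Effect of lagged IUI on catch rate,
#'   kg fisher-day^-1 per km^3 km^-1.
#' @param lag Lag between upwelling season and fishing season, seasons.
#' @param tac_change_year Start year of the first season under the reduced
#'   quota (dummy = 1 from this season onward).
#' @param tac_effect Step change in catch rate at the quota change,
#'   kg fisher-day^-1 (negative for a reduction).
#' @param noise_sd SD of the season-level noise, kg fisher-day^-1 (>= 0).
#' @param seed Integer seed, or `NULL`.
#' @return An object of class `catch_gen_params`.
#' @export
catch_gen_params <- function(n_seasons = 13, first_season_year = 1998,
                             intercept = 4, iui_coefficient = 0.24,
                             lag = 4, tac_change_year = 2004,
                             tac_effect = -2, noise_sd = 0.3, seed = NULL) {
  if (n_seasons <= lag) stop("catch_gen_params: n_seasons must exceed lag")
  if (noise_sd < 0) stop("catch_gen_params: noise_sd must be >= 0")
  structure(list(n_seasons = n_seasons, first_season_year = first_season_year,
                 intercept = intercept, iui_coefficient = iui_coefficient,
                 lag = lag, tac_change_year = tac_change_year,
                 tac_effect = tac_effect, noise_sd = noise_sd, seed = seed),
            class = "catch_gen_params")
}

#' Generate a synthetic landings/effort table
#'
#' Builds a per-season catch table whose catch rate follows
#' `intercept + iui_coefficient * IUI[i - lag] + tac_effect * 1[TAC period] +
#' noise`, then decomposes the rate into a consistent landings/effort pair
#' (effort drawn uniformly between 2500 and 4500 fisher-days).
#'
#' @param params A [catch_gen_params()] object.
#' @param iui_by_season Data frame with columns `year` and `iui` covering
#'   every year from `first_season_year - lag` through the last fishing
#'   season's start year minus `lag` (an error lists any missing year).
#' @return A data frame of class `catch_table` with columns `season`
#'   (label), `year` (season start year), `landings_kg`,
#'   `effort_fisherdays`, `catch_rate`, `tac_period`.
#' @export
gen_catch <- function(params, iui_by_season) {
  stopifnot(inherits(params, "catch_gen_params"))
  if (!all(c("year", "iui") %in% names(iui_by_season)))
    stop("gen_catch: iui_by_season must have columns 'year' and 'iui'")
  if (!is.null(params$seed)) set.seed(params$seed)
  years <- params$first_season_year + seq_len(params$n_seasons) - 1L
  iui_lag <- iui_by_season$iui[match(years - params$lag, iui_by_season$year)]
  if (anyNA(iui_lag)) {
    stop("gen_catch: missing lagged IUI for year(s) ",
         paste(years[is.na(iui_lag)] - params$lag, collapse = ", "))
  }
  tac <- as.integer(years >= params$tac_change_year)
  rate <- params$intercept + params$iui_coefficient * iui_lag +
    params$tac_effect * tac +
    stats::rnorm(params$n_seasons, sd = params$noise_sd)
  effort <- round(stats::runif(params$n_seasons, 2500, 4500))
  out <- data.frame(
    season = sprintf("%d-%02d", years, (years + 1) %% 100),
    year = years,
    landings_kg = rate * effort,
    effort_fisherdays = effort,
    catch_rate = rate,
    tac_period = tac
  )
  class(out) <- c("catch_table", "data.frame")
  out
}
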