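# Bakun upwelling indices: daily Ekman transport from coastal wind, its GAM
# seasonal cycle, and the season-integrated index.

#' Physical constants for the Bakun upwelling index
#'
#' Standard bulk-formula constants: drag coefficient, air and seawater
#' densities, Earth's angular velocity, and the anemometer noise floor
#' below which wind speeds are treated as zero (7 km h^-1, the detection
#' limit of early sensors).  All are configurable.
#'
#' @param drag_coefficient Dimensionless air-sea drag coefficient.
#' @param rho_air Air density, kg m^-3.
#' @param rho_seawater Seawater density, kg m^-3.
#' @param omega Earth's angular velocity, rad s^-1.
#' @param min_speed_kmh Wind speeds below this are set to zero, km h^-1.
#' @return Named list of constants.
#' @export
bakun_constants <- function(drag_coefficient = 1.4e-3, rho_air = 1.22,
                            rho_seawater = 1025, omega = 7.2921e-5,
                            min_speed_kmh = 7) {
  list(drag_coefficient = drag_coefficient, rho_air = rho_air,
       rho_seawater = rho_seawater, omega = omega,
       min_speed_kmh = min_speed_kmh)
}

#' Daily upwelling index (DUI) from a wind record
#'
#' Bakun's index: the cross-shore Ekman volume transport per kilometre of
#' coastline implied by the local wind stress.  Wind speeds below the
#' detection threshold are zeroed, the stress vector is the quadratic bulk
#' formula `tau = rho_air * Cd * |W| * W` (wind in m s^-1), and the
#' offshore component of the Ekman transport `(tau_y, -tau_x) / (rho_sw f)`
#' is reported in m^3 s^-1 per km of coast.  Positive values mean offshore
#' surface transport, i.e. upwelling-favourable conditions; with the
#' default east-west coast (sea to the north), easterly-component winds
#' give positive DUI.
#'
#' @param wind Data frame with columns `date`, `speed_kmh`,
#'   `direction_deg` (meteorological: direction the wind blows FROM,
#'   0 <= direction < 360).
#' @param coast_azimuth Azimuth (degrees clockwise from north) of the
#'   alongshore direction, oriented so the sea lies to its left.  The
#'   default 90 is a coast running west-to-east with the sea to the north.
#' @param latitude Station latitude, degrees (non-zero; sets the Coriolis
#'   parameter `f = 2 omega sin(latitude)`).
#' @param constants Output of [bakun_constants()].
#' @return Data frame with columns `date` and `dui` (m^3 s^-1 km^-1).
#' @export
daily_upwelling_index <- function(wind, coast_azimuth = 90, latitude = 43.55,
                                  constants = bakun_constants()) {
  need <- c("date", "speed_kmh", "direction_deg")
  if (!all(need %in% names(wind)))
    stop("daily_upwelling_index: wind must have columns ",
         paste(need, collapse = ", "))
  if (latitude == 0) stop("daily_upwelling_index: latitude must be non-zero")
  dir <- wind$direction_deg
  if (any(!is.finite(dir)) || any(dir < 0 | dir >= 360))
    stop("daily_upwelling_index: directions must lie in [0, 360)")
  if (any(wind$speed_kmh < 0))
    stop("daily_upwelling_index: negative wind speeds")

  speed <- ifelse(wind$speed_kmh < constants$min_speed_kmh, 0, wind$speed_kmh)
  speed_ms <- speed / 3.6
  th <- dir * pi / 180
  u <- -speed_ms * sin(th)            # eastward wind component
  v <- -speed_ms * cos(th)            # northward wind component
  w_abs <- sqrt(u^2 + v^2)
  coef <- constants$rho_air * constants$drag_coefficient
  tau_x <- coef * w_abs * u
  tau_y <- coef * w_abs * v
  f <- 2 * constants$omega * sin(latitude * pi / 180)
  m_east <- tau_y / (constants$rho_seawater * f)
  m_north <- -tau_x / (constants$rho_seawater * f)
  az <- coast_azimuth * pi / 180
  offshore <- c(-cos(az), sin(az))    # unit normal, 90 deg left of alongshore
  dui <- 1000 * (m_east * offshore[1] + m_north * offshore[2])
  data.frame(date = wind$date, dui = dui)
}

#' Fit the seasonal cycle of the daily upwelling index
#'
#' Smooths DUI against day of year with a generalized additive model using
#' a thin-plate regression spline whose degrees of freedom are fixed at
#' `edf` (default 4), giving a deliberately smooth curve that captures the
#' general seasonal pattern rather than day-to-day variability.
#'
#' @param dui Data frame from [daily_upwelling_index()] with at least 30
#'   distinct days.
#' @param edf Fixed effective degrees of freedom of the smooth.
#' @return Object of class `seasonal_cycle_fit`: list with the fitted
#'   `mgcv` model (`model`), `edf`, and `curve`, a data frame of
#'   `day_of_year` (1--365), `fit` and `se`.
#' @export
fit_seasonal_cycle <- function(dui, edf = 4) {
  d <- data.frame(doy = as.integer(format(as.Date(dui$date), "%j")),
                  dui = dui$dui)
  d <- d[is.finite(d$dui), ]
  if (length(unique(d$doy)) < 30)
    stop("fit_seasonal_cycle: need at least 30 distinct days of data")
  model <- mgcv::gam(dui ~ s(doy, k = edf + 1, fx = TRUE, bs = "tp"),
                     data = d)
  grid <- data.frame(doy = 1:365)
  pred <- mgcv::predict.gam(model, newdata = grid, se.fit = TRUE)
  structure(list(model = model, edf = edf,
                 curve = data.frame(day_of_year = grid$doy,
                                    fit = as.numeric(pred$fit),
                                    se = as.numeric(pred$se.fit))),
            class = "seasonal_cycle_fit")
}

#' @export
print.seasonal_cycle_fit <- function(x, ...) {
  pk <- x$curve$day_of_year[which.max(x$curve$fit)]
  cat("<seasonal_cycle_fit> thin-plate smooth, fixed df =", x$edf, "\n")
  cat(sprintf("  fitted range: %.1f to %.1f m^3 s^-1 km^-1, peak day %d\n",
              min(x$curve$fit), max(x$curve$fit), pk))
  invisible(x)
}

#' Plot the fitted seasonal upwelling cycle
#'
#' @param x A `seasonal_cycle_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.seasonal_cycle_fit <- function(x, ...) {
  with(x$curve, {
    graphics::plot(day_of_year, fit, type = "l",
                   xlab = "day of year", ylab = "DUI (m³ s⁻¹ km⁻¹)", ...)
    graphics::lines(day_of_year, fit + se, lty = 3)
    graphics::lines(day_of_year, fit - se, lty = 3)
    graphics::abline(h = 0, col = "grey")
  })
  invisible(x)
}

#' Integrated upwelling index (IUI) for a recruitment season
#'
#' Total net volume of water displaced offshore per kilometre of coastline
#' over the recruitment season: the sum of daily Ekman transports over the
#' window (June 1 to October 31 by default), each day contributing
#' `dui * 86400` m^3 km^-1, converted to km^3 km^-1.
#'
#' @param dui Data frame from [daily_upwelling_index()].
#' @param year Calendar year(s) of the season(s); defaults to every year
#'   present in `dui`.
#' @param start_month_day,end_month_day Window limits as `"MM-DD"` strings.
#' @return Data frame with columns `year` and `iui` (km^3 km^-1).  Any
#'   missing day inside a window is a hard error listing the dates.
#' @export
integrated_upwelling_index <- function(dui, year = NULL,
                                       start_month_day = "06-01",
                                       end_month_day = "10-31") {
  dates <- as.Date(dui$date)
  if (is.null(year)) year <- sort(unique(as.integer(format(dates, "%Y"))))
  iui <- vapply(year, function(y) {
    window <- seq(as.Date(sprintf("%d-%s", y, start_month_day)),
                  as.Date(sprintf("%d-%s", y, end_month_day)), by = "day")
    idx <- match(window, dates)
    if (anyNA(idx)) {
      stop("integrated_upwelling_index: missing days in ", y, ": ",
           paste(format(window[is.na(idx)]), collapse = ", "))
    }
    sum(dui$dui[idx]) * 86400 / 1e9
  }, numeric(1))
  data.frame(year = year, iui = iui)
}
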