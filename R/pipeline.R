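# End-to-end orchestration: one configuration drives currents -> length
# scales -> kernels -> recruitment metrics, and wind -> upwelling indices ->
# catch regression, with CSV artifacts and a structured log.

#' Build a pipeline configuration
#'
#' Collects every tunable of the analysis in one list.  Each data source is
#' either a file path (`currents_path`, `wind_path`, `catch_path`) or
#' synthesized from the seeded generators when the path is `NULL`.
#'
#' @param outdir Output directory (created if missing).
#' @param seed Integer master seed for all synthetic stages.
#' @param year Season year used for schedules and labels.
#' @param regime A [flow_regime()] used when `currents_path` is `NULL`.
#' @param currents_path,wind_path,catch_path Optional CSV inputs.
#' @param release_start,release_end Spawning window (defaults: 1 July to
#'   2 October of `year`).
#' @param nauplius_days,cyprid_days Stage durations, days.
#' @param decorrelation_hours Lagrangian decorrelation time, hours.
#' @param grid A [kernel_grid_spec()].
#' @param constants [bakun_constants()] for the upwelling stage.
#' @param coast_azimuth,latitude Coastline orientation and station latitude.
#' @param iui_start,iui_end IUI window as `"MM-DD"` strings.
#' @param wind_years Years of wind/IUI record to synthesize for the catch
#'   analysis.
#' @param catch_params A [catch_gen_params()] for synthetic catch data.
#' @param lags Candidate lags for the catch regression.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("percebe-run-"),
                            seed = 1,
                            year = 2009,
                            regime = regime_2009(),
                            currents_path = NULL,
                            wind_path = NULL,
                            catch_path = NULL,
                            release_start = NULL,
                            release_end = NULL,
                            nauplius_days = 30,
                            cyprid_days = 30,
                            decorrelation_hours = 12,
                            grid = kernel_grid_spec(),
                            constants = bakun_constants(),
                            coast_azimuth = 90,
                            latitude = 43.55,
                            iui_start = "06-01",
                            iui_end = "10-31",
                            wind_years = 1993:2010,
                            catch_params = catch_gen_params(),
                            lags = 1:5) {
  if (is.null(release_start))
    release_start <- sprintf("%d-07-01 00:00:00", year)
  if (is.null(release_end))
    release_end <- sprintf("%d-10-02 00:00:00", year)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML mapping whose keys are arguments of [pipeline_config()];
#' nested maps `regime`, `grid`, `constants` and `catch_params` are passed
#' to the corresponding constructors.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("read_pipeline_config: file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$regime)) raw$regime <- do.call(flow_regime, raw$regime)
  if (!is.null(raw$grid)) raw$grid <- do.call(kernel_grid_spec, raw$grid)
  if (!is.null(raw$constants))
    raw$constants <- do.call(bakun_constants, raw$constants)
  if (!is.null(raw$catch_params))
    raw$catch_params <- do.call(catch_gen_params, raw$catch_params)
  do.call(pipeline_config, raw)
}

.pipeline_log <- function(config, lines) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(config$outdir, "pipeline.log")
  cat(lines, sep = "\n")
  cat(lines, file = path, sep = "\n", append = TRUE)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

.echo_defaults <- function(config, keys) {
  vapply(keys, function(k) {
    v <- config[[k]]
    if (is.list(v)) v <- paste(deparse(unclass(v)), collapse = " ")
    sprintf("  %s = %s", k, paste(format(v), collapse = " "))
  }, character(1))
}

#' Run the dispersal analysis
#'
#' Chains current-profile ingestion (or synthesis), per-event length
#' scales over the release schedule, the ensemble dispersal kernel, and
#' the recruitment metrics.  Writes `season_scales.csv` (per-event and
#' summary), `ensemble_kernel.csv` and `dispersal_metrics.csv` to the
#' output directory, and echoes every numeric default in effect to
#' `pipeline.log`.
#'
#' @param config A [pipeline_config()].
#' @return List with `season` ([season_length_scales()]), `kernel`
#'   (`dispersal_kernel`) and `metrics` (data frame), invisibly.
#' @export
run_dispersal <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  .pipeline_log(config, c("== dispersal run ==", .echo_defaults(config,
    c("seed", "year", "release_start", "release_end", "nauplius_days",
      "cyprid_days", "decorrelation_hours"))))

  schedule <- larval_schedule(config$release_start, config$release_end,
                              nauplius_days = config$nauplius_days,
                              cyprid_days = config$cyprid_days)
  series <- .stage("currents", {
    if (!is.null(config$currents_path)) {
      if (!file.exists(config$currents_path))
        stop("input path not found: ", config$currents_path)
      load_profiles(config$currents_path)
    } else {
      pld <- (config$nauplius_days + config$cyprid_days) * 86400
      gen_currents(config$regime, schedule$release_start,
                   schedule$release_end + pld, seed = config$seed)
    }
  })
  season <- .stage("length_scales",
    season_length_scales(series, schedule,
                         decorrelation_hours = config$decorrelation_hours,
                         year = config$year))
  kernel <- .stage("kernel", ensemble_kernel(season, grid = config$grid))
  peak <- peak_recruitment(kernel)
  metrics <- data.frame(
    year = config$year,
    n_events = season$n_events,
    recruitment_success = recruitment_success(kernel),
    peak_offset_km = peak$offset_km,
    peak_density_per_km2 = peak$density_per_km2
  )
  utils::write.csv(cbind(metric = season$summary$metric,
                         season$summary[-1]),
                   file.path(config$outdir, "season_scales.csv"),
                   row.names = FALSE)
  write_kernel_csv(kernel, file.path(config$outdir, "ensemble_kernel.csv"))
  utils::write.csv(metrics, file.path(config$outdir, "dispersal_metrics.csv"),
                   row.names = FALSE)
  .pipeline_log(config, sprintf(
    "recruitment %.4f, peak at %g km (%.3e km^-2), %d events",
    metrics$recruitment_success, metrics$peak_offset_km,
    metrics$peak_density_per_km2, season$n_events))
  invisible(list(season = season, kernel = kernel, metrics = metrics))
}

#' Run the upwelling/catch-rate analysis
#'
#' Chains the wind record (file or synthesis across `wind_years`), the
#' daily and integrated upwelling indices, the synthetic or recorded catch
#' table, the lagged regression models with Akaike weights, and the
#' variance partition.  Writes `iui.csv`, `lag_models.csv` (the
#' model-comparison table) and `variance_partition.csv`.
#'
#' @param config A [pipeline_config()].
#' @return List with `iui`, `models` (`lag_model_set`) and `partition`
#'   (`variance_partition`), invisibly.
#' @export
run_catch_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  .pipeline_log(config, c("== catch analysis ==", .echo_defaults(config,
    c("seed", "coast_azimuth", "latitude", "iui_start", "iui_end", "lags"))))

  iui <- .stage("upwelling", {
    if (!is.null(config$wind_path)) {
      if (!file.exists(config$wind_path))
        stop("input path not found: ", config$wind_path)
      wind <- utils::read.csv(config$wind_path)
      wind$date <- as.Date(wind$date)
      dui <- daily_upwelling_index(wind, coast_azimuth = config$coast_azimuth,
                                   latitude = config$latitude,
                                   constants = config$constants)
      integrated_upwelling_index(dui, start_month_day = config$iui_start,
                                 end_month_day = config$iui_end)
    } else {
      set.seed(config$seed)
      gen_upwelling_seasons(config$wind_years)
    }
  })
  catch <- .stage("catch", {
    if (!is.null(config$catch_path)) {
      if (!file.exists(config$catch_path))
        stop("input path not found: ", config$catch_path)
      df <- utils::read.csv(config$catch_path)
      df$catch_rate <- df$landings_kg / df$effort_fisherdays
      df
    } else {
      p <- config$catch_params
      p$seed <- config$seed + 1L
      gen_catch(p, iui)
    }
  })
  models <- .stage("regression", fit_lag_models(catch, iui, lags = config$lags))
  best <- models$table$lag[which.min(models$table$aic)]
  iui_best <- iui$iui[match(catch$year - best, iui$year)]
  partition <- .stage("regression", variance_partition(catch, iui_best))

  utils::write.csv(iui, file.path(config$outdir, "iui.csv"),
                   row.names = FALSE)
  utils::write.csv(models$table, file.path(config$outdir, "lag_models.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(partition)),
                   file.path(config$outdir, "variance_partition.csv"),
                   row.names = FALSE)
  .pipeline_log(config, sprintf(
    "best lag %d (weight %.4f); pure TAC %.3f, pure IUI %.3f",
    best, max(models$table$akaike_weight), partition$pure_tac,
    partition$pure_iui))
  invisible(list(iui = iui, catch = catch, models = models,
                 partition = partition))
}

#' Run both analysis branches
#'
#' @param config A [pipeline_config()].
#' @return List with elements `dispersal` and `catch`, invisibly.
#' @export
run_pipeline <- function(config) {
  invisible(list(dispersal = run_dispersal(config),
                 catch = run_catch_analysis(config)))
}
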