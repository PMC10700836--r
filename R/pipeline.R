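#' Configuration for a full synthetic-study run
#'
#' Bundles every stage's parameters into one validated object; a serialized
#' copy is written to the output directory by [run_pipeline()] so a run can
#' be reproduced exactly from its artifacts.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param n_stations,n_counties,n_regions Geography sizes.
#' @param climate A [climate_params()].
#' @param waves,n_individuals,birth_year_range Panel settings.
#' @param dgp A [dgp_params()].
#' @param window_days Exposure-window length, days.
#' @param bins A [bin_spec()].
#' @param reference A [reference_spec()] for the headline model.
#' @param spec A [model_spec()].
#' @param sweep_scheme,sweep_grid Reference sweep settings.
#' @param scenarios,n_models,proj_years Scenario ensemble settings.
#' @param age_start,age_drift Average-age path settings.
#' @param fixed_window Fixed projection reference window.
#' @param catch_up_threshold Full-adaptation anomaly threshold, degC.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            n_stations = 24, n_counties = 30, n_regions = 4,
                            climate = climate_params(),
                            waves = c(2010, 2014, 2018),
                            n_individuals = 600,
                            birth_year_range = c(1955, 1990),
                            dgp = dgp_params(),
                            window_days = 30,
                            bins = bin_spec(),
                            reference = reference_spec("lifetime"),
                            spec = model_spec(),
                            sweep_scheme = "preceding_years",
                            sweep_grid = c(2, 5, 10, 20, 30, 40),
                            scenarios = c("netzero", "middle", "high"),
                            n_models = 20,
                            proj_years = 2020:2100,
                            age_start = 38.5, age_drift = 0.15,
                            fixed_window = c(1980, 2000),
                            catch_up_threshold = 0.05) {
  stopifnot(inherits(climate, "climate_params"), inherits(dgp, "dgp_params"),
            inherits(bins, "bin_spec"), inherits(reference, "reference_spec"),
            inherits(spec, "model_spec"))
  if (max(birth_year_range) > min(waves)) {
    abort("Birth years must not extend past the first wave.")
  }
  if (min(birth_year_range) < climate$start_year) {
    abort("Birth years before the weather record would leave references uncovered.")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic study end to end
#'
#' Executes simulate (geography, weather, panel), build (interpolation,
#' exposures, anomalies, outcome), estimate, sweep and project stages,
#' writing every artifact as plain CSV/JSON into `out_dir` along with the
#' serialized configuration and a checksummed manifest. All randomness flows
#' through seeds derived from `config$seed`, so a rerun with the same
#' configuration reproduces every artifact bit for bit.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of `c("simulate", "build", "estimate", "sweep",
#'   "project")`. Later stages require their upstream artifacts: projecting
#'   without an estimate (in this run or a previous `fit.json` in `out_dir`)
#'   is refused.
#' @param quiet Suppress progress messages?
#'
#' @return Invisibly, a list with the stage outputs (`fit`, `sweep`,
#'   `projection`, `catch_up`, ...) and the `manifest` tibble.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = c("simulate", "build", "estimate",
                                    "sweep", "project"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) inform(paste0(...))
  files <- character(0)
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(obj, path)
    files <<- c(files, path)
    say("  wrote ", name, " (", nrow(obj), " rows)")
  }
  res <- list()

  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(
    lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x),
    cfg_json, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
  )
  files <- c(files, cfg_json)

  if ("simulate" %in% stages) {
    say("stage simulate: geography, station weather, panel")
    geo <- generate_geography(config$n_stations, config$n_counties,
                              config$n_regions, seed = config$seed + 1)
    wx <- simulate_station_weather(geo$stations, config$climate,
                                   seed = config$seed + 2)
    panel <- simulate_panel(geo$counties, waves = config$waves,
                            n_individuals = config$n_individuals,
                            birth_year_range = config$birth_year_range,
                            seed = config$seed + 3)
    res$geo <- geo
    res$weather <- wx
    res$panel <- panel
    emit(geo$stations, "stations.csv")
    emit(geo$counties, "counties.csv")
    emit(wx, "weather_daily.csv")
  }

  if ("build" %in% stages) {
    if (is.null(res$weather)) abort("Stage `build` needs the simulate stage.")
    say("stage build: interpolation, exposures, anomalies, outcome")
    county_daily <- interpolate_counties(res$weather, res$geo$stations,
                                         res$geo$counties)
    exposures <- build_exposures(res$panel, county_daily,
                                 window_days = config$window_days,
                                 bins = config$bins)
    anomalies <- build_anomalies(res$panel, county_daily,
                                 reference = config$reference)
    res$panel <- simulate_swb(res$panel, anomalies, config$dgp,
                              seed = config$seed + 4)
    res$county_daily <- county_daily
    res$exposures <- exposures
    res$anomalies <- anomalies
    emit(county_daily, "county_daily.csv")
    emit(exposures, "exposures.csv")
    emit(anomalies, "anomalies.csv")
    emit(res$panel, "panel.csv")
  }

  if ("estimate" %in% stages) {
    if (is.null(res$anomalies)) abort("Stage `estimate` needs the build stage.")
    say("stage estimate: two-way FE fit with clustered errors")
    fit <- fit_swb_model(res$panel, anomalies = res$anomalies,
                         exposures = res$exposures, spec = config$spec)
    res$fit <- fit
    fit_path <- file.path(out_dir, "fit.json")
    jsonlite::write_json(
      list(
        term = fit$term,
        coefficients = as.list(fit$coefficients),
        se = as.list(fit$se),
        n_obs = fit$n_obs,
        n_clusters = as.list(fit$n_clusters),
        n_dropped_singletons = fit$n_dropped_singletons,
        fe_iterations = fit$fe$iterations,
        fe_delta = fit$fe$delta,
        psd_repaired = fit$psd_repaired
      ),
      fit_path, auto_unbox = TRUE, digits = NA
    )
    files <- c(files, fit_path)
    emit(tidy(fit), "fit_coefficients.csv")
  }

  if ("sweep" %in% stages) {
    if (is.null(res$fit)) abort("Stage `sweep` needs the estimate stage.")
    say("stage sweep: reference scheme grid")
    sweep <- reference_sweep(res$panel, res$county_daily, res$exposures,
                             spec = config$spec,
                             scheme = config$sweep_scheme,
                             grid = config$sweep_grid,
                             window_days = config$window_days)
    res$sweep <- sweep
    emit(sweep, "sweep.csv")
  }

  if ("project" %in% stages) {
    beta_hat <- if (!is.null(res$fit)) {
      unname(res$fit$coefficients["anomaly"])
    } else {
      fit_path <- file.path(out_dir, "fit.json")
      if (!file.exists(fit_path)) {
        abort(paste0("Stage `project` needs an estimate: run the estimate ",
                     "stage or place a fit.json in ", out_dir, "."))
      }
      jsonlite::read_json(fit_path)$coefficients$anomaly
    }
    say("stage project: scenario ensemble and impacts")
    regions <- tibble(
      region_id = seq_len(config$n_regions),
      base_temp = rep_len(config$climate$regional_base_temp, config$n_regions)
    )
    traj <- generate_projection_scenarios(regions, scenarios = config$scenarios,
                                          n_models = config$n_models,
                                          seed = config$seed + 5)
    ages <- generate_age_trajectory(config$proj_years,
                                    start_age = config$age_start,
                                    drift = config$age_drift)
    proj <- project_impacts(traj, ages, beta_hat,
                            fixed_window = config$fixed_window)
    ens <- ensemble_projection(proj)
    cu <- catch_up_year(ens, threshold = config$catch_up_threshold)
    res$trajectories <- traj
    res$ages <- ages
    res$projection <- proj
    res$ensemble <- ens
    res$catch_up <- cu
    emit(traj, "scenarios.csv")
    emit(ages, "ages.csv")
    emit(proj, "projection.csv")
    emit(dplyr::left_join(ens, cu, by = "scenario"), "projection_summary.csv")
  }

  manifest <- tibble(
    file = basename(files),
    bytes = file.size(files),
    md5 = unname(tools::md5sum(files))
  )
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  res$manifest <- manifest
  say("done: ", length(files), " artifacts in ", out_dir)
  invisible(res)
}

#' Significance stars
#'
#' `***` for p < 0.01, `**` for p < 0.05, `*` for p < 0.1.
#'
#' @param p Numeric p-values.
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(p < 0.01 ~ "***", p < 0.05 ~ "**", p < 0.1 ~ "*",
                   .default = "")
}

#' Publication-style coefficient table
#'
#' Formats one or more fits as a table with starred coefficients and
#' clustered standard errors in parentheses.
#'
#' @param ... One or more `swb_fit` objects (optionally named).
#' @param digits Digits after the decimal point.
#' @return A data frame with one row pair per term.
#' @export
render_fit_table <- function(..., digits = 4) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], "swb_fit")) {
    fits <- fits[[1]]
  }
  if (length(fits) == 0) return(data.frame(term = character(0)))
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("(", seq_along(fits), ")")
  }
  terms <- unique(unlist(lapply(fits, function(f) names(f$coefficients))))
  if (length(terms) == 0) return(data.frame(term = character(0)))
  out <- data.frame(term = terms, stringsAsFactors = FALSE)
  for (nm in names(fits)) {
    td <- tidy(fits[[nm]])
    i <- match(terms, td$term)
    est <- ifelse(is.na(i), "",
                  paste0(formatC(td$estimate[i], format = "f", digits = digits),
                         significance_stars(td$p.value[i])))
    se <- ifelse(is.na(i), "",
                 paste0("(", formatC(td$std.error[i], format = "f",
                                     digits = digits), ")"))
    out[[nm]] <- paste0(est, " ", se)
  }
  out
}
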