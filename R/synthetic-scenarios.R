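#' Generate a synthetic ensemble of scenario temperature trajectories
#'
#' Emulates a multi-model ensemble of annual regional mean temperatures under
#' three emissions archetypes, each paired with a consistent historical
#' backcast (1950-2014 by default) so that lifetime and fixed-period
#' references can be formed:
#'
#' * `"netzero"`: warming decelerates linearly from 2015 and plateaus at
#'   mid-century (net-zero / SSP1-2.6 archetype);
#' * `"middle"`: steady warming throughout (middle-of-the-road / SSP2-4.5);
#' * `"high"`: accelerating warming (very-high-emissions / SSP5-8.5).
#'
#' Inter-model spread enters through a per-model level offset and a per-model
#' slope multiplier; paths are otherwise deterministic, so scenario shapes
#' (plateau, steady, accelerating) hold exactly for every model.
#'
#' @param regions Either an integer number of regions or a tibble with a
#'   `region_id` column (and optionally `base_temp`, degC).
#' @param scenarios Subset of `c("netzero", "middle", "high")`.
#' @param n_models Ensemble size (>= 1).
#' @param years Projection years.
#' @param history_years Historical backcast years (warming at 0.015 degC/yr).
#' @param model_offset_sd SD of the per-model level offset, degC.
#' @param model_slope_sd SD of the per-model slope multiplier around 1.
#' @param seed Integer seed.
#'
#' @return Tibble with columns `scenario`, `model`, `region_id`, `year`,
#'   `temp`, `period` (`"historical"` or `"projection"`).
#' @export
#' @examples
#' traj <- generate_projection_scenarios(2, n_models = 3, seed = 1)
#' dplyr::count(traj, scenario, period)
generate_projection_scenarios <- function(regions,
                                          scenarios = c("netzero", "middle", "high"),
                                          n_models = 20,
                                          years = 2015:2100,
                                          history_years = 1950:2014,
                                          model_offset_sd = 0.3,
                                          model_slope_sd = 0.1,
                                          seed = NULL) {
  known <- c("netzero", "middle", "high")
  bad <- setdiff(scenarios, known)
  if (length(bad) > 0) {
    abort(paste0("Unknown scenario label(s): ", paste(bad, collapse = ", "),
                 ". Choose from: ", paste(known, collapse = ", "), "."))
  }
  if (n_models < 1) abort("`n_models` must be >= 1.")
  if (is.data.frame(regions)) {
    region_id <- regions$region_id
    base <- regions$base_temp %||% seq(8, 20, length.out = nrow(regions))
  } else {
    region_id <- seq_len(regions)
    base <- seq(8, 20, length.out = regions)
  }
  if (!is.null(seed)) withr::local_seed(seed)

  offsets <- rnorm(n_models, 0, model_offset_sd)
  slopes <- pmax(0.2, rnorm(n_models, 1, model_slope_sd))

  h0 <- min(history_years)
  hist_rise <- function(y) 0.015 * (y - h0)
  rise_2014 <- hist_rise(max(history_years))

  # cumulative post-2014 warming at slope multiplier 1
  proj_rise <- function(scenario, y) {
    inc_years <- 2015:max(2015, max(y))
    inc <- switch(scenario,
      netzero = 0.02 * pmax(0, (2050 - inc_years) / (2050 - 2015)),
      middle = rep(0.025, length(inc_years)),
      high = 0.02 + 0.0005 * (inc_years - 2015)
    )
    cumsum(inc)[match(y, inc_years)]
  }

  grid_h <- tidyr::crossing(
    scenario = scenarios, model = seq_len(n_models),
    tibble(region_id = region_id, base = base), year = history_years
  )
  grid_h$temp <- grid_h$base + offsets[grid_h$model] +
    slopes[grid_h$model] * hist_rise(grid_h$year)
  grid_h$period <- "historical"

  grid_p <- tidyr::crossing(
    scenario = scenarios, model = seq_len(n_models),
    tibble(region_id = region_id, base = base), year = years
  )
  rises <- purrr::map(known, function(s) proj_rise(s, years))
  names(rises) <- known
  grid_p$temp <- grid_p$base + offsets[grid_p$model] +
    slopes[grid_p$model] * (rise_2014 +
      purrr::map2_dbl(grid_p$scenario, match(grid_p$year, years),
                      function(s, i) rises[[s]][i]))
  grid_p$period <- "projection"

  dplyr::bind_rows(grid_h, grid_p) |>
    dplyr::select("scenario", "model", "region_id", "year", "temp", "period") |>
    dplyr::arrange(.data$scenario, .data$model, .data$region_id, .data$year)
}

#' Generate an average-age trajectory
#'
#' A linear path for the population's average age, used to assign the
#' representative agent's birth year in projections. The default emulates a
#' population averaging about 38.5 years in 2020 and ageing by 0.15 years per
#' calendar year. `drift = 0` gives the constant-age path used in analytic
#' checks.
#'
#' @param years Calendar years covered.
#' @param start_age Average age in the first year (> 0).
#' @param drift Change in average age per year.
#'
#' @return Tibble with columns `year`, `avg_age`.
#' @export
#' @examples
#' generate_age_trajectory(2020:2025, start_age = 40, drift = 0.1)
generate_age_trajectory <- function(years = 2020:2100, start_age = 38.5, drift = 0.15) {
  if (start_age <= 0) abort("`start_age` must be > 0.")
  age <- start_age + drift * (years - years[1])
  if (any(age <= 0)) abort("The age path must stay strictly positive.")
  tibble(year = as.integer(years), avg_age = age)
}
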