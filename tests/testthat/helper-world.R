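# Shared synthetic worlds, built in code at test time.

# Small world with realistic defaults (warming trend + noise).
make_world <- function(n_stations = 8, n_counties = 10, n_regions = 2,
                       n_individuals = 150, seed = 42,
                       climate = climate_params()) {
  geo <- generate_geography(n_stations, n_counties, n_regions, seed = seed)
  wx <- simulate_station_weather(geo$stations, climate, seed = seed + 1)
  cd <- interpolate_counties(wx, geo$stations, geo$counties)
  panel <- simulate_panel(geo$counties, n_individuals = n_individuals,
                          seed = seed + 2)
  list(geo = geo, weather = wx, county_daily = cd, panel = panel)
}

# Deterministic world: zero trend, zero noise, optional zero seasonality.
make_flat_world <- function(trend = 0, amplitude = 0, n_individuals = 50,
                            seed = 7) {
  make_world(
    n_stations = 4, n_counties = 5, n_regions = 1,
    n_individuals = n_individuals, seed = seed,
    climate = climate_params(
      regional_base_temp = 15, seasonal_amplitude = amplitude,
      warming_trend = trend, daily_noise_sd = 0, monthly_noise_sd = 0,
      station_noise_sd = 0
    )
  )
}

# Single-county daily series over a year range, from a supplied function of
# the date (deterministic), as a tibble ready for the single-series functions.
make_series <- function(from, to, f = function(d) rep(15, length(d))) {
  d <- seq(as.Date(from), as.Date(to), by = "day")
  tibble::tibble(date = d, temp = f(d))
}

# Year-step linear series: value = base + slope * (year - first year).
# Exact arithmetic for windows that do not cross a year boundary.
linear_series <- function(from, to, base = 10, slope = 0.1) {
  y0 <- as.integer(format(as.Date(from), "%Y"))
  make_series(from, to, function(d) {
    base + slope * (as.integer(format(d, "%Y")) - y0)
  })
}
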