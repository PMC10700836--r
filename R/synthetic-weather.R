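#' Climate parameters for the synthetic station weather generator
#'
#' The generator emulates a multi-decade national station record: a regional
#' base temperature, a sinusoidal seasonal cycle peaking in mid-July, a secular
#' warming trend of 0.02 degC per year (0.2 degC per decade, the rate of recent
#' decades), a persistent per-station offset and i.i.d. daily noise.
#'
#' @param regional_base_temp Numeric vector of annual-mean base temperatures
#'   (degC), one per region. Recycled/truncated to the number of regions at
#'   simulation time; defaults span a cool north to a warm south.
#' @param seasonal_amplitude Amplitude of the seasonal cycle, degC (>= 0).
#' @param seasonal_peak_day Day of year at which the cycle peaks.
#' @param warming_trend Secular trend, degC per year.
#' @param daily_noise_sd SD of day-level noise, degC (>= 0).
#' @param monthly_noise_sd SD of the region-month anomaly, degC (>= 0).
#'   Weather has a red spectrum: warm and cold spells persist for weeks, so
#'   exposure-window means vary far more than independent daily noise alone
#'   would allow. This shared region-month component gives 30-day anomalies
#'   a realistic dispersion of about 1 degC straddling zero.
#' @param station_noise_sd SD of the time-constant per-station offset, degC (>= 0).
#' @param start_year,end_year First and last calendar year of the record.
#'
#' @return A list of class `climate_params`.
#' @export
climate_params <- function(regional_base_temp = c(8, 12, 16, 20),
                           seasonal_amplitude = 10,
                           seasonal_peak_day = 196,
                           warming_trend = 0.02,
                           daily_noise_sd = 2,
                           monthly_noise_sd = 1.2,
                           station_noise_sd = 0.5,
                           start_year = 1951,
                           end_year = 2018) {
  if (seasonal_amplitude < 0) abort("`seasonal_amplitude` must be >= 0.")
  if (daily_noise_sd < 0 || station_noise_sd < 0 || monthly_noise_sd < 0) {
    abort("Noise standard deviations must be >= 0.")
  }
  if (start_year >= end_year) abort("`start_year` must be < `end_year`.")
  structure(
    list(
      regional_base_temp = regional_base_temp,
      seasonal_amplitude = seasonal_amplitude,
      seasonal_peak_day = seasonal_peak_day,
      warming_trend = warming_trend,
      daily_noise_sd = daily_noise_sd,
      monthly_noise_sd = monthly_noise_sd,
      station_noise_sd = station_noise_sd,
      start_year = start_year,
      end_year = end_year
    ),
    class = "climate_params"
  )
}

#' Simulate daily station weather
#'
#' For station s in region r on day d of year y:
#' `temp = base_r + A * cos(2*pi*(doy(d) - peak)/365.25) + trend*(y - start_year)
#'  + spell_{r,month(d)} + offset_s + noise_d`, where `spell` is the shared
#' region-month anomaly (persistent warm and cold spells) and `noise_d` is
#' independent daily noise. Auxiliary variables (wind, humidity, precipitation,
#' sunshine) are generated with mild correlation to temperature; they are
#' schematic covariates, not a physical weather model. Leap days are present.
#'
#' @param stations Station catalog tibble (`station_id`, `x`, `y`, `region_id`).
#' @param params A [climate_params()] object.
#' @param seed Integer seed.
#'
#' @return Tibble with columns `station_id`, `date`, `temp`, `wind`,
#'   `humidity`, `precip`, `sun_hours`.
#' @export
#' @examples
#' geo <- generate_geography(3, 5, 2, seed = 1)
#' wx <- simulate_station_weather(geo$stations,
#'   climate_params(start_year = 2000, end_year = 2002), seed = 1)
simulate_station_weather <- function(stations, params = climate_params(), seed = NULL) {
  stopifnot(inherits(params, "climate_params"))
  if (!is.null(seed)) withr::local_seed(seed)

  n_regions <- max(stations$region_id)
  base <- rep_len(params$regional_base_temp, n_regions)

  dates <- seq(as.Date(sprintf("%d-01-01", params$start_year)),
               as.Date(sprintf("%d-12-31", params$end_year)), by = "day")
  doy <- as.integer(format(dates, "%j"))
  yr <- as.integer(format(dates, "%Y"))
  seasonal <- params$seasonal_amplitude *
    cos(2 * pi * (doy - params$seasonal_peak_day) / 365.25)
  trend <- params$warming_trend * (yr - params$start_year)

  n_s <- nrow(stations)
  n_d <- length(dates)
  offset <- rnorm(n_s, 0, params$station_noise_sd)

  # persistent warm/cold spells shared within a region-month
  n_months <- (params$end_year - params$start_year + 1) * 12
  spell <- matrix(rnorm(n_regions * n_months, 0, params$monthly_noise_sd),
                  nrow = n_regions)
  mi <- (yr - params$start_year) * 12 + as.integer(format(dates, "%m"))

  out <- tibble(
    station_id = rep(stations$station_id, each = n_d),
    date = rep(dates, times = n_s),
    temp = rep(base[stations$region_id], each = n_d) +
      rep(seasonal + trend, times = n_s) +
      spell[cbind(rep(stations$region_id, each = n_d), rep(mi, times = n_s))] +
      rep(offset, each = n_d) +
      rnorm(n_s * n_d, 0, params$daily_noise_sd)
  )

  t_dev <- out$temp - mean(out$temp)
  n <- nrow(out)
  out$wind <- pmax(0, 3 - 0.03 * t_dev + rnorm(n, 0, 1))
  out$humidity <- pmin(100, pmax(5, 70 + 0.5 * t_dev + rnorm(n, 0, 8)))
  out$precip <- pmax(0, 0.5 + 0.05 * t_dev + rnorm(n, 0, 2))
  out$sun_hours <- pmin(14, pmax(0, 7 + 0.1 * t_dev + rnorm(n, 0, 2)))
  out
}
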