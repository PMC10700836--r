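test_that("geography generation is valid, complete and deterministic", {
  one <- generate_geography(1, 1, 1, seed = 0)
  expect_equal(nrow(one$stations), 1)
  expect_equal(nrow(one$counties), 1)
  expect_equal(one$stations$region_id, one$counties$region_id)

  a <- generate_geography(5, 10, 2, seed = 7)
  b <- generate_geography(5, 10, 2, seed = 7)
  expect_identical(a, b)

  big <- generate_geography(20, 50, 4, seed = 1)
  expect_equal(sum(table(big$counties$region_id)), 50)
  expect_true(all(big$counties$region_id %in% 1:4))
  expect_false(anyDuplicated(big$stations$station_id) > 0)
  expect_true(all(is.finite(c(big$stations$x, big$stations$y))))
  expect_true(all(sort(unique(big$stations$region_id)) == 1:4))

  expect_error(generate_geography(0, 5, 1), "must all be >= 1")
})

test_that("station weather follows the additive temperature model", {
  geo <- generate_geography(3, 3, 1, seed = 2)
  flat <- climate_params(regional_base_temp = 12, seasonal_amplitude = 0,
                         warming_trend = 0, daily_noise_sd = 0,
                         monthly_noise_sd = 0, station_noise_sd = 0,
                         start_year = 2000, end_year = 2003)
  wx <- simulate_station_weather(geo$stations, flat, seed = 1)
  expect_true(all(wx$temp == 12))
  expect_true(as.Date("2000-02-29") %in% wx$date)  # leap day present

  trended <- climate_params(regional_base_temp = 12, seasonal_amplitude = 0,
                            warming_trend = 0.02, daily_noise_sd = 0,
                            monthly_noise_sd = 0, station_noise_sd = 0,
                            start_year = 2000, end_year = 2012)
  wx2 <- simulate_station_weather(geo$stations, trended, seed = 1)
  s1 <- wx2[wx2$station_id == "S001", ]
  t0 <- s1$temp[s1$date == as.Date("2001-08-15")]
  t10 <- s1$temp[s1$date == as.Date("2011-08-15")]
  expect_equal(t10 - t0, 0.2, tolerance = 1e-12)
})

test_that("annual-mean regression on simulated weather recovers the trend", {
  geo <- generate_geography(6, 3, 2, seed = 3)
  params <- climate_params(start_year = 1951, end_year = 2018)
  wx <- simulate_station_weather(geo$stations, params, seed = 9)
  annual <- wx |>
    dplyr::mutate(year = as.integer(format(date, "%Y"))) |>
    dplyr::summarise(temp = mean(temp), .by = "year")
  fit <- stats::lm(temp ~ year, data = annual)
  est <- coef(summary(fit))["year", ]
  expect_lt(abs(est["Estimate"] - params$warming_trend), 2 * est["Std. Error"])
})

test_that("panel simulation respects waves, immobility and determinism", {
  geo <- generate_geography(2, 3, 1, seed = 4)

  single <- simulate_panel(geo$counties, waves = 2010, n_individuals = 1, seed = 1)
  expect_equal(nrow(single), 1)

  p <- simulate_panel(geo$counties, n_individuals = 20, seed = 5)
  expect_equal(nrow(p), 60)
  expect_true(all(dplyr::count(p, person_id)$n == 3))
  moves <- dplyr::summarise(p, n = dplyr::n_distinct(county_id), .by = "person_id")
  expect_true(all(moves$n == 1))
  expect_true(all(p$weight > 0))
  expect_true(all(p$birth_year <= 2010))
  months <- as.integer(format(p$interview_date, "%m"))
  expect_true(all(months >= 5 & months <= 10))

  expect_identical(p, simulate_panel(geo$counties, n_individuals = 20, seed = 5))
  expect_error(simulate_panel(geo$counties[0, ], n_individuals = 5), "at least one")
  expect_error(
    simulate_panel(geo$counties, birth_year_range = c(1950, 2012), n_individuals = 5),
    "first wave"
  )
})

test_that("well-being generator reduces to its deterministic part", {
  geo <- generate_geography(2, 3, 1, seed = 4)
  p <- simulate_panel(geo$counties, n_individuals = 30, seed = 6)
  dgp <- dgp_params(beta_true = 0, fe_sd_individual = 0, fe_sd_date = 0,
                    noise_sd = 1e-12)
  out <- simulate_swb(p, rep(1.5, nrow(p)), dgp, seed = 1)
  expected <- dgp$alpha +
    as.matrix(p[names(dgp$control_coeffs)]) %*% dgp$control_coeffs
  expect_equal(out$swb, drop(expected), tolerance = 1e-8)
  expect_error(simulate_swb(p, rep(0, 5), dgp), "one value per panel row")
})

test_that("discretizing the outcome attenuates the recovered coefficient", {
  w <- make_world(n_individuals = 250, seed = 11)
  anoms <- build_anomalies(w$panel, w$county_daily)
  expo <- build_exposures(w$panel, w$county_daily, bins = NULL)
  beta <- -0.6
  diffs <- sapply(1:8, function(r) {
    d_lat <- dgp_params(beta_true = beta, noise_sd = 0.6)
    d_dis <- dgp_params(beta_true = beta, noise_sd = 0.6, discretize = TRUE)
    p_lat <- simulate_swb(w$panel, anoms, d_lat, seed = 100 + r)
    p_dis <- simulate_swb(w$panel, anoms, d_dis, seed = 100 + r)
    f_lat <- suppressMessages(fit_swb_model(p_lat, anoms, expo))
    f_dis <- suppressMessages(fit_swb_model(p_dis, anoms, expo))
    abs(f_dis$coefficients["anomaly"]) - abs(f_lat$coefficients["anomaly"])
  })
  expect_lt(mean(diffs), 0)
})

test_that("scenario trajectories have the prescribed shapes", {
  expect_error(generate_projection_scenarios(2, scenarios = "rcp99"),
               "Unknown scenario")

  one <- generate_projection_scenarios(1, scenarios = "middle", n_models = 1,
                                       model_offset_sd = 0, model_slope_sd = 0,
                                       seed = 1)
  ens <- dplyr::summarise(one, m = mean(temp), .by = "year")
  expect_equal(ens$m, one$temp[match(ens$year, one$year)])

  traj <- generate_projection_scenarios(2, n_models = 3, seed = 8)
  nz <- traj[traj$scenario == "netzero" & traj$model == 1 &
               traj$region_id == 1 & traj$period == "projection", ]
  inc <- diff(nz$temp[order(nz$year)])
  expect_true(all(abs(inc[nz$year[-1] > 2050]) < 1e-12))

  slopes <- traj |>
    dplyr::filter(period == "projection", year >= 2050) |>
    dplyr::summarise(
      slope = coef(stats::lm(temp ~ year))[2],
      .by = c("scenario", "model", "region_id")
    ) |>
    tidyr::pivot_wider(names_from = "scenario", values_from = "slope")
  expect_true(all(slopes$high > slopes$middle))

  # history joins the projection continuously per model/region
  gap <- traj |>
    dplyr::filter(scenario == "netzero", model == 2, region_id == 1) |>
    dplyr::arrange(year)
  expect_equal(nrow(gap), length(1950:2100))
})

test_that("age trajectories are linear and positive", {
  const <- generate_age_trajectory(2020:2030, start_age = 40, drift = 0)
  expect_true(all(const$avg_age == 40))
  drifted <- generate_age_trajectory(2020:2030, start_age = 40, drift = 0.1)
  expect_equal(drifted$avg_age[drifted$year == 2030], 41)
  expect_true(all(generate_age_trajectory()$avg_age > 0))
  expect_error(generate_age_trajectory(start_age = -1), "> 0")
})
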