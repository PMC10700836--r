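test_that("lifetime reference spans birth year through the pre-interview year", {
  s <- make_series("1951-01-01", "2018-12-31")
  ref <- lifetime_reference(s, birth_year = 1989,
                            interview_date = as.Date("2014-08-25"))
  expect_equal(attr(ref, "reference_years"), c(1989, 2013))
  expect_equal(attr(ref, "reference_years_used"), 25)
  expect_equal(as.numeric(ref), 15)

  # age 1: the reference is the single birth-year window mean
  lin <- linear_series("1990-01-01", "2014-12-31", base = 12, slope = 0.3)
  r1 <- lifetime_reference(lin, 2013, as.Date("2014-08-25"))
  h <- calendar_window_history(lin, as.Date("2014-08-25"), 30, 2013, 2013)
  expect_equal(as.numeric(r1), h$mean)

  expect_error(lifetime_reference(s, 2015, as.Date("2014-08-25")), "precede")
  expect_error(lifetime_reference(s, 1940, as.Date("2014-08-25")), "coverage")
})

test_that("fixed-period references are person-invariant and truncate at the interview", {
  lin <- linear_series("1951-01-01", "2018-12-31", slope = 0.2)
  single <- fixed_period_reference(lin, as.Date("2014-08-25"), 1990, 1990)
  h <- calendar_window_history(lin, as.Date("2014-08-25"), 30, 1990, 1990)
  expect_equal(as.numeric(single), h$mean)

  expect_warning(
    tr <- fixed_period_reference(lin, as.Date("2014-08-25"), 2000, 2020),
    "truncated"
  )
  expect_equal(attr(tr, "reference_years"), c(2000, 2013))
})

test_that("scheme coincidences hold exactly", {
  lin <- linear_series("1951-01-01", "2018-12-31", slope = 0.12)
  int <- as.Date("2014-08-25")
  # preceding n = age reproduces lifetime
  expect_equal(
    as.numeric(preceding_years_reference(lin, int, n = 25)),
    as.numeric(lifetime_reference(lin, 1989, int))
  )
  # n = 1 is last year's window mean
  expect_equal(
    as.numeric(preceding_years_reference(lin, int, n = 1)),
    calendar_window_history(lin, int, 30, 2013, 2013)$mean
  )
  # cumulative cap at or above age saturates to lifetime
  expect_equal(
    as.numeric(cumulative_age_reference(lin, 1989, int, max_age = 40)),
    as.numeric(lifetime_reference(lin, 1989, int))
  )
  # cumulative cap of one year is the birth-year window mean
  expect_equal(
    as.numeric(cumulative_age_reference(lin, 1989, int, max_age = 1)),
    calendar_window_history(lin, int, 30, 1989, 1989)$mean
  )
})

test_that("linear warming separates the schemes by the closed form", {
  m <- 0.2
  lin <- linear_series("1951-01-01", "2018-12-31", slope = m)
  int <- as.Date("2014-08-25")
  age <- 40
  birth <- 2014 - age
  life <- as.numeric(lifetime_reference(lin, birth, int))
  for (n in c(5, 10, 25)) {
    prec <- as.numeric(preceding_years_reference(lin, int, n = n))
    # recent windows are warmer: preceding-n minus lifetime = m * (age - n) / 2
    expect_equal(prec - life, m * (age - n) / 2, tolerance = 1e-10)
  }
  # under warming, an early fixed period sits below the lifetime reference
  fixed <- as.numeric(fixed_period_reference(lin, int, 1960, 1980))
  expect_lt(fixed, life)
})

test_that("sign decomposition is exact", {
  expect_equal(split_sign(1.5), tibble::tibble(positive_part = 1.5,
                                               negative_part = 0))
  expect_equal(split_sign(-0.7), tibble::tibble(positive_part = 0,
                                                negative_part = -0.7))
  expect_equal(split_sign(0), tibble::tibble(positive_part = 0,
                                             negative_part = 0))
  withr::local_seed(3)
  a <- rnorm(200)
  sp <- split_sign(a)
  expect_equal(sp$positive_part + sp$negative_part, a)
  expect_true(all(sp$positive_part >= 0 & sp$negative_part <= 0))
})

test_that("day-count anomalies match a brute-force day-by-day oracle", {
  flat <- make_series("1990-01-01", "2014-12-31")
  expect_equal(day_count_anomaly(flat, "2014-08-25", 30, 1990, 2013), 0)

  lin <- linear_series("1990-01-01", "2014-12-31", slope = 0.2)
  expect_equal(day_count_anomaly(lin, "2014-08-25", 30, 1990, 2013), 30)

  withr::local_seed(21)
  noisy <- make_series("1990-01-01", "2014-12-31",
                       function(d) rnorm(length(d), 15, 3))
  end <- as.Date("2014-08-25")
  got <- day_count_anomaly(noisy, end, 30, 1990, 2013)
  # independent loop oracle
  cnt <- 0
  for (d in as.list(seq(end - 29, end, by = "day"))) {
    hist_d <- as.Date(sprintf("%d-%s", 1990:2013, format(d, "%m-%d")))
    hist_d <- hist_d[!is.na(hist_d)]
    clim <- mean(noisy$temp[noisy$date %in% hist_d])
    if (noisy$temp[noisy$date == d] > clim) cnt <- cnt + 1
  }
  expect_equal(got, cnt)
})

test_that("years-missed rate reproduces the printed cases and is a proportion", {
  expect_equal(years_missed_rate(50, 25), 0.5)
  expect_equal(years_missed_rate(20, 25), 0.2)
  expect_equal(years_missed_rate(33, 33), 0)
  withr::local_seed(5)
  age <- sample(1:90, 50, replace = TRUE)
  n <- sample(1:60, 50, replace = TRUE)
  r <- years_missed_rate(age, n)
  expect_true(all(r >= 0 & r <= 1))
  expect_equal(r, years_missed_rate(n, age))  # symmetric by construction
  expect_error(years_missed_rate(0, 5), ">= 1")
})

test_that("vectorized anomaly builder agrees with the single-series functions", {
  w <- make_world(n_individuals = 12, seed = 19)
  anoms <- build_anomalies(w$panel, w$county_daily)
  expect_equal(nrow(anoms), nrow(w$panel))
  expect_equal(anoms$anomaly, anoms$current_mean - anoms$reference_mean)
  expect_equal(anoms$positive_part + anoms$negative_part, anoms$anomaly)

  for (i in c(1, 7, 20)) {
    row <- w$panel[i, ]
    s <- w$county_daily[w$county_daily$county_id == row$county_id,
                        c("date", "temp")]
    ref <- lifetime_reference(s, row$birth_year, row$interview_date)
    cur <- window_stats(s, row$interview_date)
    expect_equal(anoms$reference_mean[i], as.numeric(ref))
    expect_equal(anoms$current_mean[i], cur)
  }

  # preceding-years and cumulative-age drivers against their scalar versions
  pre <- build_anomalies(w$panel, w$county_daily,
                         reference_spec("preceding_years", n = 7))
  cum <- build_anomalies(w$panel, w$county_daily,
                         reference_spec("cumulative_age", max_age = 12))
  row <- w$panel[5, ]
  s <- w$county_daily[w$county_daily$county_id == row$county_id,
                      c("date", "temp")]
  expect_equal(pre$reference_mean[5],
               as.numeric(preceding_years_reference(s, row$interview_date, 7)))
  expect_equal(cum$reference_mean[5],
               as.numeric(cumulative_age_reference(s, row$birth_year,
                                                   row$interview_date, 12)))
})

test_that("a stationary noiseless climate gives zero anomalies under every scheme", {
  w <- make_flat_world(n_individuals = 20)
  for (spec in list(reference_spec("lifetime"),
                    reference_spec("fixed_period", a = 1980, b = 2000),
                    reference_spec("preceding_years", n = 10),
                    reference_spec("cumulative_age", max_age = 15))) {
    anoms <- build_anomalies(w$panel, w$county_daily, spec)
    expect_lt(max(abs(anoms$anomaly)), 1e-9)
  }
})
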