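# Random panel-shaped instance for oracle checks: two FE dimensions, a few
# regressors, positive weights.
random_instance <- function(n, n_id, n_dt, p = 2, seed) {
  withr::local_seed(seed)
  tibble::tibble(
    id = sample(sprintf("i%02d", seq_len(n_id)), n, replace = TRUE),
    dt = sample(sprintf("d%02d", seq_len(n_dt)), n, replace = TRUE),
    w = runif(n, 0.5, 2),
    !!!rlang::set_names(
      lapply(seq_len(p), function(j) rnorm(n)), paste0("x", seq_len(p))
    )
  ) |>
    dplyr::mutate(y = rowSums(dplyr::across(dplyr::starts_with("x"))) +
                    rnorm(n))
}

test_that("alternating-projection demeaning matches dummy-variable least squares", {
  for (seed in 1:5) {
    d <- random_instance(n = sample(60:200, 1), n_id = 25, n_dt = 12, seed = seed)
    dm <- within_transform(d, c("y", "x1", "x2"), c("id", "dt"), weights = "w")
    rows <- attr(dm, "rows")
    f <- fit_wls(dm$y, as.matrix(dm[c("x1", "x2")]), d$w[rows])
    # oracle: full dummy-variable weighted OLS on the same retained rows
    oracle <- stats::lm(y ~ x1 + x2 + factor(id) + factor(dt),
                        data = d[rows, ], weights = d$w[rows])
    expect_equal(unname(f$coefficients),
                 unname(coef(oracle)[c("x1", "x2")]), tolerance = 1e-8)
  }
})

test_that("one fixed-effect dimension demeans exactly in a single pass", {
  d <- random_instance(100, 10, 5, seed = 9)
  dm <- within_transform(d, c("y", "x1"), "id", weights = "w")
  rows <- attr(dm, "rows")
  g <- d$id[rows]
  wm <- tapply(dm$y * d$w[rows], g, sum) / tapply(d$w[rows], g, sum)
  expect_lt(max(abs(wm)), 1e-12)
  expect_lte(attr(dm, "iterations"), 2)
})

test_that("a balanced orthogonal two-way layout converges in two sweeps", {
  d <- tidyr::crossing(id = sprintf("i%d", 1:8), dt = sprintf("d%d", 1:6))
  withr::local_seed(2)
  d$x <- rnorm(nrow(d))
  dm <- within_transform(d, "x", c("id", "dt"))
  expect_lte(attr(dm, "iterations"), 2)
})

test_that("fixed-effect singletons are dropped iteratively and counted", {
  d <- tibble::tibble(
    id = c("a", "a", "b", "c", "c"),
    dt = c("1", "2", "2", "3", "4"),
    x = rnorm(5)
  )
  # b is an id singleton; dropping it makes dt=2 a singleton, which then
  # makes a an id singleton: the cascade leaves only c's pair... whose dt
  # groups are themselves singletons, so everything goes.
  expect_error(within_transform(d, "x", c("id", "dt")), "singleton")
})

test_that("weighted least squares matches independent solvers", {
  withr::local_seed(4)
  n <- 80
  X <- cbind(1, matrix(rnorm(n * 3), n))
  colnames(X) <- c("c", "a", "b", "d")
  beta <- c(1, -2, 0.5, 0)
  y <- drop(X %*% beta) + rnorm(n)
  w <- runif(n, 0.2, 3)

  f <- fit_wls(y, X, w)
  # pseudoinverse oracle on the weighted normal equations
  oracle <- drop(solve(t(X) %*% (w * X), t(X) %*% (w * y)))
  expect_equal(unname(f$coefficients), unname(oracle), tolerance = 1e-10)

  f0 <- fit_wls(y, X)
  expect_equal(unname(f0$coefficients), unname(coef(stats::lm(y ~ X - 1))),
               tolerance = 1e-10)

  exact <- fit_wls(drop(X %*% beta), X, w)
  expect_lt(max(abs(exact$residuals)), 1e-10)

  Xbad <- cbind(X, dup = X[, "a"])
  expect_error(fit_wls(y, Xbad, w), "collinear")
  expect_error(fit_wls(y, X, rep(0, n)), "positive")
})

test_that("two-way clustered covariance reduces correctly and matches sandwich", {
  withr::local_seed(6)
  n <- 60
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rnorm(n))
  y <- 1 + 0.5 * X[, "x1"] - 0.3 * X[, "x2"] + rnorm(n)
  w <- runif(n, 0.5, 2)
  a <- sample(sprintf("a%d", 1:6), n, replace = TRUE)
  b <- sample(sprintf("b%d", 1:5), n, replace = TRUE)
  f <- fit_wls(y, X, w)

  # degenerate: both dimensions all-singletons -> heteroskedasticity-robust
  singl <- as.character(seq_len(n))
  Vs <- twoway_cluster_cov(X, f$residuals, w, singl, singl)
  bread <- solve(crossprod(X * sqrt(w)))
  u <- X * (w * f$residuals)
  hc <- (n / (n - 1)) * ((n - 1) / (n - ncol(X))) * bread %*% crossprod(u) %*% bread
  expect_equal(unclass(Vs), hc, tolerance = 1e-10, ignore_attr = TRUE)

  # second dimension all distinct -> one-way clustering on the first
  Vab <- twoway_cluster_cov(X, f$residuals, w, a, singl)
  Sa <- rowsum(u, a)
  Ga <- nrow(Sa)
  Va <- (Ga / (Ga - 1)) * ((n - 1) / (n - ncol(X))) * bread %*% crossprod(Sa) %*% bread
  expect_equal(unclass(Vab), Va, tolerance = 1e-10, ignore_attr = TRUE)

  # reference econometrics implementation on the 60-row instance
  x1 <- X[, "x1"]
  x2 <- X[, "x2"]
  lmfit <- stats::lm(y ~ x1 + x2, weights = w)
  Vref <- sandwich::vcovCL(lmfit, cluster = ~ a + b, type = "HC1",
                           cadjust = TRUE)
  Vmine <- twoway_cluster_cov(X, f$residuals, w, a, b)
  expect_equal(unclass(Vmine), unclass(Vref), tolerance = 1e-6,
               ignore_attr = TRUE)

  expect_error(twoway_cluster_cov(X, f$residuals, w, rep("z", n), b),
               "single cluster")
})

test_that("the full fit recovers a known effect and drops absorbed controls", {
  w <- make_world(n_individuals = 300, seed = 23)
  anoms <- build_anomalies(w$panel, w$county_daily)
  expo <- build_exposures(w$panel, w$county_daily, bins = NULL)
  dgp <- dgp_params(beta_true = -0.5, noise_sd = 0.3)
  p2 <- simulate_swb(w$panel, anoms, dgp, seed = 31)
  msgs <- capture_messages(fit <- fit_swb_model(p2, anoms, expo))
  expect_match(paste(msgs, collapse = " "), "age")
  expect_true(all(c("age", "education") %in% fit$dropped_controls))

  td <- tidy(fit)
  row <- td[td$term == "anomaly", ]
  expect_lt(row$conf.low, -0.5)
  expect_gt(row$conf.high, -0.5)

  g <- glance(fit)
  expect_equal(g$nobs, fit$n_obs)
  expect_equal(unname(fit$se), unname(sqrt(diag(fit$vcov))))
})

test_that("adding a fixed-effect-constant column leaves the estimate unchanged", {
  w <- make_world(n_individuals = 120, seed = 29)
  anoms <- build_anomalies(w$panel, w$county_daily)
  expo <- build_exposures(w$panel, w$county_daily, bins = NULL)
  p2 <- simulate_swb(w$panel, anoms, dgp_params(), seed = 3)
  base_fit <- suppressMessages(fit_swb_model(p2, anoms, expo))
  # a person-constant synthetic control is absorbed and harmless
  p3 <- dplyr::mutate(p2, shoe_size = as.numeric(factor(person_id)) %% 7)
  spec2 <- model_spec(controls = c("income", "age", "married", "education",
                                   "employed", "discomfort", "shoe_size"))
  aug_fit <- suppressMessages(fit_swb_model(p3, anoms, expo, spec = spec2))
  expect_equal(aug_fit$coefficients["anomaly"],
               base_fit$coefficients["anomaly"], tolerance = 1e-10)
  expect_true("shoe_size" %in% aug_fit$dropped_controls)
})

test_that("split and bins terms estimate the intended designs", {
  w <- make_world(n_individuals = 300, seed = 37)
  anoms <- build_anomalies(w$panel, w$county_daily)
  expo <- build_exposures(w$panel, w$county_daily)

  # only hotter-than-expected anomalies enter the outcome
  withr::local_seed(41)
  dgp <- dgp_params(beta_true = 0, noise_sd = 0.3)
  p2 <- simulate_swb(w$panel, anoms, dgp, seed = 43)
  p2$swb <- p2$swb - 0.5 * anoms$positive_part
  fit <- suppressMessages(
    fit_swb_model(p2, anoms, expo, spec = model_spec(term = "split"))
  )
  td <- tidy(fit)
  pos <- td[td$term == "positive_part", ]
  neg <- td[td$term == "negative_part", ]
  expect_lt(pos$conf.high, 0)                       # hot side clearly negative
  expect_lt(abs(neg$estimate), 2.6 * neg$std.error) # cold side indistinct from 0

  # flat-response outcome: every bin coefficient is (numerically) nil
  p3 <- simulate_swb(w$panel, rep(0, nrow(w$panel)),
                     dgp_params(beta_true = 0, noise_sd = 0.01,
                                fe_sd_individual = 0, fe_sd_date = 0),
                     seed = 47)
  fitb <- suppressMessages(
    fit_swb_model(p3, NULL, expo, spec = model_spec(term = "bins"))
  )
  expect_true(all(abs(fitb$coefficients[fitb$term_cols]) < 0.01))
  expect_false(any(grepl("18,21", fitb$term_cols)))  # omitted bin excluded
})

test_that("stratified fits split the sample as requested", {
  w <- make_world(n_individuals = 150, seed = 53)
  anoms <- build_anomalies(w$panel, w$county_daily)
  expo <- build_exposures(w$panel, w$county_daily, bins = NULL)
  p2 <- simulate_swb(w$panel, anoms, dgp_params(), seed = 3)

  # per-wave fits cannot absorb person effects (one row per person and
  # wave), so the cross-sectional spec uses county fixed effects instead
  cs_spec <- model_spec(fe = c("county_id", "interview_date"))
  by_wave <- suppressWarnings(suppressMessages(
    stratified_fit(p2, anoms, expo, spec = cs_spec, grouping = "wave")
  ))
  expect_equal(nrow(by_wave), 3)
  ok <- !vapply(by_wave$fit, is.null, logical(1))
  expect_true(any(ok))
  expect_equal(sum(by_wave$n_obs[ok] > 0), sum(ok))

  # single custom group reproduces the pooled fit
  p2$all <- "pooled"
  pooled <- suppressMessages(
    stratified_fit(p2, anoms, expo, grouping = "all")
  )
  direct <- suppressMessages(fit_swb_model(p2, anoms, expo))
  expect_equal(pooled$fit[[1]]$coefficients, direct$coefficients)

  quart <- suppressWarnings(suppressMessages(
    stratified_fit(p2, anoms, expo, grouping = "climate_quartile",
                   county_daily = w$county_daily)
  ))
  expect_false(is.null(attr(quart, "group_table")))
  expect_lte(nrow(quart), 4)
})

test_that("reference sweeps coincide with the lifetime fit at matched ages", {
  # uniform-age sample: everyone born the same year
  geo <- generate_geography(4, 6, 2, seed = 61)
  wx <- simulate_station_weather(geo$stations, climate_params(), seed = 62)
  cd <- interpolate_counties(wx, geo$stations, geo$counties)
  panel <- simulate_panel(geo$counties, n_individuals = 120,
                          birth_year_range = c(1970, 1970), seed = 63)
  anoms <- build_anomalies(panel, cd)
  expo <- build_exposures(panel, cd, bins = NULL)
  p2 <- simulate_swb(panel, anoms, dgp_params(beta_true = -0.3, noise_sd = 0.3),
                     seed = 64)

  life <- suppressMessages(fit_swb_model(p2, anoms, expo))
  # ages at the three waves are 40, 44, 48: no single n matches all waves,
  # so sweep a panel restricted to one wave where n = age exactly
  p1w <- p2[p2$wave == 2010, ]
  life1 <- suppressMessages(
    fit_swb_model(p1w, anoms, expo,
                  spec = model_spec(fe = c("county_id", "interview_date")))
  )
  sw <- suppressMessages(
    reference_sweep(p1w, cd, expo,
                    spec = model_spec(fe = c("county_id", "interview_date")),
                    scheme = "preceding_years", grid = c(40))
  )
  expect_equal(sw$estimate, unname(life1$coefficients["anomaly"]),
               tolerance = 1e-10)
  expect_equal(sw$mean_years_missed, 0)

  # years-missed column: age-50 sample referenced on 25 preceding years
  sw25 <- suppressMessages(
    reference_sweep(
      dplyr::mutate(p1w, birth_year = 1960, age = 50), cd, expo,
      spec = model_spec(fe = c("county_id", "interview_date")),
      scheme = "preceding_years", grid = c(25)
    )
  )
  expect_equal(sw25$mean_years_missed, 0.5)
})
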