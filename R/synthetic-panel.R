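#' Simulate a longitudinal survey panel of non-migrating respondents
#'
#' Each respondent is assigned a county at birth and never moves, so their
#' lifetime temperature exposure is fully determined by the county weather
#' series, their birth year and the interview dates. One interview date per
#' wave is drawn inside the interview window (summer and autumn by default,
#' when most survey interviews take place). Time-varying controls (income,
#' age, marital status, education, employment, a recent-discomfort indicator)
#' and positive survey weights are populated.
#'
#' @param counties County catalog tibble (`county_id`, `region_id`, ...).
#' @param waves Integer vector of survey wave years.
#' @param n_individuals Number of respondents.
#' @param birth_year_range Length-2 integer vector; birth years are drawn
#'   uniformly in this range. The maximum must not exceed the first wave year.
#' @param interview_window Length-2 character vector of month-day bounds
#'   (`"mm-dd"`) within each wave year.
#' @param n_interview_dates Number of distinct field dates per wave from
#'   which interview dates are drawn.
#' @param seed Integer seed.
#'
#' @return Tibble with one row per person-wave: `person_id`, `county_id`,
#'   `region_id`, `birth_year`, `wave`, `interview_date`, `age`, `income`,
#'   `married`, `education`, `employed`, `discomfort`, `weight`.
#' @export
#' @examples
#' geo <- generate_geography(3, 5, 2, seed = 1)
#' simulate_panel(geo$counties, n_individuals = 4, seed = 2)
simulate_panel <- function(counties,
                           waves = c(2010, 2014, 2018),
                           n_individuals = 1000,
                           birth_year_range = c(1955, 1990),
                           interview_window = c("05-01", "10-31"),
                           n_interview_dates = 20,
                           seed = NULL) {
  if (is.null(counties) || nrow(counties) == 0) {
    abort("`counties` must contain at least one county.")
  }
  if (max(birth_year_range) > min(waves)) {
    abort("`birth_year_range` must not extend past the first wave year.")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  persons <- tibble(
    person_id = sprintf("P%05d", seq_len(n_individuals)),
    county_id = sample(counties$county_id, n_individuals, replace = TRUE),
    birth_year = {
      yrs <- seq(birth_year_range[1], birth_year_range[2])
      yrs[sample.int(length(yrs), n_individuals, replace = TRUE)]
    },
    education = sample(0:16, n_individuals, replace = TRUE),
    weight = rlnorm(n_individuals, 0, 0.3),
    base_income = rlnorm(n_individuals, 9, 0.7)
  )
  persons <- dplyr::left_join(
    persons, dplyr::select(counties, "county_id", "region_id"),
    by = "county_id"
  )

  panel <- tidyr::crossing(persons, wave = as.integer(waves))
  n <- nrow(panel)
  # Interviews are fielded on a limited set of distinct dates per wave:
  # survey teams see many respondents per field day, which keeps exact
  # interview-date fixed effects identifiable at any sample size.
  panel$interview_date <- as.Date(NA)
  for (wv in as.integer(waves)) {
    ws <- as.Date(paste0(wv, "-", interview_window[1]))
    span <- as.integer(as.Date(paste0(wv, "-", interview_window[2])) - ws)
    k <- min(n_interview_dates, span + 1)
    field_dates <- ws + sort(sample.int(span + 1, k)) - 1L
    sel <- panel$wave == wv
    panel$interview_date[sel] <-
      field_dates[sample.int(k, sum(sel), replace = TRUE)]
  }

  panel |>
    dplyr::mutate(
      age = .data$wave - .data$birth_year,
      income = log(.data$base_income * exp(rnorm(n, 0.02 * (.data$wave - min(waves)), 0.2))),
      married = rbinom(n, 1, pmin(0.95, 0.2 + 0.015 * .data$age)),
      employed = rbinom(n, 1, 0.7),
      discomfort = rbinom(n, 1, 0.25)
    ) |>
    dplyr::select(
      "person_id", "county_id", "region_id", "birth_year", "wave",
      "interview_date", "age", "income", "married", "education",
      "employed", "discomfort", "weight"
    ) |>
    dplyr::arrange(.data$person_id, .data$wave)
}

#' Parameters of the well-being data-generating process
#'
#' The generative twin of the estimated panel model: well-being is a linear
#' function of the temperature anomaly, individual controls, an individual
#' fixed effect, an interview-date fixed effect and i.i.d. noise. The default
#' marginal effect of a 1 degC anomaly is -0.023 well-being points.
#' Discretization to the survey's 1-5 scale is off by default so that
#' parameter-recovery checks are clean; rounding attenuates the recovered
#' coefficient toward zero.
#'
#' @param beta_true Marginal effect of the anomaly, well-being per degC.
#' @param control_coeffs Named numeric vector of control coefficients.
#' @param alpha Grand intercept (the survey mean well-being is about 4.1).
#' @param fe_sd_individual,fe_sd_date SDs of the individual and date effects.
#' @param noise_sd SD of the idiosyncratic error (> 0).
#' @param discretize Clip to \[1, 5\] and round to the survey scale?
#'
#' @return A list of class `dgp_params`.
#' @export
dgp_params <- function(beta_true = -0.023,
                       control_coeffs = c(income = 0.02, age = 0, married = 0.15,
                                          education = 0.01, employed = 0.02,
                                          discomfort = -0.09),
                       alpha = 4.1,
                       fe_sd_individual = 0.5,
                       fe_sd_date = 0.2,
                       noise_sd = 1,
                       discretize = FALSE) {
  if (noise_sd <= 0) abort("`noise_sd` must be > 0.")
  structure(
    list(
      beta_true = beta_true, control_coeffs = control_coeffs, alpha = alpha,
      fe_sd_individual = fe_sd_individual, fe_sd_date = fe_sd_date,
      noise_sd = noise_sd, discretize = discretize
    ),
    class = "dgp_params"
  )
}

#' Simulate subjective well-being outcomes for a panel
#'
#' Generates `swb = alpha + beta_true * anomaly + controls %*% coeffs +
#' gamma_person + theta_date + noise`. When `dgp$discretize` is `TRUE` the
#' latent outcome is clipped to \[1, 5\] and rounded (kept in `swb_latent`);
#' the rounding attenuates the recoverable anomaly coefficient.
#'
#' @param panel Panel tibble from [simulate_panel()].
#' @param anomalies Either a numeric vector aligned with `panel` rows or an
#'   anomaly tibble from [build_anomalies()] (joined on `person_id`, `wave`).
#' @param dgp A [dgp_params()] object.
#' @param seed Integer seed.
#'
#' @return `panel` with an `swb` column appended (and `swb_latent` when
#'   discretizing).
#' @export
simulate_swb <- function(panel, anomalies, dgp = dgp_params(), seed = NULL) {
  stopifnot(inherits(dgp, "dgp_params"))
  if (is.data.frame(anomalies)) {
    merged <- dplyr::left_join(
      dplyr::select(panel, "person_id", "wave"),
      dplyr::select(anomalies, "person_id", "wave", "anomaly"),
      by = c("person_id", "wave")
    )
    if (anyNA(merged$anomaly)) {
      abort("`anomalies` does not cover every person-wave row of `panel`.")
    }
    a <- merged$anomaly
  } else {
    if (length(anomalies) != nrow(panel)) {
      abort("`anomalies` must have one value per panel row.")
    }
    a <- as.numeric(anomalies)
  }
  if (!is.null(seed)) withr::local_seed(seed)

  n <- nrow(panel)
  ctrl <- dgp$control_coeffs
  xb <- rep(0, n)
  for (nm in names(ctrl)) {
    if (!nm %in% names(panel)) abort(paste0("Control `", nm, "` not found in `panel`."))
    xb <- xb + ctrl[[nm]] * panel[[nm]]
  }

  gamma <- rnorm(length(unique(panel$person_id)), 0, dgp$fe_sd_individual)
  names(gamma) <- unique(panel$person_id)
  dates <- unique(panel$interview_date)
  theta <- rnorm(length(dates), 0, dgp$fe_sd_date)
  names(theta) <- as.character(dates)

  y <- dgp$alpha + dgp$beta_true * a + xb +
    gamma[panel$person_id] + theta[as.character(panel$interview_date)] +
    rnorm(n, 0, dgp$noise_sd)
  y <- unname(y)

  out <- panel
  if (dgp$discretize) {
    out$swb_latent <- y
    out$swb <- round(pmin(5, pmax(1, y)))
  } else {
    out$swb <- y
  }
  out
}
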