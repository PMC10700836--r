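#' Reference-temperature scheme specification
#'
#' The anomaly for a person-wave observation is the current exposure-window
#' mean minus a historical reference mean for the same calendar window. Four
#' reference schemes are supported:
#'
#' * `"lifetime"`: average over every year from the respondent's birth year to
#'   the year immediately preceding the interview — the individualized
#'   reference that encodes personal acclimatization;
#' * `"fixed_period"`: average over a fixed span of years (`a` to `b`),
#'   identical for everyone in a county interviewed on the same date;
#' * `"preceding_years"`: average over the `n` years preceding the interview;
#' * `"cumulative_age"`: average from the birth year up to at most
#'   `max_age` years of life.
#'
#' @param scheme One of `"lifetime"`, `"fixed_period"`, `"preceding_years"`,
#'   `"cumulative_age"`.
#' @param a,b First and last year of the fixed period (`a <= b`).
#' @param n Number of preceding years (>= 1).
#' @param max_age Maximum age included in the cumulative scheme (>= 1).
#' @param window_days Exposure-window length in days.
#'
#' @return A list of class `reference_spec`.
#' @export
reference_spec <- function(scheme = c("lifetime", "fixed_period",
                                      "preceding_years", "cumulative_age"),
                           a = 1980, b = 2000, n = 10, max_age = 40,
                           window_days = 30) {
  scheme <- match.arg(scheme)
  if (scheme == "fixed_period" && a > b) abort("`a` must be <= `b`.")
  if (scheme == "preceding_years" && n < 1) abort("`n` must be >= 1.")
  if (scheme == "cumulative_age" && max_age < 1) abort("`max_age` must be >= 1.")
  structure(
    list(scheme = scheme, a = a, b = b, n = n, max_age = max_age,
         window_days = window_days),
    class = "reference_spec"
  )
}

# Label used in output tables.
.reference_label <- function(spec) {
  switch(spec$scheme,
    lifetime = "lifetime",
    fixed_period = sprintf("fixed_%d_%d", spec$a, spec$b),
    preceding_years = sprintf("preceding_%d", spec$n),
    cumulative_age = sprintf("cumulative_age_%d", spec$max_age)
  )
}

#' Lifetime (individualized) reference temperature
#'
#' Mean of the per-year calendar-window means from the respondent's birth year
#' through the year immediately preceding the interview. A 25-year-old
#' interviewed in late August 2014 is referenced against the same late-summer
#' window averaged over 1989 through 2013 inclusive.
#'
#' @param series County daily series (tibble with `date`, `temp`).
#' @param birth_year Respondent's birth year (before the interview year).
#' @param interview_date Interview date.
#' @param window_days Window length in days.
#' @param variable Column to average.
#'
#' @return The reference mean, with attributes `reference_years`
#'   (`c(first, last)` calendar years) and `reference_years_used`.
#' @export
lifetime_reference <- function(series, birth_year, interview_date,
                               window_days = 30, variable = "temp") {
  iy <- as.integer(format(as.Date(interview_date), "%Y"))
  if (birth_year >= iy) abort("`birth_year` must precede the interview year.")
  h <- calendar_window_history(series, interview_date, window_days,
                               from_year = birth_year, to_year = iy - 1,
                               variable = variable)
  structure(mean(h$mean),
            reference_years = c(birth_year, iy - 1L),
            reference_years_used = iy - birth_year)
}

#' Fixed-period reference temperature
#'
#' Mean of the per-year window means for years `a` through `b` inclusive —
#' identical for all respondents in a county interviewed on the same date.
#' Years at or after the interview year are truncated away with a warning:
#' a reference never looks past the year preceding the interview.
#'
#' @inheritParams lifetime_reference
#' @param a,b Inclusive year range of the fixed period.
#' @export
fixed_period_reference <- function(series, interview_date, a, b,
                                   window_days = 30, variable = "temp") {
  iy <- as.integer(format(as.Date(interview_date), "%Y"))
  if (b >= iy) {
    warn(paste0("Fixed period truncated at ", iy - 1,
                " (the year preceding the interview)."))
    b <- iy - 1
  }
  if (a > b) abort("Fixed period is empty after truncation.")
  h <- calendar_window_history(series, interview_date, window_days,
                               from_year = a, to_year = b, variable = variable)
  structure(mean(h$mean),
            reference_years = c(a, b),
            reference_years_used = b - a + 1L)
}

#' Preceding-years reference temperature
#'
#' Mean of the per-year window means over the `n` years immediately preceding
#' the interview year. With `n` equal to the respondent's age this coincides
#' exactly with the lifetime reference.
#'
#' @inheritParams lifetime_reference
#' @param n Number of preceding years (>= 1).
#' @export
preceding_years_reference <- function(series, interview_date, n,
                                      window_days = 30, variable = "temp") {
  if (n < 1) abort("`n` must be >= 1.")
  iy <- as.integer(format(as.Date(interview_date), "%Y"))
  h <- calendar_window_history(series, interview_date, window_days,
                               from_year = iy - n, to_year = iy - 1,
                               variable = variable)
  structure(mean(h$mean),
            reference_years = c(iy - n, iy - 1L),
            reference_years_used = as.integer(n))
}

#' Cumulative-age reference temperature
#'
#' Mean of the per-year window means from the birth year up to at most
#' `max_age` years of life (and never past the year preceding the interview).
#' With `max_age` at or above the respondent's age this saturates to the
#' lifetime reference.
#'
#' @inheritParams lifetime_reference
#' @param max_age Oldest age (in years of life, birth year = 1) included.
#' @export
cumulative_age_reference <- function(series, birth_year, interview_date,
                                     max_age, window_days = 30,
                                     variable = "temp") {
  if (max_age < 1) abort("`max_age` must be >= 1.")
  iy <- as.integer(format(as.Date(interview_date), "%Y"))
  if (birth_year >= iy) abort("`birth_year` must precede the interview year.")
  to <- min(birth_year + max_age - 1, iy - 1)
  h <- calendar_window_history(series, interview_date, window_days,
                               from_year = birth_year, to_year = to,
                               variable = variable)
  structure(mean(h$mean),
            reference_years = c(birth_year, as.integer(to)),
            reference_years_used = as.integer(to - birth_year + 1L))
}

#' Decompose anomalies into hotter- and colder-than-expected parts
#'
#' `positive_part = max(anomaly, 0)` ("hotter-than-expected") and
#' `negative_part = min(anomaly, 0)` ("colder-than-expected");
#' the two parts always reconstruct the anomaly exactly.
#'
#' @param anomaly Numeric vector of anomalies (degC).
#' @return Tibble with columns `positive_part`, `negative_part`.
#' @export
#' @examples
#' split_sign(c(1.5, -0.7, 0))
split_sign <- function(anomaly) {
  tibble(
    positive_part = pmax(anomaly, 0),
    negative_part = pmin(anomaly, 0)
  )
}

#' Day-count anomaly: days hotter than the historical average
#'
#' Counts the days in the exposure window whose temperature exceeds the
#' historical mean temperature of the same month-day over a fixed span of
#' years — a robustness alternative to the degree-valued anomaly that is
#' insensitive to a few extreme days.
#'
#' @inheritParams window_stats
#' @param history_from,history_to Inclusive year range of the historical
#'   climatology.
#'
#' @return Integer count in `[0, window_days]`.
#' @export
day_count_anomaly <- function(series, end_date, window_days = 30,
                              history_from, history_to, variable = "temp") {
  end_date <- as.Date(end_date)
  idx <- .series_index(series, variable)
  start <- end_date - (window_days - 1)
  .win_mean(idx, start, end_date, context = paste0("ending ", format(end_date)))

  days <- seq(start, end_date, by = "day")
  md <- format(days, "%m-%d")
  vals <- idx$values[as.integer(days - idx$first) + 1L]

  years <- seq(history_from, history_to)
  hist_dates <- as.Date(outer(md, years, function(m, y) paste0(y, "-", m)))
  dim(hist_dates) <- c(length(md), length(years))
  in_range <- !is.na(hist_dates) & hist_dates >= idx$first & hist_dates <= idx$last
  if (!any(in_range)) {
    abort("No historical coverage for the requested climatology years.")
  }
  missing_rows <- rowSums(in_range) == 0
  if (any(missing_rows)) {
    abort(paste0("No historical coverage for month-day ", md[missing_rows][1],
                 " in ", history_from, "-", history_to, "."))
  }
  hv <- matrix(NA_real_, nrow = length(md), ncol = length(years))
  hv[in_range] <- idx$values[as.integer(hist_dates[in_range] - idx$first) + 1L]
  clim <- rowMeans(hv, na.rm = TRUE)
  sum(vals > clim)
}

#' Years-missed rate of a fixed-length reference window
#'
#' The mismatch between an `n`-year reference window and a person's lifetime:
#' `|age - n| / max(age, n)`. Under-coverage when `n < age` (a 50-year-old
#' referenced on 25 preceding years misses half their life: 0.50) and
#' over-inclusion when `n > age` (a 20-year-old referenced on 25 years:
#' (25 - 20)/25 = 0.20).
#'
#' @param age Respondent age in years (>= 1).
#' @param n Reference window length in years (>= 1).
#' @return Proportion in `[0, 1]`, vectorized over inputs.
#' @export
#' @examples
#' years_missed_rate(50, 25)
#' years_missed_rate(20, 25)
years_missed_rate <- function(age, n) {
  if (any(age < 1) || any(n < 1)) abort("`age` and `n` must be >= 1.")
  abs(age - n) / pmax(age, n)
}

# ---- vectorized per-observation machinery --------------------------------

#' Per-year calendar-window means for every panel observation
#'
#' For each person-wave row, computes the mean temperature of the exposure
#' window transposed to every year from `from_year` (the birth year by
#' default) through the year preceding the interview. This long table is the
#' shared input from which every reference scheme is an aggregation, so
#' scheme sweeps reuse it rather than re-reading the daily series.
#'
#' @param panel Panel tibble (needs `person_id`, `wave`, `county_id`,
#'   `birth_year`, `interview_date`).
#' @param county_daily County daily series for all counties.
#' @param window_days Exposure-window length in days.
#' @param from_year `NULL` for each person's birth year, or an integer first
#'   year applied to all observations (capped below by no one's requirement —
#'   coverage is validated against the series).
#' @param variable Weather column to average.
#'
#' @return Tibble: `person_id`, `wave`, `year`, `win_mean`.
#' @export
window_history <- function(panel, county_daily, window_days = 30,
                           from_year = NULL, variable = "temp") {
  cidx <- .county_index(county_daily, variable)
  iy <- as.integer(format(panel$interview_date, "%Y"))
  from <- if (is.null(from_year)) panel$birth_year else rep(from_year, nrow(panel))
  to <- iy - 1L
  if (any(from > to)) {
    abort("Every observation needs at least one historical year before the interview.")
  }
  reps <- to - from + 1L
  obs <- rep(seq_len(nrow(panel)), reps)
  year <- sequence(reps) - 1L + from[obs]
  win <- .transposed_window(panel$interview_date[obs], window_days, year)
  tibble(
    person_id = panel$person_id[obs],
    wave = panel$wave[obs],
    year = as.integer(year),
    win_mean = .county_win_mean(cidx, panel$county_id[obs], win$start, win$end)
  )
}

#' Build the anomaly set for a panel under a reference scheme
#'
#' Computes, per person-wave observation, the current exposure-window mean,
#' the reference mean under `reference`, the anomaly and its sign
#' decomposition.
#'
#' @param panel Panel tibble.
#' @param county_daily County daily series.
#' @param reference A [reference_spec()].
#' @param history Optional precomputed [window_history()] table covering the
#'   years the scheme needs (computed internally when `NULL`).
#' @param variable Weather column.
#'
#' @return Tibble with one row per person-wave: `person_id`, `wave`,
#'   `county_id`, `interview_date`, `scheme`, `current_mean`,
#'   `reference_mean`, `anomaly`, `positive_part`, `negative_part`,
#'   `reference_years_used`. The anomaly mean and SD are attached as the
#'   `"anomaly_summary"` attribute.
#' @export
#' @examples
#' \dontrun{
#' anoms <- build_anomalies(panel, county_daily, reference_spec("lifetime"))
#' }
build_anomalies <- function(panel, county_daily,
                            reference = reference_spec("lifetime"),
                            history = NULL, variable = "temp") {
  stopifnot(inherits(reference, "reference_spec"))
  w <- reference$window_days
  iy <- as.integer(format(panel$interview_date, "%Y"))

  lo_hi <- switch(reference$scheme,
    lifetime = list(lo = panel$birth_year, hi = iy - 1L),
    fixed_period = {
      b <- reference$b
      if (any(b >= iy)) {
        warn("Fixed period truncated at the year preceding the interview for some observations.")
      }
      list(lo = rep(reference$a, nrow(panel)), hi = pmin(b, iy - 1L))
    },
    preceding_years = list(lo = iy - reference$n, hi = iy - 1L),
    cumulative_age = list(
      lo = panel$birth_year,
      hi = pmin(panel$birth_year + reference$max_age - 1L, iy - 1L)
    )
  )
  if (any(lo_hi$lo > lo_hi$hi)) abort("Empty reference window for some observations.")

  if (is.null(history)) {
    history <- window_history(panel, county_daily, window_days = w,
                              from_year = if (reference$scheme %in%
                                              c("fixed_period", "preceding_years"))
                                min(lo_hi$lo) else NULL,
                              variable = variable)
  }
  obs_key <- paste(panel$person_id, panel$wave)
  h_obs <- match(paste(history$person_id, history$wave), obs_key)
  keep <- history$year >= lo_hi$lo[h_obs] & history$year <= lo_hi$hi[h_obs]
  # coverage: every observation must contribute exactly hi - lo + 1 years
  n_yr <- tabulate(h_obs[keep], nbins = nrow(panel))
  need <- lo_hi$hi - lo_hi$lo + 1L
  if (any(n_yr != need)) {
    b <- which(n_yr != need)[1]
    abort(paste0("History table misses reference years for ", panel$person_id[b],
                 " wave ", panel$wave[b], "; recompute `history` with a wider range."))
  }
  ref_mean <- rowsum(history$win_mean[keep], h_obs[keep])[, 1] / n_yr

  cidx <- .county_index(county_daily, variable)
  cur <- .county_win_mean(cidx, panel$county_id,
                          panel$interview_date - (w - 1), panel$interview_date)

  anomaly <- cur - ref_mean
  out <- tibble(
    person_id = panel$person_id,
    wave = panel$wave,
    county_id = panel$county_id,
    interview_date = panel$interview_date,
    scheme = .reference_label(reference),
    current_mean = cur,
    reference_mean = unname(ref_mean),
    anomaly = unname(anomaly),
    positive_part = pmax(unname(anomaly), 0),
    negative_part = pmin(unname(anomaly), 0),
    reference_years_used = as.integer(need)
  )
  attr(out, "anomaly_summary") <- c(mean = mean(out$anomaly), sd = sd(out$anomaly))
  out
}
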