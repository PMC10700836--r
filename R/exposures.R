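#' Build person-wave exposure measures from county daily weather
#'
#' Computes, for each person-wave observation, the exposure-window means of
#' every weather variable (used as weather controls, entered up to second
#' order at estimation) and the per-bin day counts of daily temperature.
#'
#' @param panel Panel tibble.
#' @param county_daily County daily series.
#' @param window_days Exposure-window length in days.
#' @param bins A [bin_spec()], or `NULL` to skip bin counts.
#' @param variables Weather columns to average.
#'
#' @return Tibble keyed by `person_id`, `wave` with columns `<var>_mean` and
#'   `bin_<label>` day counts.
#' @export
build_exposures <- function(panel, county_daily, window_days = 30,
                            bins = bin_spec(),
                            variables = c("temp", "wind", "humidity",
                                          "precip", "sun_hours")) {
  variables <- intersect(variables, names(county_daily))
  out <- tibble(person_id = panel$person_id, wave = panel$wave)
  start <- panel$interview_date - (window_days - 1)
  for (v in variables) {
    cidx <- .county_index(county_daily, v)
    out[[paste0(v, "_mean")]] <-
      .county_win_mean(cidx, panel$county_id, start, panel$interview_date)
  }

  if (!is.null(bins)) {
    stopifnot(inherits(bins, "bin_spec"))
    cidx <- .county_index(county_daily, "temp")
    n <- nrow(panel)
    obs <- rep(seq_len(n), each = window_days)
    day <- rep(start, each = window_days) + rep(seq_len(window_days) - 1L, n)
    j <- match(panel$county_id[obs], cidx$county)
    pos <- cidx$row0[j] + as.integer(day - cidx$first[j]) + 1L
    lab <- .bin_assign(cidx$values[pos], bins)
    counts <- table(obs = factor(obs, levels = seq_len(n)),
                    bin = factor(lab, levels = bins$labels))
    cm <- matrix(as.integer(counts), nrow = n)
    colnames(cm) <- paste0("bin_", bins$labels)
    out <- dplyr::bind_cols(out, as_tibble(cm))
  }
  out
}

#' Day-count anomalies for every panel observation
#'
#' Vectorized counterpart of [day_count_anomaly()]: for each person-wave
#' observation, the number of exposure-window days whose temperature exceeds
#' the month-day climatology over a fixed span of years (the same span for
#' every observation).
#'
#' @inheritParams build_exposures
#' @param history_from,history_to Inclusive climatology year range.
#'
#' @return Tibble `person_id`, `wave`, `day_count_above`.
#' @export
build_day_counts <- function(panel, county_daily, window_days = 30,
                             history_from, history_to) {
  hist <- county_daily |>
    dplyr::filter(as.integer(format(.data$date, "%Y")) >= history_from,
                  as.integer(format(.data$date, "%Y")) <= history_to) |>
    dplyr::mutate(md = format(.data$date, "%m-%d")) |>
    dplyr::summarise(clim = mean(.data$temp),
                     .by = c("county_id", "md"))
  if (nrow(hist) == 0) abort("No county-daily coverage inside the climatology years.")

  cidx <- .county_index(county_daily, "temp")
  n <- nrow(panel)
  start <- panel$interview_date - (window_days - 1)
  obs <- rep(seq_len(n), each = window_days)
  day <- rep(start, each = window_days) + rep(seq_len(window_days) - 1L, n)
  j <- match(panel$county_id[obs], cidx$county)
  pos <- cidx$row0[j] + as.integer(day - cidx$first[j]) + 1L
  temp <- cidx$values[pos]

  key <- paste(panel$county_id[obs], format(day, "%m-%d"))
  clim <- hist$clim[match(key, paste(hist$county_id, hist$md))]
  if (anyNA(clim)) {
    abort("Climatology is missing some county month-days; widen the history range.")
  }
  above <- as.integer(temp > clim)
  tibble(
    person_id = panel$person_id,
    wave = panel$wave,
    day_count_above = as.integer(rowsum(above, obs)[, 1])
  )
}
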