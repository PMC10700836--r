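#' Inverse-distance weighted interpolation of station values to a point
#'
#' Weights are proportional to `distance^(-power)`, normalized to sum to one,
#' using every station with a value (no k-nearest cutoff). If the target lies
#' within `snap` of a station the station's value is returned exactly.
#'
#' @param values Numeric station values for one date.
#' @param station_xy Two-column matrix or data frame of station coordinates (km).
#' @param point_xy Length-2 numeric, the target coordinates (km).
#' @param power Distance decay exponent (default 2).
#' @param snap Snap-to-station radius in km (default 0.001, i.e. one metre).
#'
#' @return The interpolated value (scalar). Errors if no station has a value.
#' @export
#' @examples
#' idw_to_county(c(10, 20), rbind(c(0, 0), c(2, 0)), c(1, 0))  # 15
idw_to_county <- function(values, station_xy, point_xy, power = 2, snap = 0.001) {
  station_xy <- as.matrix(station_xy)
  ok <- !is.na(values)
  if (!any(ok)) abort("No stations report a value for this date.")
  values <- values[ok]
  station_xy <- station_xy[ok, , drop = FALSE]
  d <- sqrt((station_xy[, 1] - point_xy[1])^2 + (station_xy[, 2] - point_xy[2])^2)
  if (any(d < snap)) {
    return(values[which.min(d)])
  }
  w <- d^(-power)
  sum(w * values) / sum(w)
}

#' Interpolate daily station weather to the county level
#'
#' Applies inverse-distance weighting with time-constant weights (station and
#' county locations are fixed) to every weather variable, producing one daily
#' series per county.
#'
#' @param weather Daily station table from [simulate_station_weather()].
#' @param stations,counties Catalog tibbles from [generate_geography()].
#' @param variables Weather columns to interpolate.
#' @param power,snap See [idw_to_county()].
#'
#' @return Tibble `county_id`, `date`, one column per variable.
#' @export
interpolate_counties <- function(weather, stations, counties,
                                 variables = c("temp", "wind", "humidity",
                                               "precip", "sun_hours"),
                                 power = 2, snap = 0.001) {
  variables <- intersect(variables, names(weather))
  dx <- outer(counties$x, stations$x, "-")
  dy <- outer(counties$y, stations$y, "-")
  d <- sqrt(dx^2 + dy^2)
  w <- d^(-power)
  snap_hit <- d < snap
  if (any(snap_hit)) {
    w[rowSums(snap_hit) > 0, ] <- 0
    w[snap_hit] <- 1
  }
  w <- w / rowSums(w)

  dates <- sort(unique(weather$date))
  wx <- dplyr::arrange(weather, .data$station_id, .data$date)
  if (nrow(wx) != nrow(stations) * length(dates)) {
    abort("`weather` must contain every station-date combination.")
  }
  out <- tidyr::crossing(county_id = sort(counties$county_id), date = dates)
  ord <- match(counties$county_id, sort(counties$county_id))
  for (v in variables) {
    m <- matrix(wx[[v]], nrow = length(dates))  # dates x stations
    cv <- m %*% t(w)                            # dates x counties
    val <- matrix(NA_real_, nrow = length(dates), ncol = ncol(cv))
    val[, ord] <- cv
    out[[v]] <- as.vector(val)
  }
  out
}

# ---- window machinery ----------------------------------------------------

# Validate a single-county daily series and build an O(1) window-mean index.
# Requires contiguous dates: gaps are an error, never silently filled.
.series_index <- function(series, variable = "temp") {
  if (!all(c("date", variable) %in% names(series))) {
    abort(paste0("Series must have columns `date` and `", variable, "`."))
  }
  series <- dplyr::arrange(series, .data$date)
  if (anyDuplicated(series$date)) abort("Series has duplicate dates.")
  gaps <- diff(as.integer(series$date))
  if (length(gaps) && any(gaps != 1L)) {
    first_gap <- series$date[which(gaps != 1L)[1]]
    abort(paste0("Series has a gap after ", format(first_gap),
                 "; gaps must be resolved explicitly, not imputed."))
  }
  list(
    first = series$date[1],
    last = series$date[nrow(series)],
    cs = c(0, cumsum(series[[variable]])),
    values = series[[variable]]
  )
}

# Mean over [start, end] via the cumulative-sum index; vectorized.
.win_mean <- function(idx, start, end, context = "window") {
  if (any(start < idx$first) || any(end > idx$last)) {
    bad <- which(start < idx$first | end > idx$last)[1]
    abort(paste0(
      "Exposure window ", format(start[bad]), " to ", format(end[bad]),
      " is not covered by the series (coverage ", format(idx$first), " to ",
      format(idx$last), ") [", context, "]."
    ))
  }
  i1 <- as.integer(start - idx$first) + 1L
  i2 <- as.integer(end - idx$first) + 1L
  (idx$cs[i2 + 1L] - idx$cs[i1]) / (i2 - i1 + 1L)
}

# Transpose a month-day to a target year; Feb 29 falls back to Feb 28.
.transpose_md <- function(month, day, year) {
  d <- as.Date(sprintf("%04d-%02d-%02d", year, month, day))
  bad <- is.na(d)
  if (any(bad)) {
    d[bad] <- as.Date(sprintf("%04d-02-28", year[bad]))
  }
  d
}

# Start/end dates of the calendar window ending at `end_md` transposed to
# `years`. The window is the `window_days` calendar days ending on and
# including the end date; month-day boundaries (not day-of-year) are
# transposed, so transposed windows containing Feb 29 gain or drop that day.
.transposed_window <- function(end_date, window_days, years) {
  start_date <- end_date - (window_days - 1)
  em <- as.integer(format(end_date, "%m"))
  ed <- as.integer(format(end_date, "%d"))
  sm <- as.integer(format(start_date, "%m"))
  sdy <- as.integer(format(start_date, "%d"))
  k <- as.integer(format(end_date, "%Y")) - as.integer(format(start_date, "%Y"))
  list(
    start = .transpose_md(sm, sdy, years - k),
    end = .transpose_md(em, ed, years)
  )
}

#' Mean of a weather variable over an exposure window
#'
#' Arithmetic mean over the closed window of `window_days` calendar days
#' ending on (and including) `end_date`. The window must be fully covered by
#' the series; gaps raise an error rather than being imputed.
#'
#' @param series County daily series: tibble with `date` and the variable.
#' @param end_date Last day of the window (the interview date).
#' @param window_days Window length in days (default 30).
#' @param variable Column to average (default `"temp"`).
#'
#' @return The window mean (scalar).
#' @export
#' @examples
#' s <- tibble::tibble(date = as.Date("2014-01-01") + 0:29, temp = 1:30)
#' window_stats(s, as.Date("2014-01-30"))  # 15.5
window_stats <- function(series, end_date, window_days = 30, variable = "temp") {
  stopifnot(window_days >= 1)
  end_date <- as.Date(end_date)
  idx <- .series_index(series, variable)
  .win_mean(idx, end_date - (window_days - 1), end_date,
            context = paste0("ending ", format(end_date)))
}

#' Temperature bin specification
#'
#' Half-open 3 degC bins anchored at 0 degC by default, with all days below
#' `lower_consolidation` pooled into one sub-freezing bin and all days at or
#' above `upper_consolidation` pooled into one hot bin. The omitted (comfort)
#' bin, 18-21 degC by default, is retained in day counts but excluded from the
#' regression design.
#'
#' @param bin_width Bin width, degC (> 0).
#' @param lower_consolidation Pool days below this temperature, degC.
#' @param upper_consolidation Pool days at or above this temperature, degC.
#' @param omitted_bin Length-2 vector, the omitted interval (grid-aligned).
#'
#' @return A list of class `bin_spec` with a `labels` element naming every bin
#'   in temperature order.
#' @export
bin_spec <- function(bin_width = 3, lower_consolidation = 0,
                     upper_consolidation = 30, omitted_bin = c(18, 21)) {
  if (bin_width <= 0) abort("`bin_width` must be > 0.")
  if ((omitted_bin[1] - lower_consolidation) %% bin_width != 0 ||
      diff(omitted_bin) != bin_width) {
    abort("`omitted_bin` must be one cell of the bin grid.")
  }
  breaks <- seq(lower_consolidation, upper_consolidation, by = bin_width)
  labels <- c(
    sprintf("(-Inf,%g)", lower_consolidation),
    sprintf("[%g,%g)", breaks[-length(breaks)], breaks[-1]),
    sprintf("[%g,Inf)", upper_consolidation)
  )
  structure(
    list(
      bin_width = bin_width,
      lower_consolidation = lower_consolidation,
      upper_consolidation = upper_consolidation,
      omitted_bin = omitted_bin,
      labels = labels,
      omitted_label = sprintf("[%g,%g)", omitted_bin[1], omitted_bin[2])
    ),
    class = "bin_spec"
  )
}

# Assign temperatures to bin labels; vectorized.
.bin_assign <- function(temp, spec) {
  breaks <- c(-Inf, seq(spec$lower_consolidation, spec$upper_consolidation,
                        by = spec$bin_width), Inf)
  spec$labels[findInterval(temp, breaks, left.open = FALSE)]
}

#' Count exposure-window days per temperature bin
#'
#' Assigns each day of the exposure window to exactly one half-open bin;
#' counts always sum to the number of days in the window.
#'
#' @inheritParams window_stats
#' @param spec A [bin_spec()].
#'
#' @return A named integer vector with one entry per bin label.
#' @export
bin_day_counts <- function(series, end_date, window_days = 30, spec = bin_spec()) {
  stopifnot(inherits(spec, "bin_spec"))
  end_date <- as.Date(end_date)
  idx <- .series_index(series, "temp")
  start <- end_date - (window_days - 1)
  .win_mean(idx, start, end_date, context = paste0("ending ", format(end_date)))
  days <- idx$values[seq(as.integer(start - idx$first) + 1L,
                         as.integer(end_date - idx$first) + 1L)]
  lab <- .bin_assign(days, spec)
  counts <- table(factor(lab, levels = spec$labels))
  out <- as.integer(counts)
  names(out) <- spec$labels
  out
}

#' Per-year means of the same calendar window across history
#'
#' For each year in `from_year:to_year`, transposes the month-day boundaries
#' of the window ending at `end_date` to that year and returns the mean of the
#' variable over the transposed window. Feb 29 inside a transposed window is
#' dropped in non-leap years (the date does not exist), so window lengths can
#' differ by one day across years.
#'
#' @inheritParams window_stats
#' @param from_year,to_year Inclusive historical year range.
#'
#' @return Tibble with columns `year`, `start`, `end`, `n_days`, `mean`.
#' @export
#' @examples
#' s <- tibble::tibble(date = seq(as.Date("1989-01-01"), as.Date("2014-12-31"), 1),
#'                     temp = 10)
#' calendar_window_history(s, as.Date("2014-08-25"), 30, 1989, 2013)
calendar_window_history <- function(series, end_date, window_days = 30,
                                    from_year, to_year, variable = "temp") {
  if (from_year > to_year) abort("`from_year` must be <= `to_year`.")
  end_date <- as.Date(end_date)
  idx <- .series_index(series, variable)
  years <- seq(from_year, to_year)
  win <- .transposed_window(end_date, window_days, years)
  covered <- win$start >= idx$first & win$end <= idx$last
  if (!all(covered)) {
    abort(paste0("Historical coverage missing for year ", years[!covered][1],
                 " (series covers ", format(idx$first), " to ",
                 format(idx$last), ")."))
  }
  tibble(
    year = as.integer(years),
    start = win$start,
    end = win$end,
    n_days = as.integer(win$end - win$start) + 1L,
    mean = .win_mean(idx, win$start, win$end, context = "historical window")
  )
}

# ---- vectorized multi-county window lookup (internal) --------------------

# Build a per-county cumulative-sum index over a county_daily table.
# Returns county-keyed offsets into flat vectors so that window means for
# hundreds of thousands of (county, window) pairs are O(1) arithmetic.
.county_index <- function(county_daily, variable = "temp") {
  cd <- dplyr::arrange(county_daily, .data$county_id, .data$date)
  rle_c <- rle(cd$county_id)
  starts <- cumsum(c(1L, rle_c$lengths[-length(rle_c$lengths)]))
  ends <- cumsum(rle_c$lengths)
  first <- cd$date[starts]
  last <- cd$date[ends]
  # contiguity per county
  dd <- diff(as.integer(cd$date))
  breaks <- ends[-length(ends)]
  dd[breaks] <- 1L
  if (length(dd) && any(dd != 1L)) {
    abort("`county_daily` has date gaps; resolve them explicitly.")
  }
  v <- cd[[variable]]
  cs <- cumsum(v)
  list(
    county = rle_c$values,
    row0 = starts - 1L,   # rows before this county's block
    first = first, last = last,
    cs = c(0, cs), values = v
  )
}

# Vectorized window means: for each element of (county, start, end).
.county_win_mean <- function(cidx, county, start, end) {
  j <- match(county, cidx$county)
  if (anyNA(j)) {
    abort(paste0("County ", county[is.na(j)][1], " is absent from the daily series."))
  }
  ok <- start >= cidx$first[j] & end <= cidx$last[j]
  if (!all(ok)) {
    b <- which(!ok)[1]
    abort(paste0(
      "Window ", format(start[b]), " to ", format(end[b]), " for county ",
      county[b], " is outside the series coverage (",
      format(cidx$first[j[b]]), " to ", format(cidx$last[j[b]]),
      "). Respondents born before the weather record starts need a truncated ",
      "or restricted sample."
    ))
  }
  i1 <- cidx$row0[j] + as.integer(start - cidx$first[j]) + 1L
  i2 <- cidx$row0[j] + as.integer(end - cidx$first[j]) + 1L
  (cidx$cs[i2 + 1L] - cidx$cs[i1]) / (i2 - i1 + 1L)
}
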