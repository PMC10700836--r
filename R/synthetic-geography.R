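#' Generate a synthetic station and county geography
#'
#' Draws weather stations and survey counties on a planar map (coordinates in
#' kilometres) and partitions them into climatic regions by proximity to
#' randomly placed region centres. Planar coordinates avoid geodesic
#' distance computations without changing the interpolation contract.
#' The first `n_regions` stations are pinned to the region centres so that
#' every region contains at least one station.
#'
#' @param n_stations Number of weather stations (>= 1).
#' @param n_counties Number of survey counties (>= 1).
#' @param n_regions Number of climatic regions (>= 1).
#' @param seed Integer seed; identical seeds yield identical catalogs.
#' @param extent Side length of the square map, km.
#'
#' @return A list with two tibbles:
#'   * `stations`: `station_id`, `x`, `y`, `region_id`
#'   * `counties`: `county_id`, `x`, `y`, `region_id`
#' @export
#' @examples
#' geo <- generate_geography(n_stations = 5, n_counties = 10, n_regions = 2, seed = 7)
#' geo$counties
generate_geography <- function(n_stations, n_counties, n_regions = 1,
                               seed = NULL, extent = 1000) {
  stopifnot(length(n_stations) == 1, length(n_counties) == 1, length(n_regions) == 1)
  if (n_stations < 1 || n_counties < 1 || n_regions < 1) {
    abort("`n_stations`, `n_counties` and `n_regions` must all be >= 1.")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  centres <- tibble(
    region_id = seq_len(n_regions),
    cx = runif(n_regions, 0.15 * extent, 0.85 * extent),
    cy = runif(n_regions, 0.15 * extent, 0.85 * extent)
  )
  nearest_region <- function(x, y) {
    d2 <- outer(x, centres$cx, "-")^2 + outer(y, centres$cy, "-")^2
    centres$region_id[max.col(-d2, ties.method = "first")]
  }

  sx <- runif(n_stations, 0, extent)
  sy <- runif(n_stations, 0, extent)
  pin <- seq_len(min(n_regions, n_stations))
  sx[pin] <- centres$cx[pin]
  sy[pin] <- centres$cy[pin]
  stations <- tibble(
    station_id = sprintf("S%03d", seq_len(n_stations)),
    x = sx, y = sy,
    region_id = nearest_region(sx, sy)
  )

  cx <- runif(n_counties, 0, extent)
  cy <- runif(n_counties, 0, extent)
  counties <- tibble(
    county_id = sprintf("C%03d", seq_len(n_counties)),
    x = cx, y = cy,
    region_id = nearest_region(cx, cy)
  )

  list(stations = stations, counties = counties)
}
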