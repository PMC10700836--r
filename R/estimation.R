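#' Within transformation: absorb fixed effects by iterated demeaning
#'
#' Removes group means (weighted, if weights are supplied) along each fixed-
#' effect dimension by alternating sweeps until the largest absolute group
#' mean falls below `tol`. This is the standard alternating-projections
#' within estimator; it reproduces dummy-variable least squares exactly at
#' convergence and scales to panels where explicit dummies would not.
#' Observations whose group is a singleton in either dimension contribute
#' nothing after demeaning; they are dropped (iteratively, since dropping can
#' create new singletons) and counted.
#'
#' @param data Data frame containing `cols`, the FE columns and weights.
#' @param cols Character vector of numeric columns to demean.
#' @param fe Character vector (length 1 or 2) of fixed-effect columns.
#' @param weights Optional name of a positive weight column.
#' @param tol Convergence tolerance on the largest absolute group mean.
#' @param max_iter Maximum number of alternating sweeps.
#'
#' @return A tibble of the demeaned `cols` for the retained rows, with
#'   attributes `rows` (retained row indices of `data`), `n_dropped`,
#'   `iterations`, `delta` and `fe_levels` (named level counts).
#' @export
within_transform <- function(data, cols, fe, weights = NULL,
                             tol = 1e-10, max_iter = 1000) {
  stopifnot(length(fe) %in% 1:2, all(cols %in% names(data)),
            all(fe %in% names(data)))
  w_all <- if (is.null(weights)) rep(1, nrow(data)) else data[[weights]]
  if (any(w_all <= 0)) abort("Weights must be strictly positive.")

  keep <- seq_len(nrow(data))
  repeat {
    dropped <- FALSE
    for (f in fe) {
      g <- data[[f]][keep]
      sizes <- table(g)
      single <- names(sizes)[sizes == 1L]
      if (length(single) > 0) {
        keep <- keep[!g %in% single]
        dropped <- TRUE
      }
    }
    if (!dropped) break
  }
  n_dropped <- nrow(data) - length(keep)
  if (length(keep) == 0) abort("All rows are fixed-effect singletons.")

  M <- as.matrix(data[keep, cols, drop = FALSE])
  storage.mode(M) <- "double"
  w <- w_all[keep]
  gs <- lapply(fe, function(f) {
    g <- data[[f]][keep]
    match(g, unique(g))
  })
  wsums <- lapply(gs, function(g) rowsum(w, g))

  it <- 0L
  delta <- Inf
  while (it < max_iter) {
    it <- it + 1L
    delta <- 0
    for (k in seq_along(gs)) {
      gm <- rowsum(M * w, gs[[k]]) / as.vector(wsums[[k]])
      delta <- max(delta, max(abs(gm)))
      M <- M - gm[gs[[k]], , drop = FALSE]
    }
    if (delta < tol) break
  }
  if (delta >= tol) {
    abort(paste0("Within transformation did not converge in ", max_iter,
                 " sweeps (last delta ", format(delta, digits = 3), ")."))
  }

  out <- as_tibble(as.data.frame(M))
  attr(out, "rows") <- keep
  attr(out, "n_dropped") <- n_dropped
  attr(out, "iterations") <- it
  attr(out, "delta") <- delta
  attr(out, "fe_levels") <- vapply(gs, max, integer(1)) |> rlang::set_names(fe)
  out
}

#' Weighted least squares on a prepared design
#'
#' Solves the weighted normal equations by QR on the weight-scaled design.
#' Rank deficiency is an error naming the collinear columns (for example an
#' age control absorbed by person and date fixed effects).
#'
#' @param y Numeric response.
#' @param X Numeric design matrix with column names.
#' @param weights Optional positive weights.
#'
#' @return List with `coefficients`, `residuals`, `fitted`, `xtwx_inv`.
#' @export
fit_wls <- function(y, X, weights = NULL) {
  X <- as.matrix(X)
  if (is.null(weights)) weights <- rep(1, length(y))
  if (any(weights <= 0)) abort("Weights must be strictly positive.")
  sw <- sqrt(weights)
  qr_x <- qr(X * sw)
  p <- ncol(X)
  if (qr_x$rank < p) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):p]]
    abort(paste0("Design is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", "), "."))
  }
  beta <- qr.coef(qr_x, y * sw)
  fitted <- drop(X %*% beta)
  list(
    coefficients = rlang::set_names(as.numeric(beta), colnames(X)),
    residuals = y - fitted,
    fitted = fitted,
    xtwx_inv = chol2inv(chol(crossprod(X * sw)))
  )
}

# One-way cluster-robust (sandwich) covariance with the CGM finite-cluster
# correction G/(G-1) * (N-1)/(N-K).
.cluster_cov_oneway <- function(X, scores_base, bread, cluster, df_k) {
  g <- match(cluster, unique(cluster))
  G <- max(g)
  S <- rowsum(scores_base, g)
  n <- nrow(X)
  adj <- G / (G - 1) * (n - 1) / (n - df_k)
  list(V = adj * bread %*% crossprod(S) %*% bread, G = G)
}

#' Two-way cluster-robust covariance
#'
#' Cameron-Gelbach-Miller combination `V = V_a + V_b - V_ab`, where each term
#' is a one-way cluster-robust sandwich with finite-cluster correction
#' `G/(G-1) * (N-1)/(N-K)` and `ab` is the intersection clustering. If the
#' combined matrix is not positive semi-definite its negative eigenvalues are
#' floored at zero (recorded in the `"psd_repaired"` attribute).
#'
#' @param X Design matrix used in the fit.
#' @param residuals Fit residuals (response scale).
#' @param weights Optional fit weights.
#' @param cluster_a,cluster_b Cluster labels, one per row.
#' @param df_k Degrees of freedom charged to the model in the correction;
#'   defaults to `ncol(X)`. Pass the absorbed fixed-effect count as well when
#'   the design was demeaned.
#'
#' @return Covariance matrix with attributes `"n_clusters"` (named: a, b,
#'   intersection) and `"psd_repaired"`.
#' @export
twoway_cluster_cov <- function(X, residuals, weights = NULL,
                               cluster_a, cluster_b, df_k = ncol(X)) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(cluster_a) == n, length(cluster_b) == n)
  if (length(unique(cluster_a)) < 2 || length(unique(cluster_b)) < 2) {
    abort("A cluster dimension has a single cluster; use one-way clustering instead.")
  }
  if (is.null(weights)) weights <- rep(1, n)
  bread <- chol2inv(chol(crossprod(X * sqrt(weights))))
  scores <- X * (weights * residuals)

  va <- .cluster_cov_oneway(X, scores, bread, cluster_a, df_k)
  vb <- .cluster_cov_oneway(X, scores, bread, cluster_b, df_k)
  vab <- .cluster_cov_oneway(X, scores, bread,
                             paste(cluster_a, cluster_b, sep = "\r"), df_k)
  V <- va$V + vb$V - vab$V
  V <- (V + t(V)) / 2

  repaired <- FALSE
  ev <- eigen(V, symmetric = TRUE)
  if (any(ev$values < 0)) {
    repaired <- TRUE
    V <- ev$vectors %*% diag(pmax(ev$values, 0), nrow = length(ev$values)) %*%
      t(ev$vectors)
    V <- (V + t(V)) / 2
  }
  dimnames(V) <- list(colnames(X), colnames(X))
  attr(V, "n_clusters") <- c(a = va$G, b = vb$G, intersection = vab$G)
  attr(V, "psd_repaired") <- repaired
  V
}

#' Model specification for the well-being panel regression
#'
#' Describes one estimating equation: the temperature term, the control sets,
#' the fixed effects, the survey-weight column and the clustering dimensions.
#'
#' @param term Temperature term: `"anomaly"` (degC anomaly), `"split"`
#'   (hotter- and colder-than-expected parts in one regression),
#'   `"day_count"` (days above the historical average), or `"bins"`
#'   (day counts per 3 degC bin, relative to the omitted comfort bin).
#' @param outcome Outcome column name.
#' @param controls Individual control columns.
#' @param weather_controls Exposure-mean weather control columns (entered with
#'   polynomials up to `weather_order`).
#' @param weather_order Polynomial order for weather controls.
#' @param fe Fixed-effect columns (individual and exact interview date).
#' @param weights Survey-weight column, or `NULL`.
#' @param cluster Two clustering columns (county and interview date).
#' @param bins A [bin_spec()] when `term = "bins"`.
#' @param fe_tol,fe_max_iter Within-transformation controls.
#'
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(term = c("anomaly", "split", "day_count", "bins"),
                       outcome = "swb",
                       controls = c("income", "age", "married", "education",
                                    "employed", "discomfort"),
                       weather_controls = c("wind_mean", "humidity_mean",
                                            "precip_mean", "sun_hours_mean"),
                       weather_order = 2,
                       fe = c("person_id", "interview_date"),
                       weights = "weight",
                       cluster = c("county_id", "interview_date"),
                       bins = bin_spec(),
                       fe_tol = 1e-10, fe_max_iter = 1000) {
  term <- match.arg(term)
  if (length(cluster) != 2) abort("`cluster` must name exactly two dimensions.")
  structure(
    list(term = term, outcome = outcome, controls = controls,
         weather_controls = weather_controls, weather_order = weather_order,
         fe = fe, weights = weights, cluster = cluster, bins = bins,
         fe_tol = fe_tol, fe_max_iter = fe_max_iter),
    class = "model_spec"
  )
}

# Temperature-term column names for a spec (bins exclude the omitted bin).
.term_columns <- function(spec) {
  switch(spec$term,
    anomaly = "anomaly",
    split = c("positive_part", "negative_part"),
    day_count = "day_count_above",
    bins = paste0("bin_", setdiff(spec$bins$labels, spec$bins$omitted_label))
  )
}

#' Fit the well-being panel model
#'
#' Orchestrates the estimation pipeline: joins the anomaly/exposure measures
#' onto the panel, absorbs individual and interview-date fixed effects by
#' [within_transform()], estimates by weighted least squares ([fit_wls()])
#' and computes the two-way cluster-robust covariance
#' ([twoway_cluster_cov()]). Controls whose within-transformed variation is
#' (numerically) nil — such as age, which is absorbed by person plus date
#' effects — are dropped with a message. Inference uses a t distribution with
#' `min(G_a, G_b) - 1` degrees of freedom.
#'
#' @param panel Panel tibble (outcome, controls, weights, FE and cluster
#'   columns).
#' @param anomalies Anomaly table from [build_anomalies()] (required for
#'   `"anomaly"` and `"split"` terms).
#' @param exposures Exposure table from [build_exposures()] (weather controls
#'   and bin counts).
#' @param day_counts Day-count table from [build_day_counts()] (required for
#'   the `"day_count"` term).
#' @param spec A [model_spec()].
#'
#' @return An object of class `swb_fit`; see [tidy.swb_fit()] and
#'   [glance.swb_fit()].
#' @export
fit_swb_model <- function(panel, anomalies = NULL, exposures = NULL,
                          day_counts = NULL, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  df <- panel
  join_keys <- c("person_id", "wave")
  if (!is.null(anomalies)) {
    df <- dplyr::left_join(
      df, dplyr::select(anomalies, -dplyr::any_of(c("county_id", "interview_date"))),
      by = join_keys
    )
  }
  if (!is.null(exposures)) df <- dplyr::left_join(df, exposures, by = join_keys)
  if (!is.null(day_counts)) df <- dplyr::left_join(df, day_counts, by = join_keys)

  term_cols <- .term_columns(spec)
  missing_cols <- setdiff(term_cols, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing temperature-term column(s): ",
                 paste(missing_cols, collapse = ", "),
                 ". Supply the matching anomalies/exposures table."))
  }

  weather <- intersect(spec$weather_controls, names(df))
  if (spec$weather_order >= 2) {
    for (v in weather) {
      for (o in 2:spec$weather_order) {
        df[[paste0(v, "_p", o)]] <- df[[v]]^o
      }
    }
    weather <- c(weather, as.vector(outer(weather, 2:spec$weather_order,
                                          function(v, o) paste0(v, "_p", o))))
  }
  controls <- intersect(spec$controls, names(df))
  x_cols <- c(term_cols, controls, weather)
  use_cols <- c(spec$outcome, x_cols)
  if (anyNA(df[, use_cols])) {
    abort("Model columns contain missing values after joining; check coverage.")
  }

  dm <- within_transform(df, use_cols, spec$fe, weights = spec$weights,
                         tol = spec$fe_tol, max_iter = spec$fe_max_iter)
  rows <- attr(dm, "rows")
  w <- if (is.null(spec$weights)) rep(1, length(rows)) else df[[spec$weights]][rows]

  # Drop controls with no within variation (absorbed by the fixed effects).
  sds <- vapply(dm[x_cols], function(z) sqrt(mean(z^2)), numeric(1))
  degenerate <- names(sds)[sds < 1e-8 * max(sds, 1)]
  dropped <- intersect(degenerate, c(controls, weather))
  if (length(dropped) > 0) {
    inform(paste0("Dropping control(s) absorbed by the fixed effects: ",
                  paste(dropped, collapse = ", "), "."))
    x_cols <- setdiff(x_cols, dropped)
  }
  bad_term <- intersect(term_cols, degenerate)
  if (length(bad_term) > 0) {
    if (spec$term == "bins" && length(bad_term) < length(term_cols)) {
      # bins with no occupied days carry no information; drop them
      inform(paste0("Dropping empty temperature bin(s): ",
                    paste(sub("^bin_", "", bad_term), collapse = ", "), "."))
      term_cols <- setdiff(term_cols, bad_term)
      x_cols <- setdiff(x_cols, bad_term)
    } else {
      abort("The temperature term has no within variation under these fixed effects.")
    }
  }

  X <- as.matrix(dm[, x_cols, drop = FALSE])
  y <- dm[[spec$outcome]]

  # Rank check: collinear controls (common in small samples where window
  # weather means barely vary across counties) are dropped with a message;
  # a collinear temperature term is a hard error.
  qr_x <- qr(X * sqrt(w))
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    bad_term2 <- intersect(bad, term_cols)
    if (length(bad_term2) > 0) {
      abort(paste0("Temperature term column(s) collinear with the design: ",
                   paste(bad_term2, collapse = ", "), "."))
    }
    inform(paste0("Dropping collinear control(s): ",
                  paste(bad, collapse = ", "), "."))
    x_cols <- setdiff(x_cols, bad)
    dropped <- c(dropped, bad)
    X <- X[, x_cols, drop = FALSE]
  }
  fit <- fit_wls(y, X, w)

  # Finite-cluster correction charges the explicit regressors only: both
  # fixed-effect dimensions are nested within their cluster dimensions
  # (persons within counties, dates within dates), the standard convention.
  fe_levels <- attr(dm, "fe_levels")
  df_k <- ncol(X)
  V <- twoway_cluster_cov(X, fit$residuals, w,
                          cluster_a = df[[spec$cluster[1]]][rows],
                          cluster_b = df[[spec$cluster[2]]][rows],
                          df_k = df_k)
  nc <- attr(V, "n_clusters")

  structure(
    list(
      coefficients = fit$coefficients,
      se = sqrt(pmax(diag(V), 0)),
      vcov = V,
      residuals = fit$residuals,
      n_obs = length(rows),
      n_dropped_singletons = attr(dm, "n_dropped"),
      n_clusters = rlang::set_names(nc[1:2], spec$cluster),
      n_cluster_intersection = unname(nc[3]),
      df = unname(min(nc[1:2]) - 1),
      fe = list(levels = fe_levels, iterations = attr(dm, "iterations"),
                delta = attr(dm, "delta")),
      term = spec$term,
      term_cols = term_cols,
      dropped_controls = dropped,
      psd_repaired = attr(V, "psd_repaired"),
      spec = spec
    ),
    class = "swb_fit"
  )
}

#' @export
print.swb_fit <- function(x, ...) {
  cat("Well-being panel fit (", x$term, " term)\n", sep = "")
  cat("  obs: ", x$n_obs, "; clusters: ",
      paste(names(x$n_clusters), x$n_clusters, sep = "=", collapse = ", "),
      "\n\n", sep = "")
  print(render_fit_table(x), row.names = FALSE)
  invisible(x)
}

#' @rdname fit_swb_model
#' @param x An `swb_fit`.
#' @param conf.level Confidence level for intervals.
#' @param ... Unused.
#' @method tidy swb_fit
#' @export
tidy.swb_fit <- function(x, conf.level = 0.95, ...) {
  est <- x$coefficients
  se <- x$se
  stat <- est / se
  p <- 2 * pt(abs(stat), df = x$df, lower.tail = FALSE)
  crit <- qt(1 - (1 - conf.level) / 2, df = x$df)
  tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = unname(p),
    conf.low = unname(est - crit * se),
    conf.high = unname(est + crit * se)
  )
}

#' @rdname fit_swb_model
#' @method glance swb_fit
#' @export
glance.swb_fit <- function(x, ...) {
  tibble(
    nobs = x$n_obs,
    n_singletons_dropped = x$n_dropped_singletons,
    n_clusters_a = unname(x$n_clusters[1]),
    n_clusters_b = unname(x$n_clusters[2]),
    df = x$df,
    fe_iterations = x$fe$iterations,
    fe_delta = x$fe$delta,
    psd_repaired = x$psd_repaired
  )
}

#' Fit the model separately within groups
#'
#' Repeats one specification across sample strata: survey waves, county
#' climate quartiles (counties ranked by their mean temperature over the 50
#' years preceding the last interview year), or any label column already in
#' the panel. Groups in which the fit fails (too little within variation for
#' the fixed effects) are skipped with a warning.
#'
#' @inheritParams fit_swb_model
#' @param grouping `"wave"`, `"climate_quartile"`, or the name of a column of
#'   `panel`.
#' @param county_daily County daily series (required for
#'   `"climate_quartile"`).
#'
#' @return Tibble with one row per group: `group`, `n_obs`, `fit`
#'   (list-column of `swb_fit`). For climate quartiles the county-to-quartile
#'   map is attached as attribute `"group_table"`.
#' @export
stratified_fit <- function(panel, anomalies = NULL, exposures = NULL,
                           day_counts = NULL, spec = model_spec(),
                           grouping = "wave", county_daily = NULL) {
  group_table <- NULL
  if (identical(grouping, "climate_quartile")) {
    if (is.null(county_daily)) {
      abort("`county_daily` is required for climate-quartile grouping.")
    }
    last_year <- max(as.integer(format(county_daily$date, "%Y")))
    clim <- county_daily |>
      dplyr::filter(as.integer(format(.data$date, "%Y")) > last_year - 50) |>
      dplyr::summarise(mean_temp = mean(.data$temp), .by = "county_id") |>
      dplyr::mutate(group = paste0("Q", dplyr::ntile(dplyr::desc(.data$mean_temp), 4)))
    group_table <- clim
    panel <- dplyr::left_join(panel, dplyr::select(clim, "county_id", "group"),
                              by = "county_id")
    gcol <- "group"
  } else if (identical(grouping, "wave")) {
    gcol <- "wave"
  } else {
    if (!grouping %in% names(panel)) {
      abort(paste0("Grouping column `", grouping, "` not found in `panel`."))
    }
    gcol <- grouping
  }

  groups <- sort(unique(panel[[gcol]]))
  res <- purrr::map(groups, function(g) {
    sub <- panel[panel[[gcol]] == g, , drop = FALSE]
    fit <- tryCatch(
      fit_swb_model(sub, anomalies = anomalies, exposures = exposures,
                    day_counts = day_counts, spec = spec),
      error = function(e) {
        warn(paste0("Skipping group ", g, ": ", conditionMessage(e)))
        NULL
      }
    )
    tibble(group = as.character(g),
           n_obs = if (is.null(fit)) NA_integer_ else fit$n_obs,
           fit = list(fit))
  })
  out <- dplyr::bind_rows(res)
  attr(out, "group_table") <- group_table
  out
}

#' Sweep the reference scheme and refit
#'
#' Re-estimates one specification across a grid of reference constructions —
#' preceding-years windows of varying length or cumulative-age caps — and
#' reports each coefficient together with the sample-average years-missed
#' rate. Per-year window means are computed once and reused across the grid.
#'
#' @inheritParams fit_swb_model
#' @param county_daily County daily series.
#' @param scheme `"preceding_years"` or `"cumulative_age"`.
#' @param grid Integer grid of `n` (preceding years) or `max_age` values.
#' @param window_days Exposure-window length in days.
#'
#' @return Tibble of class `swb_sweep`: `scheme`, `param`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`, `p.value`, `mean_years_missed`,
#'   `n_obs`.
#' @export
reference_sweep <- function(panel, county_daily, exposures = NULL,
                            spec = model_spec(),
                            scheme = c("preceding_years", "cumulative_age"),
                            grid = c(2, 5, 10, 20, 30, 40),
                            window_days = 30) {
  scheme <- match.arg(scheme)
  iy <- as.integer(format(panel$interview_date, "%Y"))
  from_all <- if (scheme == "preceding_years") {
    min(c(panel$birth_year, iy - max(grid)))
  } else {
    NULL  # birth year
  }
  history <- window_history(panel, county_daily, window_days = window_days,
                            from_year = from_all)

  age <- panel$age %||% (panel$wave - panel$birth_year)
  rows <- purrr::map(grid, function(gv) {
    ref <- if (scheme == "preceding_years") {
      reference_spec("preceding_years", n = gv, window_days = window_days)
    } else {
      reference_spec("cumulative_age", max_age = gv, window_days = window_days)
    }
    anoms <- build_anomalies(panel, county_daily, reference = ref,
                             history = history)
    fit <- fit_swb_model(panel, anomalies = anoms, exposures = exposures,
                         spec = spec)
    td <- tidy(fit)
    td <- td[td$term == "anomaly", ]
    n_used <- if (scheme == "preceding_years") rep(gv, length(age)) else pmin(age, gv)
    tibble(
      scheme = scheme, param = gv,
      estimate = td$estimate, std.error = td$std.error,
      conf.low = td$conf.low, conf.high = td$conf.high, p.value = td$p.value,
      mean_years_missed = mean(years_missed_rate(age, n_used)),
      n_obs = fit$n_obs
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("swb_sweep", class(out))
  out
}
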