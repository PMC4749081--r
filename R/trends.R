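# Monthly-anomaly construction and least-squares trend estimation.

#' Monthly mean predictions per cell
#'
#' Mean per (cell, year, month) computed only where at least `min_days`
#' daily predictions are available; other months are omitted.
#'
#' @param pred_daily tibble `cell_id`, `date`, `pred`.
#' @param min_days minimum daily predictions per month (default 6).
#' @return tibble `cell_id`, `year`, `month`, `mean`, `n_days`.
#' @export
monthly_means <- function(pred_daily, min_days = 6L) {
  m <- aggregate_daily(pred_daily, "monthly", min_days, value = "pred")
  m[m$included, c("cell_id", "year", "month", "mean", "n_days")]
}

#' Monthly anomalies relative to the per-cell monthly climatology
#'
#' The anomaly is the monthly mean minus the average of that calendar month
#' over all years in the record, per cell, so any pure seasonal cycle is
#' removed. For each cell and calendar month the anomalies sum to zero over
#' the years present. Calendar months observed in a single year have anomaly
#' 0 by construction and are flagged low-information.
#'
#' @param monthly output of [monthly_means()].
#' @return tibble `cell_id`, `year`, `month`, `time` (fractional years at
#'   mid-month), `anomaly`, `n_days`, `n_years_clim`.
#' @export
compute_anomalies <- function(monthly) {
  if (max(table(monthly$cell_id, monthly$month) > 0) < 1)
    stopf("no monthly means supplied")
  out <- monthly |>
    dplyr::group_by(.data$cell_id, .data$month) |>
    dplyr::mutate(anomaly = .data$mean - mean(.data$mean),
                  n_years_clim = dplyr::n()) |>
    dplyr::ungroup()
  if (max(out$n_years_clim) < 2L)
    stopf("at least one calendar month must be observed in >= 2 years")
  tibble(cell_id = out$cell_id, year = out$year, month = out$month,
         time = out$year + (out$month - 0.5) / 12,
         anomaly = out$anomaly, n_days = out$n_days,
         n_years_clim = out$n_years_clim)
}

#' Least-squares trend of an anomaly series
#'
#' Ordinary least squares of the anomaly on fractional time in years
#' (centered at the period midpoint; the slope is unchanged by centering).
#' Years contributing fewer than `min_months_per_year` anomaly months are
#' dropped entirely before fitting. The 95% confidence half-width and the
#' p-value use the classical slope standard error (independent homoscedastic
#' errors).
#'
#' @param series tibble with `time`, `anomaly` and optionally `year` (taken
#'   as `floor(time)` when absent).
#' @param period optional `c(start_year, end_year)` (inclusive) restricting
#'   the months used.
#' @param min_months_per_year minimum anomaly months per calendar year
#'   (default 6).
#' @return one-row tibble of class `trend_result`: `slope` (per year),
#'   `ci_halfwidth`, `p_value`, `n_months`, `period_start`, `period_end`;
#'   or a 0-row tibble with attribute `reason` when insufficient data
#'   remain.
#' @export
fit_trend <- function(series, period = NULL, min_months_per_year = 6L) {
  x <- series
  if (!"year" %in% names(x)) x$year <- floor(x$time)
  if (!is.null(period))
    x <- x[x$year >= period[1L] & x$year <= period[2L], ]
  keep_years <- names(which(table(x$year) >= min_months_per_year))
  x <- x[x$year %in% as.numeric(keep_years), ]
  empty <- function(reason) {
    structure(tibble(slope = numeric(), ci_halfwidth = numeric(),
                     p_value = numeric(), n_months = integer(),
                     period_start = numeric(), period_end = numeric()),
              reason = reason, class = c("trend_result", "tbl_df", "tbl",
                                         "data.frame"))
  }
  if (nrow(x) < 3L) return(empty("fewer than 3 qualifying months"))
  t <- x$time - mean(range(x$time))
  if (sd(t) == 0) return(empty("degenerate time axis"))
  fit <- lm(x$anomaly ~ t)
  s <- suppressWarnings(summary(fit))$coefficients
  slope <- s["t", "Estimate"]
  se <- s["t", "Std. Error"]
  df <- fit$df.residual
  structure(tibble(
    slope = slope,
    ci_halfwidth = qt(0.975, df) * se,
    p_value = if (se == 0) 0 else 2 * pt(-abs(slope / se), df),
    n_months = nrow(x),
    period_start = if (is.null(period)) min(x$year) else period[1L],
    period_end = if (is.null(period)) max(x$year) else period[2L]
  ), class = c("trend_result", "tbl_df", "tbl", "data.frame"))
}

#' Per-cell trends over one or more periods
#'
#' @param anomalies output of [compute_anomalies()].
#' @param periods list of `c(start_year, end_year)` pairs (or `NULL` entries
#'   for the full record).
#' @param min_months_per_year see [fit_trend()].
#' @return tibble with one row per cell and period (cells with insufficient
#'   data omitted).
#' @export
cell_trends <- function(anomalies, periods = list(NULL),
                        min_months_per_year = 6L) {
  out <- list()
  for (p in periods) {
    per_cell <- lapply(split(anomalies, anomalies$cell_id), function(a) {
      tr <- fit_trend(a, period = p, min_months_per_year)
      if (nrow(tr) == 0L) return(NULL)
      tibble(cell_id = a$cell_id[1L], tr)
    })
    out[[length(out) + 1L]] <- dplyr::bind_rows(per_cell)
  }
  dplyr::bind_rows(out)
}

#' Regional anomaly series and trends
#'
#' The regional monthly anomaly is the mean of the member cells' anomalies
#' (cells meeting the monthly inclusion rule); trends are then fitted on the
#' regional series for each requested period.
#'
#' @param pred_daily tibble `cell_id`, `date`, `pred`.
#' @param region_cells integer vector of member cell ids.
#' @param periods list of `c(start_year, end_year)` pairs or `NULL` for the
#'   full record.
#' @param min_days_per_month,min_months_per_year inclusion rules.
#' @return list with `series` (tibble `year`, `month`, `time`, `anomaly`,
#'   `n_cells`) and `trends` (tibble, one row per period).
#' @export
regional_trend <- function(pred_daily, region_cells, periods = list(NULL),
                           min_days_per_month = 6L,
                           min_months_per_year = 6L) {
  if (length(region_cells) == 0L) stopf("empty region")
  sub <- pred_daily[pred_daily$cell_id %in% region_cells, ]
  if (nrow(sub) == 0L) stopf("no predictions in the region")
  an <- compute_anomalies(monthly_means(sub, min_days_per_month))
  series <- an |>
    dplyr::group_by(.data$year, .data$month, .data$time) |>
    dplyr::summarise(anomaly = mean(.data$anomaly),
                     n_cells = dplyr::n(), .groups = "drop")
  trends <- dplyr::bind_rows(lapply(periods, function(p) {
    tr <- fit_trend(series, period = p, min_months_per_year)
    if (nrow(tr) == 0L) return(NULL)
    tr
  }))
  list(series = series, trends = trends)
}
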