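# Fit/CV statistics and historical-evaluation machinery.

#' Prediction performance statistics
#'
#' Computes, over aligned prediction/observation pairs: n, R-squared (the
#' squared Pearson correlation of predicted vs observed), mean prediction
#' error `MPE = mean(pred - obs)`, root mean squared prediction error RMSE,
#' relative prediction error `RPE = 100 * RMSE / mean(obs)` (percent), and
#' the least-squares slope and intercept of predicted (y) on observed (x).
#'
#' @param pred,obs numeric vectors of equal length (n >= 2).
#' @return one-row tibble `n`, `r2`, `mpe`, `rmse`, `rpe`, `slope`,
#'   `intercept`.
#' @export
compute_stats <- function(pred, obs) {
  if (length(pred) != length(obs)) stopf("`pred` and `obs` lengths differ")
  ok <- !is.na(pred) & !is.na(obs)
  pred <- pred[ok]; obs <- obs[ok]
  n <- length(pred)
  if (n < 2L) stopf("at least 2 aligned pairs are required")
  err <- pred - obs
  mpe <- mean(err)
  rmse <- sqrt(mean(err^2))
  rpe <- if (mean(obs) == 0) NA_real_ else 100 * rmse / mean(obs)
  if (sd(obs) > 0 && sd(pred) > 0) {
    r2 <- cor(pred, obs)^2
    slope <- cor(pred, obs) * sd(pred) / sd(obs)
    intercept <- mean(pred) - slope * mean(obs)
  } else {
    r2 <- NA_real_; slope <- NA_real_; intercept <- NA_real_
  }
  tibble(n = n, r2 = r2, mpe = mpe, rmse = rmse, rpe = rpe,
         slope = slope, intercept = intercept)
}

#' Monthly or seasonal aggregation with minimum-count rules
#'
#' Means per (cell, period) computed only for groups whose daily count meets
#' the rule; other groups are returned with `included = FALSE` and the
#' failing count. The defaults follow the convention that a monthly mean
#' requires more than five daily values (i.e. >= 6) and a seasonal mean more
#' than ten (>= 11). December is assigned to the following year's winter.
#'
#' @param daily tibble with `cell_id`, `date` and a value column.
#' @param level `"monthly"` or `"seasonal"`.
#' @param min_days minimum daily values per group (defaults: 6 monthly,
#'   11 seasonal).
#' @param value name of the value column (default `"value"`).
#' @return tibble `cell_id`, period keys (`year`+`month`, or
#'   `season_year`+`season`), `mean`, `n_days`, `included`.
#' @export
aggregate_daily <- function(daily, level = c("monthly", "seasonal"),
                            min_days = NULL, value = "value") {
  level <- match.arg(level)
  min_days <- min_days %||% if (level == "monthly") 6L else 11L
  stopifnot(value %in% names(daily))
  x <- daily
  x$.val <- x[[value]]
  if (level == "monthly") {
    x$year <- as.integer(format(x$date, "%Y"))
    x$month <- as.integer(format(x$date, "%m"))
    keys <- c("cell_id", "year", "month")
  } else {
    x$season_year <- season_year(x$date)
    x$season <- season_of(x$date)
    keys <- c("cell_id", "season_year", "season")
  }
  out <- x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(mean = mean(.data$.val), n_days = dplyr::n(),
                     .groups = "drop")
  out$included <- out$n_days >= min_days
  out$mean[!out$included] <- NA_real_
  out
}

# monthly observation means under the evaluation rule (>= min_obs per month)
obs_monthly_means <- function(obs, min_obs = 25L, value = "obs") {
  m <- aggregate_daily(obs, "monthly", min_days = min_obs, value = value)
  m[m$included, c("cell_id", "year", "month", "mean", "n_days")]
}

#' Evaluate historical predictions at daily, monthly and seasonal scales
#'
#' Daily pairs are matched on (cell, date). Monthly pairs require at least
#' `min_pred_month` predicted days (default 6, i.e. "more than five") and at
#' least `min_obs_month` ground measurements (default 25) in the month.
#' Seasonal pairs require at least `min_pred_season` predicted days (default
#' 11, "more than ten") and at least `min_obs_month` measurements in each
#' month of the season.
#'
#' @param pred_daily tibble `cell_id`, `date`, `pred`.
#' @param obs_daily tibble `cell_id`, `date`, `obs`.
#' @param min_pred_month,min_pred_season,min_obs_month threshold rules.
#' @return list with elements `daily`, `monthly`, `seasonal`, each a list
#'   of `stats` ([compute_stats()] row, or `NULL` when no pairs matched)
#'   and `pairs` (the matched table).
#' @export
evaluate_historical <- function(pred_daily, obs_daily, min_pred_month = 6L,
                                min_pred_season = 11L, min_obs_month = 25L) {
  out <- list()

  daily <- dplyr::inner_join(pred_daily[, c("cell_id", "date", "pred")],
                             obs_daily[, c("cell_id", "date", "obs")],
                             by = c("cell_id", "date"))
  out$daily <- list(
    stats = if (nrow(daily) >= 2L) compute_stats(daily$pred, daily$obs),
    pairs = daily)

  pm <- aggregate_daily(pred_daily, "monthly", min_pred_month, "pred")
  pm <- pm[pm$included, ]
  om <- obs_monthly_means(obs_daily, min_obs_month)
  monthly <- dplyr::inner_join(pm, om, by = c("cell_id", "year", "month"),
                               suffix = c("_pred", "_obs"))
  out$monthly <- list(
    stats = if (nrow(monthly) >= 2L)
      compute_stats(monthly$mean_pred, monthly$mean_obs),
    pairs = monthly)

  ps <- aggregate_daily(pred_daily, "seasonal", min_pred_season, "pred")
  ps <- ps[ps$included, ]
  # observed seasonal mean over daily values, requiring >= min obs in every
  # month of the season
  ok_months <- om[, c("cell_id", "year", "month")]
  od <- obs_daily
  od$year <- as.integer(format(od$date, "%Y"))
  od$month <- as.integer(format(od$date, "%m"))
  od <- dplyr::inner_join(od, ok_months, by = c("cell_id", "year", "month"))
  od$season <- season_of(od$date)
  od$season_year <- season_year(od$date)
  os <- od |>
    dplyr::group_by(.data$cell_id, .data$season_year, .data$season) |>
    dplyr::summarise(mean = mean(.data$obs),
                     n_months = length(unique(.data$month)),
                     .groups = "drop")
  os <- os[os$n_months == 3L, ]
  seasonal <- dplyr::inner_join(ps, os,
                                by = c("cell_id", "season_year", "season"),
                                suffix = c("_pred", "_obs"))
  out$seasonal <- list(
    stats = if (nrow(seasonal) >= 2L)
      compute_stats(seasonal$mean_pred, seasonal$mean_obs),
    pairs = seasonal)
  out
}

#' Cross-validation fold assignment
#'
#' Assigns each fitting row to exactly one of `k` test folds, either
#' independently per record or by whole site (cell), so that the union of
#' the test folds is the fitting table.
#'
#' @param fitting_table tibble with at least `cell_id`.
#' @param k number of folds (>= 2).
#' @param unit `"record"` or `"site"`.
#' @param seed integer seed.
#' @return integer vector of fold ids (length `nrow(fitting_table)`).
#' @export
make_cv_folds <- function(fitting_table, k = 10L, unit = c("record", "site"),
                          seed = 1L) {
  unit <- match.arg(unit)
  n <- nrow(fitting_table)
  if (k < 2L) stopf("`k` must be >= 2")
  with_seed(seed, {
    if (unit == "record") {
      sample(rep_len(seq_len(k), n))
    } else {
      cells <- unique(fitting_table$cell_id)
      cf <- sample(rep_len(seq_len(k), length(cells)))
      cf[match(fitting_table$cell_id, cells)]
    }
  })
}

#' K-fold cross-validation of the two-stage model
#'
#' Partitions the fitting table at the record or site (cell) level, refits
#' both stages on each training set (buffer thresholds re-evaluated per
#' fold), predicts the held-out rows, and computes pooled statistics over
#' all held-out predictions.
#'
#' @param fitting_table assembled fitting rows.
#' @param grid a `grid_spec`.
#' @param k number of folds (default 10).
#' @param unit `"record"` (default) or `"site"` (folds split whole cells).
#' @param seed integer seed for the partition.
#' @param min_records,min_days,stage2,k_xy,k_1d passed to [fit_two_stage()].
#' @return list with `stats` (pooled [compute_stats()]), `predictions`
#'   (held-out rows with `pred`, `fold`), and `folds` (fold id per row).
#' @export
crossvalidate <- function(fitting_table, grid, k = 10L,
                          unit = c("record", "site"), seed = 1L,
                          min_records = 3000L, min_days = 300L,
                          stage2 = TRUE, k_xy = NULL, k_1d = 10L) {
  unit <- match.arg(unit)
  fold <- make_cv_folds(fitting_table, k, unit, seed)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    train <- fitting_table[fold != f, ]
    test <- fitting_table[fold == f, ]
    if (nrow(train) == 0L) stopf("fold %d has an empty training set", f)
    if (nrow(test) == 0L) next
    ts_fit <- fit_two_stage(train, grid, min_records = min_records,
                            min_days = min_days, stage2 = stage2,
                            k_xy = k_xy, k_1d = k_1d)
    p <- predict_full(ts_fit, test)
    preds[[f]] <- tibble(test[, c("cell_id", "date", "pm25")],
                         pred = p$pred, fold = f)
  }
  predictions <- dplyr::bind_rows(preds)
  list(stats = compute_stats(predictions$pred, predictions$pm25),
       predictions = predictions, folds = fold)
}
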