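# Three-step custom AOD fusion: crosswalk gap-filling between the DT and DB
# retrieval streams, seasonal error-variance calibration against ground
# reference stations, and inverse variance weighted combination; plus the
# operational NDVI-based combiner for coverage comparison.

#' Fit the DT/DB crosswalk regressions
#'
#' Ordinary least squares between daily collocated (same cell, same day)
#' DT and DB retrievals, in both directions. Per-day fits fall back to the
#' pooled (all-days) fit when a day has fewer than `min_pairs` collocations
#' or a degenerate predictor.
#'
#' @param dt,db stream tibbles `cell_id`, `date`, `aod`.
#' @param min_pairs minimum collocated pairs for a day-specific fit
#'   (default 10).
#' @return object of class `crosswalk_fit`: list with `pooled` and `per_day`
#'   coefficient tables (columns `direction` in `dt_to_db` / `db_to_dt`,
#'   `slope`, `intercept`, `n_pairs`, and `pooled_fallback` for per-day rows).
#' @export
fit_crosswalk <- function(dt, db, min_pairs = 10L) {
  pairs <- dplyr::inner_join(dt, db, by = c("cell_id", "date"),
                             suffix = c("_dt", "_db"))
  if (nrow(pairs) < 2L)
    stopf("cannot calibrate crosswalk: %d collocated DT/DB pair(s)",
          nrow(pairs))
  ols <- function(x, y) {
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) return(c(slope = NA_real_, intercept = NA_real_))
    sl <- sum((x - mean(x)) * (y - mean(y))) / sxx
    c(slope = sl, intercept = mean(y) - sl * mean(x))
  }
  pooled <- dplyr::bind_rows(
    tibble(direction = "dt_to_db",
           !!!ols(pairs$aod_dt, pairs$aod_db), n_pairs = nrow(pairs)),
    tibble(direction = "db_to_dt",
           !!!ols(pairs$aod_db, pairs$aod_dt), n_pairs = nrow(pairs))
  )
  if (anyNA(pooled$slope))
    stopf("cannot calibrate crosswalk: degenerate pooled regression")

  day_fit <- function(x, y, n, pooled_row) {
    if (n >= min_pairs) {
      co <- ols(x, y)
      if (!is.na(co[["slope"]]))
        return(tibble(slope = co[["slope"]], intercept = co[["intercept"]],
                      pooled_fallback = FALSE))
    }
    tibble(slope = pooled_row$slope, intercept = pooled_row$intercept,
           pooled_fallback = TRUE)
  }
  per_day <- pairs |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      fwd = day_fit(.data$aod_dt, .data$aod_db, dplyr::n(), pooled[1L, ]),
      rev = day_fit(.data$aod_db, .data$aod_dt, dplyr::n(), pooled[2L, ]),
      .groups = "drop"
    )
  per_day <- dplyr::bind_rows(
    tibble(date = per_day$date, direction = "dt_to_db", per_day$fwd,
           n_pairs = per_day$n_pairs),
    tibble(date = per_day$date, direction = "db_to_dt", per_day$rev,
           n_pairs = per_day$n_pairs)
  )
  structure(list(pooled = pooled, per_day = per_day,
                 min_pairs = min_pairs),
            class = "crosswalk_fit")
}

#' Gap-fill each stream from the other via the crosswalk
#'
#' Cell-days with both streams keep their observed values. Cell-days with
#' exactly one stream gain the other through the (per-day, pooled-fallback)
#' crosswalk, flagged `imputed`. Cell-days with neither remain missing.
#' Filled values are clipped at 0.
#'
#' @param dt,db stream tibbles `cell_id`, `date`, `aod`.
#' @param crosswalks a [fit_crosswalk()] object.
#' @return list with tibbles `dt_filled` and `db_filled`
#'   (`cell_id`, `date`, `aod`, `imputed`).
#' @export
gap_fill <- function(dt, db, crosswalks) {
  stopifnot(inherits(crosswalks, "crosswalk_fit"))
  both <- dplyr::full_join(dt, db, by = c("cell_id", "date"),
                           suffix = c("_dt", "_db"))
  cw <- function(direction) {
    pd <- crosswalks$per_day[crosswalks$per_day$direction == direction,
                             c("date", "slope", "intercept")]
    po <- crosswalks$pooled[crosswalks$pooled$direction == direction, ]
    list(per_day = pd, slope0 = po$slope, intercept0 = po$intercept)
  }
  fill_one <- function(x, dates, direction) {
    f <- cw(direction)
    idx <- match(dates, f$per_day$date)
    sl <- ifelse(is.na(idx), f$slope0, f$per_day$slope[idx])
    ic <- ifelse(is.na(idx), f$intercept0, f$per_day$intercept[idx])
    pmax(0, sl * x + ic)
  }
  miss_db <- is.na(both$aod_db) & !is.na(both$aod_dt)
  miss_dt <- is.na(both$aod_dt) & !is.na(both$aod_db)
  both$aod_db[miss_db] <- fill_one(both$aod_dt[miss_db], both$date[miss_db],
                                   "dt_to_db")
  both$aod_dt[miss_dt] <- fill_one(both$aod_db[miss_dt], both$date[miss_dt],
                                   "db_to_dt")
  list(
    dt_filled = tibble(cell_id = both$cell_id, date = both$date,
                       aod = both$aod_dt, imputed = miss_dt),
    db_filled = tibble(cell_id = both$cell_id, date = both$date,
                       aod = both$aod_db, imputed = miss_db)
  )
}

#' Seasonal error variances of the gap-filled streams
#'
#' Sample variance, per season and stream, of the differences between the
#' gap-filled retrievals and the ground reference stations, matched on the
#' same cell and day. Seasons with fewer than 2 matches are flagged
#' undefined (the combination then falls back to equal weights). A variance
#' floor prevents degenerate infinite weights.
#'
#' @param dt_filled,db_filled gap-filled stream tibbles (see [gap_fill()]).
#' @param truth_stations tibble `cell_id`, `date`, `aod`.
#' @param var_floor minimum admissible variance in AOD^2 (default 1e-4).
#' @return object of class `seasonal_variances`: tibble `season`, `stream`
#'   (`"DT"`/`"DB"`), `variance`, `n_matches`, `undefined`.
#' @export
seasonal_error_variance <- function(dt_filled, db_filled, truth_stations,
                                    var_floor = 1e-4) {
  one <- function(stream_tbl, label) {
    m <- dplyr::inner_join(stream_tbl, truth_stations,
                           by = c("cell_id", "date"),
                           suffix = c("_ret", "_truth"))
    m$season <- season_of(m$date)
    full <- tibble(season = SEASONS)
    got <- m |>
      dplyr::group_by(.data$season) |>
      dplyr::summarise(
        variance = if (dplyr::n() >= 2L)
          max(var(.data$aod_ret - .data$aod_truth), var_floor)
        else NA_real_,
        n_matches = dplyr::n(), .groups = "drop")
    out <- dplyr::left_join(full, got, by = "season")
    out$n_matches[is.na(out$n_matches)] <- 0L
    out$stream <- label
    out$undefined <- is.na(out$variance)
    out
  }
  res <- dplyr::bind_rows(one(dt_filled, "DT"), one(db_filled, "DB"))
  structure(res[, c("season", "stream", "variance", "n_matches",
                    "undefined")],
            class = c("seasonal_variances", class(res)))
}

#' Inverse variance weighted combination of the gap-filled streams
#'
#' Where both streams are present the combined AOD is
#' \deqn{AOD_c = \frac{AOD_{DT}/Var_{DT,m} + AOD_{DB}/Var_{DB,m}}
#'              {1/Var_{DT,m} + 1/Var_{DB,m}},}
#' with season-specific variances; the two weights sum to 1 exactly. Where
#' only one stream is present its value is used. Seasons whose variance is
#' undefined fall back to equal weights.
#'
#' @param dt_filled,db_filled gap-filled stream tibbles.
#' @param variances a [seasonal_error_variance()] table.
#' @return tibble `cell_id`, `date`, `aod`, `w_dt`, `w_db`.
#' @export
ivw_combine <- function(dt_filled, db_filled, variances) {
  vw <- tidyr::pivot_wider(
    as_tibble(variances)[, c("season", "stream", "variance")],
    names_from = "stream", values_from = "variance")
  both <- dplyr::full_join(dt_filled, db_filled, by = c("cell_id", "date"),
                           suffix = c("_dt", "_db"))
  both$season <- season_of(both$date)
  both <- dplyr::left_join(both, vw, by = "season")
  has_dt <- !is.na(both$aod_dt)
  has_db <- !is.na(both$aod_db)
  w_dt <- ifelse(is.na(both$DT) | is.na(both$DB), 0.5,
                 (1 / both$DT) / (1 / both$DT + 1 / both$DB))
  w_dt[has_dt & !has_db] <- 1
  w_dt[!has_dt & has_db] <- 0
  w_db <- 1 - w_dt
  aod <- ifelse(has_dt & has_db, w_dt * both$aod_dt + w_db * both$aod_db,
                ifelse(has_dt, both$aod_dt, both$aod_db))
  out <- tibble(cell_id = both$cell_id, date = both$date, aod = aod,
                w_dt = w_dt, w_db = w_db)
  out[!is.na(out$aod), ]
}

#' Operational NDVI-based combiner
#'
#' The reference combination rule: the combined AOD equals DT where
#' NDVI > 0.3, DB where NDVI < 0.2, and in the transition band
#' (0.2 <= NDVI <= 0.3) the mean of DT and DB when both carry high quality
#' assurance, or the higher-QA stream when the flags differ. In the band a
#' lone stream is used as is. Outside its NDVI range a stream is discarded
#' even if the preferred one is missing.
#'
#' @param dt,db stream tibbles `cell_id`, `date`, `aod`.
#' @param ndvi tibble `cell_id`, `ndvi` (per cell, static).
#' @param qa_dt,qa_db optional QA tables `cell_id`, `date`, `qa` (integer,
#'   3 = high); all retrievals are treated as high QA when `NULL`.
#' @param high_qa QA value counted as "high" (default 3).
#' @return tibble `cell_id`, `date`, `aod`.
#' @export
operational_combine <- function(dt, db, ndvi, qa_dt = NULL, qa_db = NULL,
                                high_qa = 3L) {
  both <- dplyr::full_join(dt, db, by = c("cell_id", "date"),
                           suffix = c("_dt", "_db"))
  both <- dplyr::left_join(both, ndvi, by = "cell_id")
  if (anyNA(both$ndvi)) stopf("`ndvi` must be defined for every cell")
  get_qa <- function(qa) {
    if (is.null(qa)) return(rep(high_qa, nrow(both)))
    q <- dplyr::left_join(both[, c("cell_id", "date")], qa,
                          by = c("cell_id", "date"))$qa
    ifelse(is.na(q), high_qa, q)
  }
  q_dt <- get_qa(qa_dt); q_db <- get_qa(qa_db)
  has_dt <- !is.na(both$aod_dt); has_db <- !is.na(both$aod_db)

  val <- rep(NA_real_, nrow(both))
  hi <- both$ndvi > 0.3
  lo <- both$ndvi < 0.2
  band <- !hi & !lo
  val[hi] <- both$aod_dt[hi]
  val[lo] <- both$aod_db[lo]

  b_both <- band & has_dt & has_db
  use_mean <- b_both & ((q_dt >= high_qa & q_db >= high_qa) | q_dt == q_db)
  use_dt <- b_both & !use_mean & q_dt > q_db
  use_db <- b_both & !use_mean & q_db > q_dt
  val[use_mean] <- (both$aod_dt[use_mean] + both$aod_db[use_mean]) / 2
  val[use_dt] <- both$aod_dt[use_dt]
  val[use_db] <- both$aod_db[use_db]
  only_dt <- band & has_dt & !has_db
  only_db <- band & has_db & !has_dt
  val[only_dt] <- both$aod_dt[only_dt]
  val[only_db] <- both$aod_db[only_db]

  out <- tibble(cell_id = both$cell_id, date = both$date, aod = val)
  out[!is.na(out$aod), ]
}

#' Run the full three-step AOD fusion
#'
#' Convenience wrapper: crosswalk fit, gap filling, seasonal error-variance
#' calibration against the reference stations, and inverse variance weighted
#' combination.
#'
#' @param dt,db stream tibbles `cell_id`, `date`, `aod`.
#' @param truth_stations reference-station tibble `cell_id`, `date`, `aod`.
#' @param min_pairs per-day crosswalk threshold (see [fit_crosswalk()]).
#' @param var_floor variance floor (see [seasonal_error_variance()]).
#' @return list with `crosswalk`, `filled`, `variances`, `combined`.
#' @export
fuse_aod <- function(dt, db, truth_stations, min_pairs = 10L,
                     var_floor = 1e-4) {
  cw <- fit_crosswalk(dt, db, min_pairs = min_pairs)
  gf <- gap_fill(dt, db, cw)
  sv <- seasonal_error_variance(gf$dt_filled, gf$db_filled, truth_stations,
                                var_floor = var_floor)
  comb <- ivw_combine(gf$dt_filled, gf$db_filled, sv)
  list(crosswalk = cw, filled = gf, variances = sv, combined = comb)
}

#' Coverage comparison between two combined-AOD fields
#'
#' Per-cell available-day counts for each field and the percentage
#' improvement `100 * (n_combined - n_operational) / n_operational`
#' (undefined, reported `NA`, where the reference count is 0). The returned
#' tibble carries a `domain` attribute with the domain-total counts and
#' improvement.
#'
#' @param combined,operational AOD tibbles `cell_id`, `date`, `aod`.
#' @param grid a `grid_spec` enumerating the cells.
#' @return tibble `cell_id`, `n_combined`, `n_operational`, `improvement`.
#' @export
coverage_comparison <- function(combined, operational, grid) {
  cnt <- function(x, nm) {
    out <- x |> dplyr::count(.data$cell_id, name = nm)
    out <- dplyr::left_join(grid[, "cell_id"], out, by = "cell_id")
    out[[nm]][is.na(out[[nm]])] <- 0L
    out
  }
  res <- dplyr::inner_join(cnt(combined, "n_combined"),
                           cnt(operational, "n_operational"),
                           by = "cell_id")
  res$improvement <- ifelse(
    res$n_operational > 0,
    100 * (res$n_combined - res$n_operational) / res$n_operational,
    NA_real_)
  dom_c <- sum(res$n_combined); dom_o <- sum(res$n_operational)
  attr(res, "domain") <- list(
    n_combined = dom_c, n_operational = dom_o,
    improvement = if (dom_o > 0) 100 * (dom_c - dom_o) / dom_o else NA_real_)
  res
}
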