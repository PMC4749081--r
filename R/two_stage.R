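# Two-stage calibration model: per-region linear mixed-effects fits with
# day-specific random intercept/AOD slope and season-specific meteorology
# slopes, buffer-zone expansion for data-poor regions with overlap
# averaging, then a national residual spatial smooth.

STAGE1_COVARS <- c("AOD", "WS", "PBLH", "PS", "RH_PBLH", "Precip_Lag1",
                   "Fire_spots")
SEASON_COVARS <- c("WS", "PBLH", "PS", "RH_PBLH")

#' Build region training buffers
#'
#' Each region's training set starts with the fitting records in its own
#' cells and expands outward by concentric rings of neighbouring cells (in
#' increasing centroid distance to the region's own cells) until it contains
#' at least `min_records` records and `min_days` distinct days, or the whole
#' domain is included. The expansion is deterministic given the grid.
#'
#' @param grid a `grid_spec`.
#' @param fitting_table tibble with at least `cell_id`, `date`.
#' @param min_records,min_days inclusion thresholds (defaults 3000 and 300).
#' @return named list mapping each region label to the sorted integer vector
#'   of buffer cell ids (always including the region's own cells). The
#'   attribute `met_thresholds` is a named logical vector.
#' @export
build_region_buffers <- function(grid, fitting_table, min_records = 3000L,
                                 min_days = 300L) {
  if (nrow(fitting_table) == 0L) stopf("fitting table is empty")
  regions <- sort(unique(grid$region))
  all_dates <- sort(unique(fitting_table$date))
  recs_by_cell <- table(factor(fitting_table$cell_id,
                               levels = grid$cell_id))
  # day index per record, for incremental distinct-day counting
  day_idx_by_cell <- split(match(fitting_table$date, all_dates),
                           factor(fitting_table$cell_id,
                                  levels = grid$cell_id))
  buffers <- list()
  met <- logical(length(regions)); names(met) <- regions
  for (r in regions) {
    own <- grid$cell_id[grid$region == r]
    others <- grid$cell_id[grid$region != r]
    # min planar centroid distance from each outside cell to the region
    if (length(others) > 0L) {
      d2 <- outer(grid$lat[others + 1L], grid$lat[own + 1L], "-")^2 +
        outer(grid$lon[others + 1L], grid$lon[own + 1L], "-")^2
      dmin <- round(sqrt(apply(d2, 1L, min)), 9)
      ring_levels <- sort(unique(dmin))
    } else {
      dmin <- numeric(); ring_levels <- numeric()
    }
    buf <- own
    day_counts <- integer(length(all_dates))
    add_cells <- function(cells) {
      for (cid in cells) {
        di <- day_idx_by_cell[[as.character(cid)]]
        if (length(di)) {
          t <- tabulate(di, nbins = length(all_dates))
          day_counts <<- day_counts + t
        }
      }
    }
    add_cells(own)
    n_rec <- sum(recs_by_cell[as.character(own)])
    ok <- function() n_rec >= min_records && sum(day_counts > 0L) >= min_days
    i <- 1L
    while (!ok() && i <= length(ring_levels)) {
      ring <- others[dmin == ring_levels[i]]
      add_cells(ring)
      n_rec <- n_rec + sum(recs_by_cell[as.character(ring)])
      buf <- c(buf, ring)
      i <- i + 1L
    }
    if (!ok())
      warning(sprintf(
        "region %s: thresholds unattainable on the whole domain (%d records, %d days)",
        r, n_rec, sum(day_counts > 0L)), call. = FALSE)
    met[r] <- ok()
    buffers[[r]] <- sort(buf)
  }
  attr(buffers, "met_thresholds") <- met
  buffers
}

#' Fit the stage-1 linear mixed-effects model for one region
#'
#' Restricted maximum likelihood fit of PM2.5 on the seven centered
#' covariates, with crossed random effects: a correlated day-specific random
#' intercept and AOD slope, and season-specific random slopes for the four
#' meteorological variables. If the full season covariance does not
#' converge, the fit falls back to a diagonal season covariance, then to no
#' season effects; each fallback is recorded on the returned object.
#' Singular (boundary) fits are accepted: a zero variance component is a
#' legitimate estimate.
#'
#' @param region_table fitting rows for the (buffered) region, with centered
#'   covariates, `pm25`, `day_key`, `season`.
#' @param region label stored on the fit.
#' @return object of class `lme_stage1` with elements `fixed` (named
#'   vector), `fixed_se`, `day_effects`, `season_effects` (conditional
#'   modes), `Psi1`,
#'   `Psi2`, `sigma2`, `n_records`, `n_days`, `fallback`
#'   (`"none"`/`"diagonal"`/`"no_season"`), `messages`, and `fitted`
#'   (tibble of in-sample fitted values keyed by `cell_id`, `date`).
#' @export
fit_stage1 <- function(region_table, region = "all") {
  df <- as.data.frame(region_table)
  df$day_key <- factor(df$day_key)
  df$season <- factor(df$season, levels = SEASONS)
  forms <- list(
    full = pm25 ~ AOD + WS + PBLH + PS + RH_PBLH + Precip_Lag1 + Fire_spots +
      (1 + AOD | day_key) + (0 + WS + PBLH + PS + RH_PBLH | season),
    diagonal = pm25 ~ AOD + WS + PBLH + PS + RH_PBLH + Precip_Lag1 +
      Fire_spots + (1 + AOD | day_key) +
      (0 + WS + PBLH + PS + RH_PBLH || season),
    no_season = pm25 ~ AOD + WS + PBLH + PS + RH_PBLH + Precip_Lag1 +
      Fire_spots + (1 + AOD | day_key)
  )
  msgs <- character()
  fit <- NULL; level <- NA_character_
  for (lv in names(forms)) {
    warns <- character()
    res <- tryCatch(
      withCallingHandlers(
        suppressMessages(lme4::lmer(
          forms[[lv]], data = df, REML = TRUE,
          control = lme4::lmerControl(calc.derivs = FALSE))),
        warning = function(w) {
          warns <<- c(warns, conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) conditionMessage(e))
    if (!is.character(res) &&
        !any(grepl("failed to converge|convergence code", warns,
                   ignore.case = TRUE))) {
      fit <- res; level <- lv
      break
    }
    msgs <- c(msgs, sprintf("[%s] %s", lv,
                            paste(c(if (is.character(res)) res, warns),
                                  collapse = "; ")))
  }
  if (is.null(fit))
    stopf("stage-1 fit failed at every fallback level: %s",
          paste(msgs, collapse = " | "))

  fixed <- lme4::fixef(fit)
  fixed_se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  re <- lme4::ranef(fit)
  day_re <- NULL
  season_cols <- list()
  for (i in seq_along(re)) {
    gf <- names(re)[i]
    if (gf == "day_key") {
      day_re <- tibble(day_key = rownames(re[[i]]),
                       re_intercept = re[[i]][["(Intercept)"]],
                       re_aod = re[[i]][["AOD"]])
    } else {
      for (cn in colnames(re[[i]]))
        season_cols[[cn]] <- re[[i]][[cn]][match(SEASONS,
                                                 rownames(re[[i]]))]
    }
  }
  season_re <- tibble(season = SEASONS)
  for (v in SEASON_COVARS)
    season_re[[paste0("re_", v)]] <-
      if (!is.null(season_cols[[v]])) {
        x <- season_cols[[v]]; x[is.na(x)] <- 0; x
      } else rep(0, 4L)

  vc <- lme4::VarCorr(fit)
  Psi1 <- matrix(as.numeric(vc$day_key), 2L, 2L)
  Psi2 <- if (level == "no_season") matrix(0, 4L, 4L) else {
    m <- matrix(0, 4L, 4L, dimnames = list(SEASON_COVARS, SEASON_COVARS))
    for (i in seq_along(vc)) {
      if (names(vc)[i] == "day_key") next
      blk <- as.matrix(vc[[i]])
      m[rownames(blk), colnames(blk)] <- blk
    }
    m
  }

  structure(list(
    region = region,
    fixed = fixed,
    fixed_se = fixed_se,
    day_effects = day_re,
    season_effects = season_re,
    Psi1 = Psi1, Psi2 = Psi2, sigma2 = sigma(fit)^2,
    n_records = nrow(df),
    n_days = length(unique(df$day_key)),
    fallback = c(full = "none", diagonal = "diagonal",
                 no_season = "no_season")[[level]],
    messages = msgs,
    fitted = tibble(cell_id = df$cell_id, date = df$date,
                    fitted = unname(stats::fitted(fit)))
  ), class = "lme_stage1")
}

# stage-1 prediction for a single regional fit
predict_lme_stage1 <- function(fit, newdata) {
  f <- fit$fixed
  pred <- unname(f[["(Intercept)"]]) +
    as.matrix(newdata[, STAGE1_COVARS]) %*% f[STAGE1_COVARS]
  pred <- as.vector(pred)
  dk <- day_key(newdata$date)
  idx <- match(dk, fit$day_effects$day_key)
  has_day <- !is.na(idx)
  pred[has_day] <- pred[has_day] + fit$day_effects$re_intercept[idx[has_day]] +
    fit$day_effects$re_aod[idx[has_day]] * newdata$AOD[has_day]
  sidx <- match(season_of(newdata$date), fit$season_effects$season)
  se <- fit$season_effects
  pred <- pred + se$re_WS[sidx] * newdata$WS +
    se$re_PBLH[sidx] * newdata$PBLH +
    se$re_PS[sidx] * newdata$PS +
    se$re_RH_PBLH[sidx] * newdata$RH_PBLH
  list(pred = pred, day_effect_used = has_day)
}

#' Stage-1 predictions with buffer-overlap averaging
#'
#' Each cell is predicted by every regional model whose buffer contains it;
#' overlapping predictions are averaged (unweighted). Day-specific effects
#' are transferred across years by calendar month-day (February 29 uses
#' February 28); a date whose month-day was never fitted uses the fixed
#' effects only and is flagged.
#'
#' @param fits named list of [fit_stage1()] objects (one per region).
#' @param buffers region-to-cells mapping from [build_region_buffers()].
#' @param newdata prediction rows with centered covariates and `cell_id`,
#'   `date`.
#' @return tibble of `newdata` keys plus `stage1_pred`, `n_models`,
#'   `day_effect_used` (TRUE when every contributing model had a fitted day
#'   effect for the date).
#' @export
predict_stage1 <- function(fits, buffers, newdata) {
  n <- nrow(newdata)
  acc <- numeric(n); cnt <- integer(n); day_ok <- rep(TRUE, n)
  for (r in names(fits)) {
    in_buf <- newdata$cell_id %in% buffers[[r]]
    if (!any(in_buf)) next
    p <- predict_lme_stage1(fits[[r]], newdata[in_buf, ])
    acc[in_buf] <- acc[in_buf] + p$pred
    cnt[in_buf] <- cnt[in_buf] + 1L
    day_ok[in_buf] <- day_ok[in_buf] & p$day_effect_used
  }
  if (any(cnt == 0L))
    stopf("%d prediction rows are covered by no regional model",
          sum(cnt == 0L))
  tibble(cell_id = newdata$cell_id, date = newdata$date,
         stage1_pred = acc / cnt, n_models = cnt,
         day_effect_used = day_ok)
}

#' Fit the stage-2 residual spatial smooth
#'
#' Penalized additive model of the stage-1 residuals: a two-dimensional
#' thin-plate smooth of the cell centroid coordinates plus univariate
#' smooths of forest and urban cover. Smoothing parameters are selected by
#' REML with an extra shrinkage penalty on each smooth's null space
#' (`select = TRUE`), so pure-noise residuals shrink toward a constant.
#' Basis dimensions are capped at the number of unique covariate values,
#' with a message when reduced. Above 5000 rows the fit uses
#' `mgcv::bam(discrete = TRUE)` (fast REML variant), below it
#' `mgcv::gam(method = "REML")`.
#'
#' @param resid_table tibble with `resid`, `lon`, `lat`, `forest_frac`,
#'   `urban_frac`.
#' @param k_xy basis dimension of the coordinate smooth (default
#'   `min(100, n/10)`, at least 20).
#' @param k_1d basis dimension of each cover smooth (default 10).
#' @return object of class `gam_stage2` wrapping the `mgcv::gam` fit, with
#'   `edf` (per-term effective degrees of freedom) and `mu0` (intercept).
#' @export
fit_stage2 <- function(resid_table, k_xy = NULL, k_1d = 10L) {
  n <- nrow(resid_table)
  n_xy <- nrow(unique(resid_table[, c("lon", "lat")]))
  k_xy <- k_xy %||% max(20L, min(100L, floor(n / 10)))
  if (k_xy > n_xy - 1L) {
    k_xy <- max(3L, n_xy - 1L)
    message("stage 2: coordinate smooth basis reduced to k = ", k_xy)
  }
  terms <- sprintf("s(lon, lat, k = %d)", k_xy)
  for (v in c("forest_frac", "urban_frac")) {
    nu <- length(unique(resid_table[[v]]))
    k <- k_1d
    if (k > nu - 1L) {
      k <- nu - 1L
      if (k >= 3L)
        message("stage 2: ", v, " smooth basis reduced to k = ", k)
    }
    if (k >= 3L) terms <- c(terms, sprintf("s(%s, k = %d)", v, k))
    else message("stage 2: ", v, " has too few unique values; term dropped")
  }
  form <- stats::as.formula(paste("resid ~", paste(terms, collapse = " + ")))
  g <- if (n > 5000L) {
    mgcv::bam(form, data = resid_table, method = "fREML", select = TRUE,
              discrete = TRUE)
  } else {
    mgcv::gam(form, data = resid_table, method = "REML", select = TRUE)
  }
  edf <- vapply(seq_along(g$smooth), function(i) {
    sm <- g$smooth[[i]]
    sum(g$edf[sm$first.para:sm$last.para])
  }, numeric(1))
  names(edf) <- vapply(g$smooth, function(s) s$label, character(1))
  structure(list(gam = g, edf = edf, mu0 = unname(coef(g)[1L]),
                 k_xy = k_xy),
            class = "gam_stage2")
}

#' @export
predict.gam_stage2 <- function(object, newdata, ...) {
  as.vector(predict(object$gam, newdata = newdata, ...))
}

#' Fit the full two-stage model
#'
#' Builds the region buffers, fits the stage-1 mixed model per region, forms
#' the (overlap-averaged) stage-1 residuals on the fitting rows, and fits
#' the national stage-2 residual smooth.
#'
#' @param fitting_table assembled fitting rows (see [assemble_tables()]).
#' @param grid a `grid_spec`.
#' @param min_records,min_days buffer thresholds (see
#'   [build_region_buffers()]).
#' @param stage2 fit the residual smooth (default TRUE)?
#' @param k_xy,k_1d stage-2 basis dimensions.
#' @return object of class `two_stage_fit`: list with `region_fits`,
#'   `buffers`, `stage2` (a `gam_stage2` or `NULL`), `stage1_fitting`
#'   (fitting rows with `stage1_pred` and `resid`).
#' @export
fit_two_stage <- function(fitting_table, grid, min_records = 3000L,
                          min_days = 300L, stage2 = TRUE, k_xy = NULL,
                          k_1d = 10L) {
  buffers <- build_region_buffers(grid, fitting_table, min_records, min_days)
  fits <- lapply(names(buffers), function(r) {
    fit_stage1(fitting_table[fitting_table$cell_id %in% buffers[[r]], ],
               region = r)
  })
  names(fits) <- names(buffers)
  s1 <- predict_stage1(fits, buffers, fitting_table)
  s1_fit <- fitting_table
  s1_fit$stage1_pred <- s1$stage1_pred
  s1_fit$resid <- s1_fit$pm25 - s1_fit$stage1_pred
  g <- if (stage2) fit_stage2(s1_fit, k_xy = k_xy, k_1d = k_1d) else NULL
  structure(list(region_fits = fits, buffers = buffers, stage2 = g,
                 stage1_fitting = as_tibble(s1_fit)),
            class = "two_stage_fit")
}

#' Predict PM2.5 from a fitted two-stage model
#'
#' Stage-1 prediction (buffer-overlap averaged, day effects transferred by
#' calendar month-day) plus the stage-2 residual surface. Negative totals
#' are truncated at 0 and flagged.
#'
#' @param fits a [fit_two_stage()] object.
#' @param newdata prediction rows with centered covariates, `cell_id`,
#'   `date`, `lon`, `lat`, `forest_frac`, `urban_frac`.
#' @return tibble `cell_id`, `date`, `pred`, `stage1_pred`, `surface`,
#'   `day_effect_used`, `truncated`.
#' @export
predict_full <- function(fits, newdata) {
  stopifnot(inherits(fits, "two_stage_fit"))
  s1 <- predict_stage1(fits$region_fits, fits$buffers, newdata)
  surf <- if (!is.null(fits$stage2))
    predict(fits$stage2, newdata) else rep(0, nrow(newdata))
  raw <- s1$stage1_pred + surf
  tibble(cell_id = newdata$cell_id, date = newdata$date,
         pred = pmax(0, raw), stage1_pred = s1$stage1_pred,
         surface = surf, day_effect_used = s1$day_effect_used,
         truncated = raw < 0)
}
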