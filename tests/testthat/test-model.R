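# hand-built stage-1 fit object: a pure intercept model
mk_const_fit <- function(const) {
  seas <- c("DJF", "MAM", "JJA", "SON")
  structure(list(
    region = "X",
    fixed = c("(Intercept)" = const, AOD = 0, WS = 0, PBLH = 0, PS = 0,
              RH_PBLH = 0, Precip_Lag1 = 0, Fire_spots = 0),
    fixed_se = rep(0, 8),
    day_effects = tibble::tibble(day_key = character(),
                                 re_intercept = numeric(),
                                 re_aod = numeric()),
    season_effects = tibble::tibble(season = seas, re_WS = 0, re_PBLH = 0,
                                    re_PS = 0, re_RH_PBLH = 0),
    Psi1 = matrix(0, 2, 2), Psi2 = matrix(0, 4, 4), sigma2 = 1,
    n_records = 0L, n_days = 0L, fallback = "none", messages = character(),
    fitted = tibble::tibble()), class = "lme_stage1")
}

zero_cov_rows <- function(cell_id, date) tibble::tibble(
  cell_id = cell_id, date = date, AOD = 0, WS = 0, PBLH = 0, PS = 0,
  RH_PBLH = 0, Precip_Lag1 = 0, Fire_spots = 0,
  lon = 0.05, lat = 0.05, forest_frac = 0.3, urban_frac = 0.1)

recovery1 <- function() cached("recovery1", {
  rw <- recovery_world(seed = 301L)
  fit <- fit_stage1(rw$tables$fitting, region = "all")
  c(rw, list(fit = fit))
})

test_that("buffers expand data-poor regions by distance rings until thresholds hold", {
  w <- small_world()
  ft <- small_tables()$fitting

  # degenerate thresholds: every region keeps only its own cells
  b1 <- build_region_buffers(w$grid, ft, min_records = 1L, min_days = 1L)
  for (r in names(b1))
    expect_equal(b1[[r]], sort(w$grid$cell_id[w$grid$region == r]))
  expect_true(all(attr(b1, "met_thresholds")))

  # a region with zero monitors expands until the record threshold is met
  east <- names(sort(tapply(w$grid$lon, w$grid$region, mean),
                     decreasing = TRUE))[1:2]
  poor <- setdiff(unique(w$grid$region), east)[1]
  ft_poor <- ft[!ft$cell_id %in% w$grid$cell_id[w$grid$region == poor], ]
  b2 <- build_region_buffers(w$grid, ft_poor, min_records = 400L,
                             min_days = 60L)
  own <- w$grid$cell_id[w$grid$region == poor]
  expect_gt(length(b2[[poor]]), length(own))
  expect_true(all(own %in% b2[[poor]]))
  n_rec <- sum(ft_poor$cell_id %in% b2[[poor]])
  expect_gte(n_rec, 400L)

  # unattainable thresholds: whole domain with a warning (one per region)
  ws <- testthat::capture_warnings(
    b3 <- build_region_buffers(w$grid, ft, min_records = 1e6))
  expect_true(all(grepl("unattainable", ws)))
  expect_equal(length(ws), length(unique(w$grid$region)))
  expect_equal(sort(b3[[1L]]), sort(w$grid$cell_id))

  expect_error(build_region_buffers(w$grid, ft[0, ]), "empty")
})

test_that("stage-1 REML fit recovers the generative fixed slopes and day effects", {
  r1 <- recovery1()
  fit <- r1$fit
  b <- r1$params$beta
  est <- fit$fixed[names(b)]
  se <- fit$fixed_se[names(b)]
  z <- (est - b) / se
  expect_true(all(abs(z) < 3), label = paste("z:", paste(round(z, 2),
                                                         collapse = " ")))
  # day-specific AOD slopes track the truth series
  de <- dplyr::inner_join(fit$day_effects, r1$world$day_effects,
                          by = "day_key")
  expect_gte(cor(de$re_aod.x, de$re_aod.y), 0.8)
  # conditional modes are shrunken: less variable than the truth draws
  expect_lte(var(de$re_aod.x), var(de$re_aod.y))
  expect_lte(var(de$re_intercept.x), var(de$re_intercept.y))
  # shrinkage contract: estimated effects average near zero
  expect_lt(abs(mean(de$re_aod.x)), 0.05 * sd(de$re_aod.x))
  expect_lt(abs(mean(de$re_intercept.x)), 0.05 * sd(de$re_intercept.x))
  # variance components are estimated near the truth
  expect_equal(fit$sigma2, r1$params$sigma^2, tolerance = 0.15)
  expect_equal(fit$Psi1[1, 1], r1$params$Psi1[1, 1], tolerance = 0.35)
})

test_that("zero-variance day effects are recovered at the boundary", {
  g <- make_grid(c(30, 31.4, 110, 111.4), 0.1, 1L)
  params <- truth_parameters(Psi1 = matrix(0, 2, 2), spatial_surface = NULL)
  w <- simulate_world(grid = g,
                      dates = seq(as.Date("2013-01-01"), by = "day",
                                  length.out = 120L),
                      params = params, seed = 77L,
                      n_monitors_east = 40L, n_monitors_other = 0L)
  tabs <- assemble_tables(w$truth_aod, w$met_fine, w$fire_counts,
                          w$covariates$landuse, w$monitors, g)
  fit <- fit_stage1(tabs$fitting)
  expect_true(all(abs(fit$Psi1) < 0.05 * fit$sigma2))
})

test_that("stage-1 predictions reproduce the mixed model's fitted values exactly", {
  r1 <- recovery1()
  fit <- r1$fit
  ft <- r1$tables$fitting
  buf <- list(all = sort(unique(r1$world$grid$cell_id)))
  p <- predict_stage1(list(all = fit), buf, ft)
  expect_equal(p$stage1_pred,
               fit$fitted$fitted[match(paste(ft$cell_id, ft$date),
                                       paste(fit$fitted$cell_id,
                                             fit$fitted$date))],
               tolerance = 1e-9)
  expect_true(all(p$day_effect_used))
  expect_true(all(p$n_models == 1L))
})

test_that("overlapping regional predictions are averaged and stay in their hull", {
  rows <- zero_cov_rows(cell_id = c(0L, 1L), date = as.Date("2013-06-01"))
  fits <- list(A = mk_const_fit(50), B = mk_const_fit(70))
  # cell 0 in both buffers, cell 1 only in A's
  buffers <- list(A = c(0L, 1L), B = 0L)
  p <- predict_stage1(fits, buffers, rows)
  expect_equal(p$stage1_pred[p$cell_id == 0L], 60)
  expect_equal(p$stage1_pred[p$cell_id == 1L], 50)
  expect_equal(p$n_models, c(2L, 1L))
  # convex hull: averaged prediction lies between the contributors
  expect_true(p$stage1_pred[1] >= 50 && p$stage1_pred[1] <= 70)

  # a cell covered by no model is an error
  expect_error(predict_stage1(fits, list(A = 5L, B = 5L), rows), "covered")

  # with zero covariates and no day effect the prediction is the intercept
  p1 <- predict_stage1(list(A = mk_const_fit(42)), list(A = c(0L, 1L)), rows)
  expect_equal(p1$stage1_pred, c(42, 42))
  expect_false(any(p1$day_effect_used)) # no fitted day effects -> flagged
})

test_that("day effects transfer by calendar month-day with Feb 29 mapped to Feb 28", {
  r1 <- recovery1()
  fit <- r1$fit
  buf <- list(all = sort(unique(r1$world$grid$cell_id)))
  # 2012 is a leap year: Feb 29 must reuse the Feb 28 day effect
  rows <- zero_cov_rows(0L, as.Date(c("2012-02-28", "2012-02-29")))
  p <- predict_stage1(list(all = fit), buf, rows)
  expect_equal(p$stage1_pred[1], p$stage1_pred[2])
  expect_true(all(p$day_effect_used))
  de <- fit$day_effects
  expect_equal(p$stage1_pred[1],
               unname(fit$fixed[["(Intercept)"]]) +
                 de$re_intercept[de$day_key == "02-28"],
               tolerance = 1e-9)
})

test_that("season-effect fallback ladder engages when the season factor degenerates", {
  r1 <- recovery1()
  jan <- r1$tables$fitting[format(r1$tables$fitting$date, "%m") == "01", ]
  fit <- fit_stage1(jan)                 # a single season level
  expect_equal(fit$fallback, "no_season")
  expect_true(length(fit$messages) >= 1L)
  expect_equal(fit$Psi2, matrix(0, 4, 4), ignore_attr = TRUE)
  expect_true(all(as.matrix(fit$season_effects[, -1L]) == 0))
})

test_that("stage-2 smooth recovers an injected surface and shrinks on pure noise", {
  set.seed(21)
  n_cell <- 80L
  cells <- tibble::tibble(lon = runif(n_cell), lat = runif(n_cell),
                          forest_frac = runif(n_cell),
                          urban_frac = runif(n_cell) * 0.5)
  # replicated across days like real residual tables
  df <- cells[rep(seq_len(n_cell), 30L), ]
  truth <- 10 * sin(2 * pi * df$lon) * cos(pi * df$lat) + 4 * df$forest_frac

  df$resid <- truth
  g1 <- fit_stage2(df, k_xy = 40L)
  expect_gte(cor(predict(g1, df), truth), 0.99)

  df$resid <- rnorm(nrow(df))
  g2 <- fit_stage2(df, k_xy = 40L)
  expect_true(all(g2$edf <= 2),
              label = paste("edf:", paste(round(g2$edf, 2), collapse = " ")))
  # effective degrees of freedom never exceed the basis dimension
  expect_true(all(g2$edf <= c(40, 10, 10)))

  # small-sample path: intercept equals the residual mean (sum-to-zero smooths)
  df_small <- df[1:400, ]
  df_small$resid <- rnorm(400)
  g3 <- fit_stage2(df_small, k_xy = 20L)
  expect_lt(abs(g3$mu0 - mean(df_small$resid)), 1e-6)

  # basis reduction on few unique values is logged, not fatal
  df2 <- df[1:200, ]
  df2$forest_frac <- rep(c(0.1, 0.2, 0.3, 0.4, 0.5), 40L)
  expect_message(fit_stage2(df2, k_xy = 20L), "reduced")
})

test_that("full-model prediction adds the surface, truncates at zero and beats stage 1", {
  # additivity with hand-built objects: stage 1 of 40 plus surface +20 is 60
  rows <- zero_cov_rows(0L, as.Date("2013-06-01"))
  fits <- structure(list(
    region_fits = list(A = mk_const_fit(40)), buffers = list(A = 0L),
    stage2 = NULL, stage1_fitting = tibble::tibble()),
    class = "two_stage_fit")
  p0 <- predict_full(fits, rows)
  expect_equal(p0$pred, 40)           # zero surface: full equals stage 1
  expect_equal(p0$surface, 0)

  # negative totals truncate at 0 and are flagged
  fits$region_fits$A <- mk_const_fit(-5)
  pneg <- predict_full(fits, rows)
  expect_equal(pneg$pred, 0)
  expect_true(pneg$truncated)

  # on the small world, the full model fits at least as well as stage 1
  tf <- small_fit()
  ft <- small_tables()$fitting
  full <- predict_full(tf, ft)
  r2_full <- compute_stats(full$pred, ft$pm25)$r2
  r2_s1 <- compute_stats(full$stage1_pred, ft$pm25)$r2
  expect_gte(r2_full, r2_s1)
  # and the surface is additive by construction
  expect_equal(full$pred,
               pmax(0, full$stage1_pred + full$surface), tolerance = 1e-12)
})
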