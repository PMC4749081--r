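# helper: stream tibbles from vectors
stream <- function(cell_id, date, aod) tibble::tibble(
  cell_id = as.integer(cell_id), date = as.Date(date), aod = aod)

test_that("crosswalk recovers an exact linear relation and matches lm on noisy data", {
  set.seed(1)
  n <- 100L
  d <- rep(seq(as.Date("2013-01-01"), by = "day", length.out = 5L), each = 20L)
  x <- runif(n, 0.2, 1.2)
  dt <- stream(seq_len(n) - 1L, d, x)
  db <- stream(seq_len(n) - 1L, d, 0.8 * x + 0.02)
  cw <- fit_crosswalk(dt, db)
  po <- cw$pooled
  expect_equal(po$slope[po$direction == "dt_to_db"], 0.8, tolerance = 1e-12)
  expect_equal(po$intercept[po$direction == "dt_to_db"], 0.02,
               tolerance = 1e-12)
  # exact data: every per-day fit reproduces the same line, no fallback
  pd <- cw$per_day[cw$per_day$direction == "dt_to_db", ]
  expect_true(all(abs(pd$slope - 0.8) < 1e-10))
  expect_false(any(pd$pooled_fallback))

  # noisy pairs: pooled OLS equals stats::lm and lands within 3 SE of truth
  set.seed(2)
  x2 <- runif(500L, 0.2, 1.2)
  y2 <- 0.8 * x2 + 0.02 + rnorm(500L, 0, 0.05)
  dt2 <- stream(seq_len(500L) - 1L, as.Date("2013-06-01"), x2)
  db2 <- stream(seq_len(500L) - 1L, as.Date("2013-06-01"), y2)
  cw2 <- fit_crosswalk(dt2, db2)
  ref <- lm(y2 ~ x2)
  est <- cw2$pooled[cw2$pooled$direction == "dt_to_db", ]
  expect_equal(est$slope, unname(coef(ref)[2L]), tolerance = 1e-10)
  expect_equal(est$intercept, unname(coef(ref)[1L]), tolerance = 1e-10)
  se <- summary(ref)$coefficients["x2", "Std. Error"]
  expect_lt(abs(est$slope - 0.8), 3 * se)
})

test_that("sparse days fall back to the pooled crosswalk and empty overlap errors", {
  d1 <- as.Date("2013-01-01"); d2 <- as.Date("2013-01-02")
  # day 1 rich (12 pairs), day 2 has a single pair -> fallback
  dt <- stream(c(0:11, 0L), c(rep(d1, 12L), d2), c(seq(0.1, 1.2, by = 0.1), 0.5))
  db <- stream(c(0:11, 0L), c(rep(d1, 12L), d2),
               c(0.9 * seq(0.1, 1.2, by = 0.1) + 0.05, 0.77))
  cw <- fit_crosswalk(dt, db, min_pairs = 10L)
  pd <- cw$per_day[cw$per_day$direction == "dt_to_db", ]
  expect_false(pd$pooled_fallback[pd$date == d1])
  expect_true(pd$pooled_fallback[pd$date == d2])
  po <- cw$pooled[cw$pooled$direction == "dt_to_db", ]
  expect_equal(pd$slope[pd$date == d2], po$slope)
  expect_equal(pd$intercept[pd$date == d2], po$intercept)

  # no collocated pairs at all -> cannot calibrate
  expect_error(
    fit_crosswalk(stream(0L, d1, 0.5), stream(1L, d1, 0.4)),
    "cannot calibrate")
})

test_that("gap filling imputes exactly the one-stream cell-days", {
  d <- as.Date("2013-01-01")
  # 12 collocated pairs define the crosswalk DB = 0.8 DT + 0.02 exactly
  x <- seq(0.1, 1.2, by = 0.1)
  dt <- stream(c(0:11, 20L), rep(d, 13L), c(x, 0.5))          # cell 20: DT only
  db <- stream(c(0:11, 30L), rep(d, 13L), c(0.8 * x + 0.02, 0.3)) # 30: DB only
  cw <- fit_crosswalk(dt, db)
  gf <- gap_fill(dt, db, cw)

  f20 <- gf$db_filled[gf$db_filled$cell_id == 20L, ]
  expect_equal(f20$aod, 0.8 * 0.5 + 0.02, tolerance = 1e-12)
  expect_true(f20$imputed)

  # both-stream cell-days unchanged and unflagged
  keep <- gf$dt_filled$cell_id %in% 0:11
  expect_equal(gf$dt_filled$aod[keep][order(gf$dt_filled$cell_id[keep])], x)
  expect_false(any(gf$dt_filled$imputed[keep]))
  expect_false(any(gf$db_filled$imputed[gf$db_filled$cell_id %in% 0:11]))

  # count of imputed cell-days equals the count of one-stream cell-days
  expect_equal(sum(gf$dt_filled$imputed) + sum(gf$db_filled$imputed), 2L)

  # on the synthetic world: brute-force count over the generated masks
  w <- small_world()
  gfw <- small_fusion()$filled
  key <- function(x) paste(x$cell_id, x$date)
  one_stream <- length(setdiff(key(w$dt), key(w$db))) +
    length(setdiff(key(w$db), key(w$dt)))
  expect_equal(sum(gfw$dt_filled$imputed) + sum(gfw$db_filled$imputed),
               one_stream)
})

test_that("seasonal error variances match hand values, floor and Monte-Carlo noise", {
  d_djf <- as.Date(c("2013-01-10", "2013-01-11"))
  st <- stream(c(0L, 0L), d_djf, c(0.5, 0.5))
  ret <- stream(c(0L, 0L), d_djf, c(0.6, 0.4)) # diffs +0.1, -0.1
  ret$imputed <- FALSE
  sv <- seasonal_error_variance(ret, ret, st)
  v <- sv$variance[sv$season == "DJF" & sv$stream == "DT"]
  expect_equal(v, 0.02, tolerance = 1e-12)

  # identical retrieval and truth: degenerate zero variance gets the floor
  sv0 <- seasonal_error_variance(st, st, st)
  expect_equal(sv0$variance[sv0$season == "DJF" & sv0$stream == "DT"], 1e-4)

  # seasons with < 2 matches are flagged undefined
  expect_true(all(sv$undefined[sv$season == "JJA"]))
  expect_equal(sv$n_matches[sv$season == "JJA" & sv$stream == "DT"], 0L)

  # Monte-Carlo: noise SD 0.1, zero bias, n >= 1000 matches
  set.seed(3)
  n <- 2000L
  dates <- rep(seq(as.Date("2013-06-01"), by = "day", length.out = 40L), 50L)
  truth_v <- runif(n, 0.2, 1)
  stn <- stream(rep(0:49, each = 40L), dates, truth_v)
  retn <- stn
  retn$aod <- truth_v + rnorm(n, 0, 0.1)
  retn$imputed <- FALSE
  svn <- seasonal_error_variance(retn, retn, stn)
  vhat <- svn$variance[svn$season == "JJA" & svn$stream == "DT"]
  se_var <- 0.01 * sqrt(2 / (n - 1))
  expect_lt(abs(vhat - 0.01), 3 * se_var)
})

test_that("inverse variance weighting reproduces the closed form and stays convex", {
  d <- as.Date("2013-01-15") # DJF
  mk_var <- function(v_dt, v_db) {
    v <- expand.grid(season = c("DJF", "MAM", "JJA", "SON"),
                     stream = c("DT", "DB"), stringsAsFactors = FALSE)
    v$variance <- ifelse(v$stream == "DT", v_dt, v_db)
    v$n_matches <- 10L; v$undefined <- FALSE
    structure(tibble::as_tibble(v), class = c("seasonal_variances",
                                              class(tibble::tibble())))
  }
  dt <- stream(0L, d, 0.6); dt$imputed <- FALSE
  db <- stream(0L, d, 0.3); db$imputed <- FALSE

  # hand-computed: (0.6/0.04 + 0.3/0.01)/(1/0.04 + 1/0.01) = 0.36
  out <- ivw_combine(dt, db, mk_var(0.04, 0.01))
  expect_equal(out$aod, 0.36, tolerance = 1e-12)
  expect_equal(out$w_dt + out$w_db, 1)

  # equal variances -> arithmetic mean
  out_eq <- ivw_combine(dt, db, mk_var(0.02, 0.02))
  expect_equal(out_eq$aod, 0.45, tolerance = 1e-12)

  # single-stream cell-days pass through; both-missing stays missing
  dt2 <- stream(c(0L, 1L), d, c(0.6, 0.5)); dt2$imputed <- FALSE
  db2 <- stream(c(0L, 2L), d, c(0.3, 0.2)); db2$imputed <- FALSE
  out2 <- ivw_combine(dt2, db2, mk_var(0.04, 0.01))
  expect_equal(out2$aod[out2$cell_id == 1L], 0.5)
  expect_equal(out2$aod[out2$cell_id == 2L], 0.2)
  expect_equal(nrow(out2), 3L)

  # convexity on the synthetic world: combined strictly between the streams
  fz <- small_fusion()
  both <- dplyr::inner_join(fz$filled$dt_filled, fz$filled$db_filled,
                            by = c("cell_id", "date"),
                            suffix = c("_dt", "_db"))
  both <- dplyr::inner_join(both, fz$combined, by = c("cell_id", "date"))
  differ <- abs(both$aod_dt - both$aod_db) > 1e-12
  expect_true(all(
    both$aod[differ] > pmin(both$aod_dt, both$aod_db)[differ] &
      both$aod[differ] < pmax(both$aod_dt, both$aod_db)[differ]))
  expect_equal(both$w_dt + both$w_db, rep(1, nrow(both)))
})

test_that("operational combiner follows the NDVI and QA rules exactly", {
  d <- as.Date("2013-05-01")
  ndvi <- tibble::tibble(cell_id = 0:5,
                         ndvi = c(0.4, 0.25, 0.1, 0.25, 0.4, 0.25))
  dt <- stream(c(0L, 1L, 3L, 5L), d, c(0.5, 0.4, 0.6, 0.8))
  db <- stream(c(1L, 2L, 3L, 5L), d, c(0.2, 0.7, 0.4, 0.6))

  out <- operational_combine(dt, db, ndvi)
  val <- function(i) out$aod[out$cell_id == i]
  expect_equal(val(0L), 0.5)                # NDVI > 0.3 -> DT
  expect_equal(val(1L), 0.3)                # band, both high QA -> mean
  expect_equal(val(2L), 0.7)                # NDVI < 0.2 -> DB
  expect_equal(val(3L), 0.5)                # band mean again
  expect_false(4L %in% out$cell_id)         # NDVI > 0.3 but DT missing

  # unequal QA in the band: the higher-QA stream wins
  qa_dt <- tibble::tibble(cell_id = 5L, date = d, qa = 2L)
  out_qa <- operational_combine(dt, db, ndvi, qa_dt = qa_dt)
  expect_equal(out_qa$aod[out_qa$cell_id == 5L], 0.6) # DB has high QA
})

test_that("coverage comparison counts days and flags undefined improvements", {
  g <- make_grid(c(0, 0.3, 0, 0.2), 0.1, 1L) # 6 cells
  d <- seq(as.Date("2013-01-01"), by = "day", length.out = 10L)
  combined <- stream(rep(c(0L, 1L, 2L), times = c(10L, 10L, 4L)),
                     c(d, d, d[1:4]), 0.5)
  operational <- stream(rep(c(0L, 1L), times = c(10L, 5L)),
                        c(d, d[1:5]), 0.5)
  cc <- coverage_comparison(combined, operational, g)
  expect_equal(cc$improvement[cc$cell_id == 0L], 0)
  expect_equal(cc$improvement[cc$cell_id == 1L], 100)
  expect_true(is.na(cc$improvement[cc$cell_id == 2L])) # reference count 0
  expect_equal(attr(cc, "domain")$n_combined, 24L)

  # combined availability dominates each input stream (monotonicity)
  w <- small_world()
  comb <- small_fusion()$combined
  n_days <- function(x) dplyr::count(x, .data$cell_id, name = "n")
  for (s in list(w$dt, w$db)) {
    j <- dplyr::left_join(n_days(s), n_days(comb), by = "cell_id",
                          suffix = c("_s", "_c"))
    expect_true(all(j$n_c >= j$n_s))
  }
})

test_that("default scenario improves coverage more over bright than vegetated cells", {
  w <- small_world()
  comb <- small_fusion()$combined
  oper <- operational_combine(
    w$dt, w$db, w$covariates$landuse[, c("cell_id", "ndvi")])
  cc <- coverage_comparison(comb, oper, w$grid)
  bright <- w$covariates$landuse$bright[cc$cell_id + 1L]
  impr_bright <- mean(cc$improvement[bright], na.rm = TRUE)
  impr_veg <- mean(cc$improvement[!bright], na.rm = TRUE)
  expect_gt(impr_bright, impr_veg)
})

test_that("IVW fusion error variance does not exceed either stream where both report", {
  w <- small_world()
  fz <- small_fusion()
  both <- dplyr::inner_join(w$dt, w$db, by = c("cell_id", "date"),
                            suffix = c("_dt", "_db")) |>
    dplyr::inner_join(fz$combined, by = c("cell_id", "date")) |>
    dplyr::inner_join(w$truth_aod, by = c("cell_id", "date"),
                      suffix = c("", "_truth"))
  v_comb <- var(both$aod - both$aod_truth)
  v_dt <- var(both$aod_dt - both$aod_truth)
  v_db <- var(both$aod_db - both$aod_truth)
  expect_lt(v_comb, min(v_dt, v_db) * 1.05)
})
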