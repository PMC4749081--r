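# Synthetic study world: grid, AOD retrieval streams, reference AOD stations,
# meteorology, land use, fires, monitors and PM2.5, all generated from known
# parameters so that every downstream stage can be tested against the truth.

#' Ground-truth generative parameters
#'
#' Parameters of the generative PM2.5 model: a linear predictor in the seven
#' covariates with day-specific random intercept/AOD-slope (covariance
#' `Psi1`), season-specific random slopes for the four meteorological
#' variables (covariance `Psi2`), iid residual noise, a deterministic
#' spatial surface, and an optional linear trend.
#'
#' @param mu fixed intercept (micrograms/m3): the expected PM2.5 when every
#'   covariate sits at its reference level `ref`.
#' @param beta named numeric vector of fixed slopes for `AOD`, `WS`, `PBLH`,
#'   `PS`, `RH_PBLH`, `Precip_Lag1`, `Fire_spots`.
#' @param ref named numeric vector of reference covariate levels; the linear
#'   predictor uses `beta * (x - ref)`, mirroring the centering applied
#'   before fitting (slopes are unaffected by the centering constant).
#' @param Psi1 2x2 covariance of the day random (intercept, AOD slope).
#' @param Psi2 4x4 covariance of the season random slopes
#'   (WS, PBLH, PS, RH_PBLH).
#' @param sigma residual standard deviation (micrograms/m3); 0 is allowed
#'   for degenerate noise-free checks.
#' @param spatial_surface `NULL` for no surface, or a function taking a data
#'   frame with `lon`, `lat`, `forest_frac`, `urban_frac` and returning a
#'   per-row offset in micrograms/m3 (see [default_surface()]).
#' @param trend linear trend in micrograms/m3 per year: a scalar, a per-cell
#'   vector (indexed by `cell_id + 1`), or a function of `Date` returning a
#'   domain-wide offset.
#' @param seed default seed used by [simulate_world()].
#' @return list of class `truth_parameters`.
#' @export
truth_parameters <- function(
    mu = 77,
    beta = c(AOD = 60, WS = -2.5, PBLH = -2, PS = 0.15, RH_PBLH = 0.25,
             Precip_Lag1 = -0.8, Fire_spots = 1.5),
    ref = c(AOD = 0.65, WS = 3, PBLH = 8, PS = 1000, RH_PBLH = 60,
            Precip_Lag1 = 1.5, Fire_spots = 0.2),
    Psi1 = matrix(c(144, 54, 54, 225), 2, 2),
    Psi2 = matrix(0, 4, 4),
    sigma = 12,
    spatial_surface = default_surface(),
    trend = 0,
    seed = 1L) {
  need <- c("AOD", "WS", "PBLH", "PS", "RH_PBLH", "Precip_Lag1", "Fire_spots")
  if (!all(need %in% names(beta))) stopf("`beta` must name all of: %s",
                                         paste(need, collapse = ", "))
  if (!all(need %in% names(ref))) stopf("`ref` must name all of: %s",
                                        paste(need, collapse = ", "))
  check_psd <- function(m, d, nm) {
    if (!isTRUE(all.equal(m, t(m))) || nrow(m) != d ||
        min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stopf("`%s` must be a symmetric positive semidefinite %dx%d matrix",
            nm, d, d)
  }
  check_psd(Psi1, 2L, "Psi1"); check_psd(Psi2, 4L, "Psi2")
  if (sigma < 0) stopf("`sigma` must be >= 0")
  structure(list(mu = mu, beta = beta[need], ref = ref[need], Psi1 = Psi1,
                 Psi2 = Psi2, sigma = sigma,
                 spatial_surface = spatial_surface,
                 trend = trend, seed = as.integer(seed)),
            class = "truth_parameters")
}

#' Default deterministic spatial surface
#'
#' A smooth sinusoidal surface in normalised coordinates plus linear
#' contributions of forest and urban cover, centered to mean zero over the
#' rows it is evaluated on. The default amplitude gives regional offsets of
#' roughly +/- 15 micrograms/m3, the magnitude of the corrections the
#' residual smooth is meant to capture.
#'
#' @param amplitude peak of the sinusoidal component (micrograms/m3).
#' @param forest_coef,urban_coef linear coefficients on the cover fractions.
#' @return a function of a data frame with `lon`, `lat`, `forest_frac`,
#'   `urban_frac`.
#' @export
default_surface <- function(amplitude = 12, forest_coef = -12,
                            urban_coef = 10) {
  function(df) {
    xr <- range(df$lon); yr <- range(df$lat)
    x <- if (diff(xr) > 0) (df$lon - xr[1]) / diff(xr) else rep(0.5, nrow(df))
    y <- if (diff(yr) > 0) (df$lat - yr[1]) / diff(yr) else rep(0.5, nrow(df))
    s <- amplitude * sin(2 * pi * x) * cos(pi * y) +
      forest_coef * df$forest_frac + urban_coef * df$urban_frac
    s - mean(s)
  }
}

#' Retrieval scenario for the two AOD streams
#'
#' Describes how the DT-like (dark-target) and DB-like (deep-blue) retrieval
#' streams distort and subsample the true AOD field. Missingness is
#' land-type dependent: DT fails preferentially over bright (sparsely
#' vegetated) surfaces, DB over densely vegetated ones. The DB stream is
#' related to truth through a linear crosswalk
#' `DB = crosswalk_slope * truth + crosswalk_intercept + db_bias + noise`;
#' DT is `truth + dt_bias + noise`.
#'
#' @param dt_bias,db_bias additive AOD offsets.
#' @param dt_noise_sd,db_noise_sd retrieval noise standard deviations (> 0).
#' @param dt_missing,db_missing named vectors `c(bright=, vegetated=)` of
#'   per-cell-day missingness probabilities in `[0, 1]`.
#' @param crosswalk_slope,crosswalk_intercept linear DT-DB relation.
#' @param n_truth_stations number of ground reference (sun-photometer-like)
#'   stations.
#' @return list of class `retrieval_scenario`.
#' @export
retrieval_scenario <- function(
    dt_bias = 0.15, db_bias = 0,
    dt_noise_sd = 0.10, db_noise_sd = 0.12,
    dt_missing = c(bright = 0.70, vegetated = 0.35),
    db_missing = c(bright = 0.50, vegetated = 0.75),
    crosswalk_slope = 0.9, crosswalk_intercept = 0.08,
    n_truth_stations = 8L) {
  for (p in list(dt_missing, db_missing)) {
    if (!all(c("bright", "vegetated") %in% names(p)) ||
        any(p < 0) || any(p > 1))
      stopf("missingness must be named c(bright=, vegetated=) in [0, 1]")
  }
  if (dt_noise_sd < 0 || db_noise_sd < 0) stopf("noise SDs must be >= 0")
  structure(list(dt_bias = dt_bias, db_bias = db_bias,
                 dt_noise_sd = dt_noise_sd, db_noise_sd = db_noise_sd,
                 dt_missing = dt_missing, db_missing = db_missing,
                 crosswalk_slope = crosswalk_slope,
                 crosswalk_intercept = crosswalk_intercept,
                 n_truth_stations = as.integer(n_truth_stations)),
            class = "retrieval_scenario")
}

with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

field_to_tbl <- function(mat, grid, dates, value_name = "aod") {
  out <- tibble(
    cell_id = rep(grid$cell_id, times = length(dates)),
    date = rep(dates, each = nrow(grid))
  )
  out[[value_name]] <- as.vector(mat)
  out
}

# smooth daily fields with AR(1) persistence; returns n_cells x n_days matrix
# (cells in cell_id order) with marginal sd ~ `sd`.
daily_smooth_fields <- function(nr, nc, n_days, sd, sigma_cells, ar1 = 0.5) {
  out <- matrix(0, nr * nc, n_days)
  f <- smooth_field(nr, nc, sigma_cells)
  out[, 1L] <- as.vector(t(f))
  for (t in seq_len(n_days)[-1L]) {
    e <- smooth_field(nr, nc, sigma_cells)
    out[, t] <- ar1 * out[, t - 1L] + sqrt(1 - ar1^2) * as.vector(t(e))
  }
  out * sd
}

#' Simulate the true AOD field
#'
#' Log-normal AOD with a static spatial component, a day-to-day smooth
#' random field with AR(1) persistence, and a seasonal cycle peaking in
#' winter. All values are strictly positive and the field is a pure function
#' of `(grid, dates, seed)`.
#'
#' @param grid a `grid_spec`.
#' @param dates `Date` vector.
#' @param seed integer seed.
#' @param mean_log mean of log AOD.
#' @param seasonal_amp amplitude of the seasonal cycle on the log scale.
#' @param spatial_sd,daily_sd standard deviations of the static and daily
#'   log-scale components.
#' @param sigma_cells Gaussian smoothing width (in cells) of the random
#'   fields.
#' @param trend optional function of `Date` returning a domain-wide additive
#'   AOD offset, used to emulate multi-year emission trends that the
#'   downstream calibration should transfer into PM2.5.
#' @return tibble `cell_id`, `date`, `aod` (complete over cells x dates).
#' @export
simulate_true_aod <- function(grid, dates, seed,
                              mean_log = log(0.6), seasonal_amp = 0.3,
                              spatial_sd = 0.25, daily_sd = 0.3,
                              sigma_cells = 4, trend = NULL) {
  if (length(dates) < 1L) stopf("at least one date is required")
  nr <- attr(grid, "nrow"); nc <- attr(grid, "ncol")
  with_seed(seed, {
    static <- spatial_sd * as.vector(t(smooth_field(nr, nc, sigma_cells)))
    daily <- daily_smooth_fields(nr, nc, length(dates), daily_sd, sigma_cells)
    doy <- as.integer(format(dates, "%j"))
    seas <- seasonal_amp * cos(2 * pi * (doy - 15) / 365.25)
    lg <- mean_log + outer(static, rep(1, length(dates))) + daily +
      outer(rep(1, nrow(grid)), seas)
    aod <- exp(lg)
    if (!is.null(trend))
      aod <- pmax(0, aod + outer(rep(1, nrow(grid)), trend(dates)))
    field_to_tbl(aod, grid, dates)
  })
}

#' Simulate the two retrieval streams from the true AOD
#'
#' Applies the scenario's stream-specific bias, noise and land-type-dependent
#' missingness to the truth. Negative retrievals are clipped at 0.
#'
#' @param truth output of [simulate_true_aod()].
#' @param scenario a [retrieval_scenario()].
#' @param bright logical per-cell vector (indexed by `cell_id + 1`): `TRUE`
#'   for bright (sparsely vegetated) cells.
#' @param seed integer seed.
#' @return list with tibbles `dt` and `db` (`cell_id`, `date`, `aod`),
#'   containing only the retained (non-missing) cell-days.
#' @export
simulate_retrievals <- function(truth, scenario, bright, seed) {
  stopifnot(inherits(scenario, "retrieval_scenario"))
  br <- bright[truth$cell_id + 1L]
  with_seed(seed, {
    n <- nrow(truth)
    dt_val <- truth$aod + scenario$dt_bias + rnorm(n, 0, scenario$dt_noise_sd)
    db_val <- scenario$crosswalk_slope * truth$aod +
      scenario$crosswalk_intercept + scenario$db_bias +
      rnorm(n, 0, scenario$db_noise_sd)
    p_dt <- ifelse(br, scenario$dt_missing["bright"],
                   scenario$dt_missing["vegetated"])
    p_db <- ifelse(br, scenario$db_missing["bright"],
                   scenario$db_missing["vegetated"])
    keep_dt <- runif(n) >= p_dt
    keep_db <- runif(n) >= p_db
    list(
      dt = tibble(cell_id = truth$cell_id[keep_dt],
                  date = truth$date[keep_dt],
                  aod = pmax(0, dt_val[keep_dt])),
      db = tibble(cell_id = truth$cell_id[keep_db],
                  date = truth$date[keep_db],
                  aod = pmax(0, db_val[keep_db]))
    )
  })
}

#' Simulate meteorology, land cover, fires and reference AOD stations
#'
#' Meteorology is generated on a grid coarser than the analysis lattice
#' (exercising the IDW step) with smooth spatial structure, AR(1) daily
#' variation and seasonal cycles; one extra lead-in day is generated so the
#' lagged-precipitation covariate is defined on every requested date. Land
#' cover is a fine categorical raster (forest / urban / other) from which
#' per-cell fractions are tallied; cells with low vegetation are labelled
#' bright. Fire spots are sparse Poisson point events. Reference stations
#' report the true AOD plus small noise at a fixed set of cells.
#'
#' @param grid a `grid_spec`.
#' @param dates `Date` vector of study days.
#' @param seed integer seed.
#' @param truth_aod optional output of [simulate_true_aod()]; required for a
#'   non-empty station table.
#' @param landcover optional raster from a previous call, reused verbatim so
#'   that multi-year worlds share static land cover.
#' @param station_cells optional fixed station cell ids to reuse.
#' @param n_truth_stations number of reference stations.
#' @param met_factor coarse-grid coarsening factor (default 5, i.e. 0.5
#'   degrees for a 0.1-degree analysis grid).
#' @param raster_factor land-cover raster refinement factor (default 5).
#' @param station_noise_sd station AOD noise SD.
#' @param fire_rate mean domain-wide fire events per day.
#' @return list with `met_coarse`, `coarse_nodes`, `landcover`, `landuse`
#'   (per-cell `forest_frac`, `urban_frac`, `ndvi`, `bright`), `fires`,
#'   `truth_stations`, `station_cells`.
#' @export
simulate_covariates <- function(grid, dates, seed, truth_aod = NULL,
                                n_truth_stations = 8L, met_factor = 5L,
                                raster_factor = 5L, station_noise_sd = 0.02,
                                fire_rate = 2, landcover = NULL,
                                station_cells = NULL) {
  b <- attr(grid, "bounds"); res <- attr(grid, "resolution")
  dates_ext <- c(min(dates) - 1L, dates)
  # coarse met bounds padded out to whole coarse cells covering the grid
  cres <- res * met_factor
  cb <- c(b[1L], b[1L] + ceiling((b[2L] - b[1L]) / cres - 1e-9) * cres,
          b[3L], b[3L] + ceiling((b[4L] - b[3L]) / cres - 1e-9) * cres)
  coarse <- make_grid(cb, cres)
  ncr <- attr(coarse, "nrow"); ncc <- attr(coarse, "ncol")
  doy <- as.integer(format(dates_ext, "%j"))
  cyc <- function(amp, peak_doy) amp * cos(2 * pi * (doy - peak_doy) / 365.25)

  met_var <- function(base, seas, spatial_sd, daily_sd, lo = -Inf, hi = Inf) {
    static <- spatial_sd * as.vector(t(smooth_field(ncr, ncc, 1.5)))
    daily <- daily_smooth_fields(ncr, ncc, length(dates_ext), daily_sd, 1.5,
                                 ar1 = 0.6)
    v <- base + outer(static, rep(1, length(dates_ext))) + daily +
      outer(rep(1, nrow(coarse)), seas)
    pmin(pmax(v, lo), hi)
  }

  with_seed(seed, {
    ws <- met_var(3, cyc(0.5, 105), 0.5, 1.2, lo = 0.1)
    pblh <- met_var(8, cyc(2, 196), 1.0, 2.0, lo = 0.5)
    ps <- met_var(1000, cyc(5, 15), 3.0, 4.0)
    rh <- met_var(60, cyc(10, 196), 5.0, 8.0, lo = 5, hi = 100)
    z <- met_var(-1, cyc(0.8, 196), 0.5, 1.5)
    precip <- pmax(0, z) * 4

    met_coarse <- tibble(
      node_id = rep(coarse$cell_id, times = length(dates_ext)),
      lat = rep(coarse$lat, times = length(dates_ext)),
      lon = rep(coarse$lon, times = length(dates_ext)),
      date = rep(dates_ext, each = nrow(coarse)),
      WS = as.vector(ws), PBLH = as.vector(pblh), PS = as.vector(ps),
      RH_PBLH = as.vector(rh), Precip = as.vector(precip)
    )

    # land cover raster: two smooth scores -> forest / urban / other classes
    # (static: a supplied raster is reused so multi-year worlds share it)
    if (is.null(landcover)) {
      rnr <- attr(grid, "nrow") * raster_factor
      rnc <- attr(grid, "ncol") * raster_factor
      rres <- res / raster_factor
      f1 <- smooth_field(rnr, rnc, 1.5 * raster_factor)
      f2 <- smooth_field(rnr, rnc, 1.0 * raster_factor)
      cls <- matrix("other", rnr, rnc)
      cls[f1 > 0.25] <- "forest"
      cls[f1 <= 0.25 & f2 > 1.0] <- "urban"
      landcover <- tibble(
        lat = b[1L] + (rep(0:(rnr - 1L), each = rnc) + 0.5) * rres,
        lon = b[3L] + (rep(0:(rnc - 1L), times = rnr) + 0.5) * rres,
        class = as.vector(t(cls))
      )
    }
    lu <- landuse_fractions(landcover, grid)
    landuse <- tibble(
      cell_id = lu$cell_id,
      forest_frac = lu$forest_frac,
      urban_frac = lu$urban_frac,
      ndvi = 0.08 + 0.6 * lu$forest_frac,
      bright = lu$forest_frac < 0.2
    )

    # sparse fire events, peaking in spring
    lam <- fire_rate * (1 + 0.8 * cos(2 * pi * (doy[-1L] - 105) / 365.25))
    n_ev <- rpois(length(dates), lam)
    fires <- tibble(
      date = rep(dates, times = n_ev),
      lat = runif(sum(n_ev), b[1L], b[2L]),
      lon = runif(sum(n_ev), b[3L], b[4L])
    )

    if (is.null(station_cells))
      station_cells <- sort(sample(grid$cell_id, n_truth_stations))
    truth_stations <- if (is.null(truth_aod)) {
      tibble(station_id = integer(), cell_id = integer(),
             date = as.Date(character()), aod = numeric())
    } else {
      st <- truth_aod[truth_aod$cell_id %in% station_cells, ]
      tibble(station_id = match(st$cell_id, station_cells),
             cell_id = st$cell_id, date = st$date,
             aod = pmax(0, st$aod + rnorm(nrow(st), 0, station_noise_sd)))
    }

    list(met_coarse = met_coarse, coarse_nodes = as_tibble(coarse),
         landcover = landcover, landuse = landuse, fires = fires,
         truth_stations = truth_stations, station_cells = station_cells)
  })
}

#' Draw day-specific random effects
#'
#' One (intercept, AOD slope) pair per calendar month-day present in
#' `dates`, drawn from `N(0, Psi1)`.
#'
#' @param dates `Date` vector.
#' @param Psi1 2x2 covariance matrix.
#' @param seed integer seed.
#' @return tibble `day_key`, `re_intercept`, `re_aod`.
#' @export
make_day_effects <- function(dates, Psi1, seed) {
  keys <- sort(unique(day_key(dates)))
  with_seed(seed, {
    L <- chol_psd(Psi1)
    z <- matrix(rnorm(2L * length(keys)), ncol = 2L) %*% t(L)
    tibble(day_key = keys, re_intercept = z[, 1L], re_aod = z[, 2L])
  })
}

#' Draw season-specific random meteorology slopes
#' @param Psi2 4x4 covariance matrix (order WS, PBLH, PS, RH_PBLH).
#' @param seed integer seed.
#' @return tibble `season`, `re_WS`, `re_PBLH`, `re_PS`, `re_RH_PBLH`.
#' @export
make_season_effects <- function(Psi2, seed) {
  with_seed(seed, {
    L <- chol_psd(Psi2)
    z <- matrix(rnorm(4L * 4L), ncol = 4L) %*% t(L)
    tibble(season = SEASONS, re_WS = z[, 1L], re_PBLH = z[, 2L],
           re_PS = z[, 3L], re_RH_PBLH = z[, 4L])
  })
}

chol_psd <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(m)) %*% t(e$vectors)
}

#' Generate PM2.5 from the two-stage generative model
#'
#' The linear predictor combines the fixed intercept and slopes (applied to
#' covariates centered at the reference levels `params$ref`) with the
#' day-specific random intercept/AOD slope, the season-specific meteorology
#' slopes, iid residual noise, the deterministic spatial surface and the
#' optional trend. Negative totals are truncated at 0 and flagged.
#'
#' @param truth_aod tibble `cell_id`, `date`, `aod` (the AOD entering the
#'   linear predictor).
#' @param covariates per-cell-day covariate table with `cell_id`, `date`,
#'   `WS`, `PBLH`, `PS`, `RH_PBLH`, `Precip_Lag1`, `Fire_spots`,
#'   `forest_frac`, `urban_frac`, `lon`, `lat`. Every cell-day of
#'   `truth_aod` must be present.
#' @param params a [truth_parameters()] object.
#' @param seed integer seed for the residual noise (and for effects not
#'   supplied).
#' @param day_effects optional tibble from [make_day_effects()]; drawn from
#'   `params$Psi1` when `NULL`. Supplying the model-year table reproduces
#'   the constant same-day-of-year regime; a fresh draw emulates a year
#'   whose daily relationships differ.
#' @param season_effects optional tibble from [make_season_effects()].
#' @return list with `pm` (tibble `cell_id`, `date`, `pm25`, `truncated`),
#'   `day_effects`, `season_effects`.
#' @export
simulate_pm25 <- function(truth_aod, covariates, params, seed,
                          day_effects = NULL, season_effects = NULL) {
  stopifnot(inherits(params, "truth_parameters"))
  df <- dplyr::left_join(truth_aod, covariates, by = c("cell_id", "date"))
  need <- c("WS", "PBLH", "PS", "RH_PBLH", "Precip_Lag1", "Fire_spots",
            "forest_frac", "urban_frac", "lon", "lat")
  if (!all(need %in% names(df)) || anyNA(df[need]))
    stopf("inconsistent input: covariates missing for some cell-days")
  if (is.null(day_effects))
    day_effects <- make_day_effects(df$date, params$Psi1, seed + 101L)
  if (is.null(season_effects))
    season_effects <- make_season_effects(params$Psi2, seed + 102L)

  df$day_key <- day_key(df$date)
  df$season <- season_of(df$date)
  df <- df |>
    dplyr::left_join(day_effects, by = "day_key") |>
    dplyr::left_join(season_effects, by = "season")
  df$re_intercept[is.na(df$re_intercept)] <- 0
  df$re_aod[is.na(df$re_aod)] <- 0

  b <- params$beta; rf <- params$ref
  lp <- params$mu + df$re_intercept +
    (b[["AOD"]] + df$re_aod) * (df$aod - rf[["AOD"]]) +
    (b[["WS"]] + df$re_WS) * (df$WS - rf[["WS"]]) +
    (b[["PBLH"]] + df$re_PBLH) * (df$PBLH - rf[["PBLH"]]) +
    (b[["PS"]] + df$re_PS) * (df$PS - rf[["PS"]]) +
    (b[["RH_PBLH"]] + df$re_RH_PBLH) * (df$RH_PBLH - rf[["RH_PBLH"]]) +
    b[["Precip_Lag1"]] * (df$Precip_Lag1 - rf[["Precip_Lag1"]]) +
    b[["Fire_spots"]] * (df$Fire_spots - rf[["Fire_spots"]])

  if (!is.null(params$spatial_surface))
    lp <- lp + params$spatial_surface(df)

  tr <- params$trend
  if (is.function(tr)) {
    lp <- lp + tr(df$date)
  } else if (any(tr != 0)) {
    slope <- if (length(tr) == 1L) rep(tr, max(df$cell_id) + 1L) else tr
    t0 <- year_fraction(min(df$date))
    lp <- lp + slope[df$cell_id + 1L] * (year_fraction(df$date) - t0)
  }

  noise <- with_seed(seed, rnorm(nrow(df), 0, params$sigma))
  raw <- lp + noise
  list(
    pm = tibble(cell_id = df$cell_id, date = df$date,
                pm25 = pmax(0, raw), truncated = raw < 0),
    day_effects = day_effects,
    season_effects = season_effects
  )
}

#' Choose monitor cells, dense in the eastern regions
#'
#' Regions are ranked by mean centroid longitude; `n_east` monitor cells are
#' sampled from the two easternmost regions and `n_other` from the rest,
#' mimicking a network dense on one side of the domain and sparse elsewhere.
#'
#' @param grid a `grid_spec`.
#' @param n_east,n_other monitor cell counts.
#' @param seed integer seed.
#' @return sorted integer vector of cell ids.
#' @export
choose_monitor_cells <- function(grid, n_east = 45L, n_other = 15L, seed = 1L) {
  mean_lon <- tapply(grid$lon, grid$region, mean)
  east <- names(sort(mean_lon, decreasing = TRUE))[seq_len(min(2L,
                                                               length(mean_lon)))]
  east_cells <- grid$cell_id[grid$region %in% east]
  other_cells <- grid$cell_id[!grid$region %in% east]
  with_seed(seed, {
    picked <- c(sample(east_cells, min(n_east, length(east_cells))),
                if (length(other_cells) > 0L)
                  sample(other_cells, min(n_other, length(other_cells))))
    sort(picked)
  })
}

#' Generate a complete synthetic study world
#'
#' Orchestrates the full generative pipeline: analysis grid, true AOD, two
#' retrieval streams, meteorology (IDW-interpolated to the grid), land use,
#' fire buffers, reference AOD stations, ground-truth PM2.5 and a monitor
#' network. The default configuration is a 40x40-cell 0.1-degree lattice
#' with 4 regions, 365 days, 60 monitor cells (45 in the two eastern
#' regions, 15 elsewhere) and 8 reference stations.
#'
#' @param grid a `grid_spec` (default 40x40, 4 regions).
#' @param dates `Date` vector (default calendar year 2013).
#' @param params a [truth_parameters()].
#' @param scenario a [retrieval_scenario()].
#' @param seed master seed (defaults to `params$seed`); sub-stage seeds are
#'   small fixed offsets from it.
#' @param n_monitors_east,n_monitors_other monitor network size.
#' @param day_effects,season_effects optional effect tables to re-use (see
#'   [simulate_pm25()]).
#' @param aod_for_pm which AOD enters the generative linear predictor:
#'   `"truth"` (default) or a tibble (`cell_id`, `date`, `aod`) to use
#'   instead.
#' @param base_world optional `synthetic_world` whose static structure
#'   (grid, land cover, reference stations, monitor network, parameters,
#'   scenario) is reused; only the time-varying fields are regenerated,
#'   emulating a different year of the same study domain. Day and season
#'   effects are re-drawn unless passed explicitly.
#' @param aod_trend optional AOD trend function, see [simulate_true_aod()].
#' @return list of class `synthetic_world` with elements `grid`, `dates`,
#'   `truth_aod`, `dt`, `db`, `covariates` (the [simulate_covariates()]
#'   list), `met_fine`, `fire_counts`, `cov_table`, `pm_truth`, `monitors`,
#'   `monitor_cells`, `day_effects`, `season_effects`, `params`, `scenario`.
#' @export
simulate_world <- function(grid = make_grid(c(30, 34, 110, 114), 0.1, 4L),
                           dates = seq(as.Date("2013-01-01"),
                                       as.Date("2013-12-31"), by = "day"),
                           params = truth_parameters(),
                           scenario = retrieval_scenario(),
                           seed = params$seed,
                           n_monitors_east = 45L, n_monitors_other = 15L,
                           day_effects = NULL, season_effects = NULL,
                           aod_for_pm = "truth", base_world = NULL,
                           aod_trend = NULL) {
  if (!is.null(base_world)) {
    stopifnot(inherits(base_world, "synthetic_world"))
    grid <- base_world$grid
    params <- base_world$params
    scenario <- base_world$scenario
  }
  truth_aod <- simulate_true_aod(grid, dates, seed + 1L, trend = aod_trend)
  cov <- simulate_covariates(
    grid, dates, seed + 2L, truth_aod,
    n_truth_stations = scenario$n_truth_stations,
    landcover = base_world$covariates$landcover,
    station_cells = base_world$covariates$station_cells)
  retr <- simulate_retrievals(truth_aod, scenario, cov$landuse$bright,
                              seed + 3L)
  met_fine <- interpolate_met(cov$met_coarse, grid)
  met_fine <- met_fine[met_fine$date %in% dates, ]
  fire_counts <- buffer_fire_counts(cov$fires, grid, 75, dates = dates)
  cov_table <- met_fine |>
    dplyr::inner_join(dplyr::rename(fire_counts, Fire_spots = "count"),
                      by = c("cell_id", "date")) |>
    dplyr::inner_join(
      dplyr::select(cov$landuse, "cell_id", "forest_frac", "urban_frac"),
      by = "cell_id") |>
    dplyr::inner_join(dplyr::select(grid, "cell_id", "lon", "lat"),
                      by = "cell_id")

  aod_pm <- if (identical(aod_for_pm, "truth")) truth_aod else aod_for_pm
  sim <- simulate_pm25(aod_pm, cov_table, params, seed + 4L,
                       day_effects = day_effects,
                       season_effects = season_effects)
  monitor_cells <- if (!is.null(base_world)) base_world$monitor_cells else
    choose_monitor_cells(grid, n_monitors_east, n_monitors_other, seed + 5L)
  monitors <- sim$pm[sim$pm$cell_id %in% monitor_cells,
                     c("cell_id", "date", "pm25")]
  monitors <- tibble(site_id = paste0("S", match(monitors$cell_id,
                                                 monitor_cells)),
                     monitors)

  structure(list(grid = grid, dates = dates, truth_aod = truth_aod,
                 dt = retr$dt, db = retr$db, covariates = cov,
                 met_fine = met_fine, fire_counts = fire_counts,
                 cov_table = cov_table, pm_truth = sim$pm,
                 monitors = monitors, monitor_cells = monitor_cells,
                 day_effects = sim$day_effects,
                 season_effects = sim$season_effects,
                 params = params, scenario = scenario, seed = seed),
            class = "synthetic_world")
}
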