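# Shared synthetic worlds, built once per test run.

.world_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .world_cache))
    assign(key, force(expr), envir = .world_cache)
  get(key, envir = .world_cache)
}

# Small multi-region world: 12x12 cells, 4 regions, 120 days, 22 monitors.
small_world <- function() {
  cached("small_world", {
    g <- make_grid(c(30, 31.2, 110, 111.2), 0.1, 4L)
    simulate_world(
      grid = g,
      dates = seq(as.Date("2013-01-01"), as.Date("2013-04-30"), by = "day"),
      seed = 101L, n_monitors_east = 16L, n_monitors_other = 6L)
  })
}

# Fusion products on the small world.
small_fusion <- function() {
  cached("small_fusion", {
    w <- small_world()
    fuse_aod(w$dt, w$db, w$covariates$truth_stations)
  })
}

# Assembled tables for the small world (fit on combined AOD).
small_tables <- function() {
  cached("small_tables", {
    w <- small_world()
    comb <- small_fusion()$combined
    assemble_tables(comb[, c("cell_id", "date", "aod")], w$met_fine,
                    w$fire_counts, w$covariates$landuse, w$monitors, w$grid)
  })
}

# Two-stage fit on the small world (reduced buffer thresholds to match size).
small_fit <- function() {
  cached("small_fit", {
    suppressMessages(
      fit_two_stage(small_tables()$fitting, small_world()$grid,
                    min_records = 400L, min_days = 60L))
  })
}

# Parameter-recovery world: single region, truth AOD as fitted covariate,
# no spatial surface — the stage-1 generative model exactly.
recovery_world <- function(seed, n_days = 365L, n_monitors = 32L) {
  g <- make_grid(c(30, 32, 110, 112), 0.1, 1L)
  params <- truth_parameters(spatial_surface = NULL)
  dates <- seq(as.Date("2013-01-01"), by = "day", length.out = n_days)
  w <- simulate_world(grid = g, dates = dates, params = params, seed = seed,
                      n_monitors_east = n_monitors, n_monitors_other = 0L)
  tabs <- assemble_tables(w$truth_aod, w$met_fine, w$fire_counts,
                          w$covariates$landuse, w$monitors, g)
  list(world = w, tables = tabs, params = params)
}

expect_tbl_equal <- function(a, b, tol = 1e-12) {
  a <- as.data.frame(a)[do.call(order, as.data.frame(a)), , drop = FALSE]
  b <- as.data.frame(b)[do.call(order, as.data.frame(b)), , drop = FALSE]
  rownames(a) <- NULL; rownames(b) <- NULL
  expect_equal(a, b, tolerance = tol, ignore_attr = TRUE)
}
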