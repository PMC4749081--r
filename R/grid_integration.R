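#' Assign point-valued AOD pixels to grid cells (Thiessen rule)
#'
#' Each cell takes, per day, the value of the pixel whose Thiessen polygon
#' contains the cell centroid — equivalently the pixel with the nearest
#' centroid (planar distance in degrees at this scale). Days with no pixels
#' yield no rows for that day.
#'
#' @param pixels tibble with columns `date`, `lat`, `lon`, `value`.
#' @param grid a [make_grid()] `grid_spec`.
#' @param max_dist optional maximum centroid distance in degrees beyond which
#'   a cell is left missing (default `Inf`).
#' @return tibble `cell_id`, `date`, `value` (one row per cell-day assigned).
#' @export
assign_pixels_to_cells <- function(pixels, grid, max_dist = Inf) {
  stopifnot(all(c("date", "lat", "lon", "value") %in% names(pixels)))
  if (nrow(pixels) == 0L)
    return(tibble(cell_id = integer(), date = as.Date(character()),
                  value = numeric()))
  out <- lapply(split(pixels, pixels$date), function(px) {
    # squared planar distance from every cell centroid to every pixel
    d2 <- outer(grid$lat, px$lat, "-")^2 + outer(grid$lon, px$lon, "-")^2
    j <- max.col(-d2, ties.method = "first")
    dmin <- sqrt(d2[cbind(seq_len(nrow(d2)), j)])
    keep <- dmin <= max_dist
    tibble(cell_id = grid$cell_id[keep], date = px$date[1L],
           value = px$value[j][keep])
  })
  dplyr::bind_rows(out) |> dplyr::arrange(.data$date, .data$cell_id)
}

#' Inverse distance weighted interpolation to target points
#'
#' Interpolates values at scattered nodes to target coordinates using
#' inverse-distance weights \eqn{w_i = d_i^{-p}} over the `k` nearest nodes.
#' A target coinciding with a node returns that node's value exactly. The
#' output is a convex combination of node values, so it never exceeds the
#' input extrema.
#'
#' @param nodes tibble with `lat`, `lon` of the coarse nodes.
#' @param values numeric vector (length `nrow(nodes)`) or matrix with one row
#'   per node; each column is interpolated independently (e.g. one per day).
#' @param targets tibble with `lat`, `lon` of the target points.
#' @param power IDW exponent (default 2).
#' @param k number of nearest nodes used (default 4; capped at the node count).
#' @return numeric vector or matrix with one row per target.
#' @export
idw_interpolate <- function(nodes, values, targets, power = 2, k = 4L) {
  if (nrow(nodes) < 1L) stopf("at least one node is required")
  vmat <- if (is.matrix(values)) values else matrix(values, ncol = 1L)
  if (nrow(vmat) != nrow(nodes)) stopf("`values` must have one row per node")
  k <- min(k, nrow(nodes))
  d <- sqrt(outer(targets$lat, nodes$lat, "-")^2 +
              outer(targets$lon, nodes$lon, "-")^2)
  n_t <- nrow(targets)
  W <- matrix(0, n_t, nrow(nodes))
  for (i in seq_len(n_t)) {
    ord <- order(d[i, ])[seq_len(k)]
    di <- d[i, ord]
    if (di[1L] == 0) {
      W[i, ord[1L]] <- 1
    } else {
      w <- di^(-power)
      W[i, ord] <- w / sum(w)
    }
  }
  out <- W %*% vmat
  if (is.matrix(values)) out else drop(out)
}

#' Count point events within a great-circle buffer of each cell centroid
#'
#' Counts, per day, the events (e.g. satellite-detected fire spots) whose
#' great-circle distance (haversine, spherical Earth R = 6371 km) from the
#' cell centroid is at most `radius_km`.
#'
#' @param events tibble with `date`, `lat`, `lon` (one row per event).
#' @param grid a `grid_spec`.
#' @param radius_km buffer radius in kilometres (default 75).
#' @param dates optional `Date` vector of days to report (defaults to the
#'   event days); days without events get count 0.
#' @return tibble `cell_id`, `date`, `count` (complete over cells x dates).
#' @export
buffer_fire_counts <- function(events, grid, radius_km = 75, dates = NULL) {
  if (radius_km <= 0) stopf("`radius_km` must be positive")
  dates <- sort(unique(c(as.Date(dates %||% events$date))))
  cells <- cbind(grid$lon, grid$lat)
  per_day <- lapply(dates, function(d) {
    ev <- events[events$date == d, , drop = FALSE]
    cnt <- integer(nrow(grid))
    for (i in seq_len(nrow(ev))) {
      dist_m <- geosphere::distHaversine(cells, c(ev$lon[i], ev$lat[i]),
                                         r = 6371000)
      cnt <- cnt + as.integer(dist_m <= radius_km * 1000)
    }
    tibble(cell_id = grid$cell_id, date = d, count = cnt)
  })
  dplyr::bind_rows(per_day)
}

#' Forest and urban fractions per grid cell from a categorical raster
#'
#' Tallies the fraction of raster pixels of class `"forest"` and `"urban"`
#' whose centres fall in each cell. Cells containing no raster pixel get
#' `NA` fractions and are flagged.
#'
#' @param landcover tibble with `lat`, `lon`, `class` (character; classes
#'   other than `"forest"`/`"urban"` count only toward the denominator).
#' @param grid a `grid_spec`.
#' @return tibble `cell_id`, `forest_frac`, `urban_frac`, `n_pixels`,
#'   `undefined` (logical).
#' @export
landuse_fractions <- function(landcover, grid) {
  cid <- cell_of_point(grid, landcover$lat, landcover$lon)
  ok <- !is.na(cid)
  tab <- tibble(cell_id = cid[ok], class = landcover$class[ok]) |>
    dplyr::count(.data$cell_id, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
  for (cl in c("forest", "urban"))
    if (!cl %in% names(tab)) tab[[cl]] <- 0L
  tab$n_pixels <- rowSums(tab[setdiff(names(tab), "cell_id")])
  out <- dplyr::left_join(grid[, "cell_id"], tab, by = "cell_id")
  out$n_pixels[is.na(out$n_pixels)] <- 0L
  tibble(
    cell_id = out$cell_id,
    forest_frac = ifelse(out$n_pixels > 0, out$forest / out$n_pixels, NA_real_),
    urban_frac = ifelse(out$n_pixels > 0, out$urban / out$n_pixels, NA_real_),
    n_pixels = out$n_pixels,
    undefined = out$n_pixels == 0L
  )
}

#' Interpolate coarse meteorology to the analysis grid
#'
#' Applies [idw_interpolate()] per variable and day, and derives
#' `Precip_Lag1` as the previous calendar day's accumulated precipitation.
#' Days whose previous day is absent from the coarse record get `NA` lagged
#' precipitation.
#'
#' @param met_coarse long tibble `node_id`, `lat`, `lon`, `date`, plus the
#'   variable columns `WS`, `PBLH`, `PS`, `RH_PBLH`, `Precip`.
#' @param grid a `grid_spec`.
#' @param power,k IDW parameters, see [idw_interpolate()].
#' @return tibble `cell_id`, `date`, `WS`, `PBLH`, `PS`, `RH_PBLH`,
#'   `Precip`, `Precip_Lag1`.
#' @export
interpolate_met <- function(met_coarse, grid, power = 2, k = 4L) {
  vars <- c("WS", "PBLH", "PS", "RH_PBLH", "Precip")
  stopifnot(all(c("node_id", "lat", "lon", "date", vars) %in%
                  names(met_coarse)))
  nodes <- met_coarse |>
    dplyr::distinct(.data$node_id, .data$lat, .data$lon) |>
    dplyr::arrange(.data$node_id)
  dates <- sort(unique(met_coarse$date))
  ord <- order(met_coarse$date, met_coarse$node_id)
  mc <- met_coarse[ord, ]
  n_nodes <- nrow(nodes)
  out <- tibble(
    cell_id = rep(grid$cell_id, times = length(dates)),
    date = rep(dates, each = nrow(grid))
  )
  for (v in vars) {
    vm <- matrix(mc[[v]], nrow = n_nodes, ncol = length(dates))
    fine <- idw_interpolate(nodes, vm, grid, power = power, k = k)
    out[[v]] <- as.vector(fine)
  }
  prev <- out[, c("cell_id", "date", "Precip")]
  prev$date <- prev$date + 1L
  names(prev)[3L] <- "Precip_Lag1"
  dplyr::left_join(out, prev, by = c("cell_id", "date"))
}

#' Assemble fitting and prediction tables
#'
#' Joins AOD, meteorology, fire counts and land use by cell-day; attaches
#' monitor PM2.5 (multiple monitors in a cell averaged); keeps complete
#' cases only; and centers every covariate on its fitting-set mean. The same
#' centering constants are applied to prediction rows, and can be supplied
#' to assemble prediction-only tables for other years.
#'
#' @param aod combined-AOD tibble `cell_id`, `date`, `aod`.
#' @param met output of [interpolate_met()].
#' @param fires output of [buffer_fire_counts()].
#' @param landuse output of [landuse_fractions()] (or any tibble with
#'   `cell_id`, `forest_frac`, `urban_frac`).
#' @param monitors tibble `site_id`, `cell_id`, `date`, `pm25`, or `NULL`
#'   for a prediction-only assembly (then `centering` must be supplied).
#' @param grid a `grid_spec`.
#' @param centering optional named numeric vector of covariate means from a
#'   previous assembly; computed from the fitting rows when `NULL`.
#' @return list with `fitting` (rows with observed PM2.5 and all covariates),
#'   `prediction` (all complete-covariate cell-days), and `centering`
#'   (named means used). Both tables carry centered covariates plus `pm25`
#'   (raw, `NA` in prediction-only rows), `doy`, `season`, `day_key`,
#'   `region`, `lon`, `lat`.
#' @export
assemble_tables <- function(aod, met, fires, landuse, monitors, grid,
                            centering = NULL) {
  covars <- c("AOD", "WS", "PBLH", "PS", "RH_PBLH", "Precip_Lag1",
              "Fire_spots")
  base <- aod |>
    dplyr::rename(AOD = "aod") |>
    dplyr::inner_join(met, by = c("cell_id", "date")) |>
    dplyr::inner_join(dplyr::rename(fires, Fire_spots = "count"),
                      by = c("cell_id", "date")) |>
    dplyr::inner_join(
      dplyr::select(landuse, "cell_id", "forest_frac", "urban_frac"),
      by = "cell_id") |>
    dplyr::inner_join(
      dplyr::select(grid, "cell_id", "lon", "lat", "region"),
      by = "cell_id")
  base <- base[complete.cases(base[, c(covars, "forest_frac", "urban_frac")]), ]
  base$doy <- as.integer(format(base$date, "%j"))
  base$season <- season_of(base$date)
  base$day_key <- day_key(base$date)

  if (!is.null(monitors)) {
    pm <- monitors |>
      dplyr::group_by(.data$cell_id, .data$date) |>
      dplyr::summarise(pm25 = mean(.data$pm25), .groups = "drop")
    base <- dplyr::left_join(base, pm, by = c("cell_id", "date"))
  } else {
    if (is.null(centering))
      stopf("`centering` must be supplied for a prediction-only assembly")
    base$pm25 <- NA_real_
  }

  fitting <- base[!is.na(base$pm25), ]
  if (is.null(centering)) {
    if (nrow(fitting) == 0L)
      stopf("empty fitting table: no cell-day has both PM2.5 and covariates")
    centering <- vapply(fitting[covars], mean, numeric(1))
  }
  for (v in covars) {
    base[[v]] <- base[[v]] - centering[[v]]
  }
  fitting <- base[!is.na(base$pm25), ]
  list(fitting = as_tibble(fitting), prediction = as_tibble(base),
       centering = centering)
}
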