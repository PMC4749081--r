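# Plain-text serialization: gridded fields as long-format CSV, truth
# parameters as a JSON sidecar usable as a test oracle.

#' Read or write a gridded AOD/PM field as long-format CSV
#'
#' Columns `cell_id`, `date` (ISO-8601) and one value column; missing
#' cell-days are simply absent rows.
#'
#' @param field tibble with `cell_id`, `date` and a value column.
#' @param path file path.
#' @return `read_field_csv` returns a tibble with `date` parsed as `Date`.
#' @export
write_field_csv <- function(field, path) {
  utils::write.csv(field, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  x <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if ("date" %in% names(x)) x$date <- as.Date(x$date)
  x
}

#' Write a synthetic world to a directory of plain-text files
#'
#' Writes `monitors.csv`, the truth/DT/DB AOD fields, coarse meteorology,
#' land use, fires and the grid as CSV, and echoes the truth parameters to
#' `params.json` so downstream tests can recover the generative values.
#'
#' @param world a [simulate_world()] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_field_csv(world$monitors, p("monitors.csv"))
  write_field_csv(world$truth_aod, p("aod_truth.csv"))
  write_field_csv(world$dt, p("aod_dt.csv"))
  write_field_csv(world$db, p("aod_db.csv"))
  write_field_csv(world$covariates$met_coarse, p("met_coarse.csv"))
  write_field_csv(world$covariates$landuse, p("landuse.csv"))
  write_field_csv(world$covariates$fires, p("fires.csv"))
  write_field_csv(world$covariates$truth_stations, p("truth_stations.csv"))
  write_field_csv(as_tibble(world$grid), p("grid.csv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    pr <- world$params
    jsonlite::write_json(
      list(mu = pr$mu, beta = as.list(pr$beta), Psi1 = pr$Psi1,
           Psi2 = pr$Psi2, sigma = pr$sigma, seed = world$seed),
      p("params.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
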