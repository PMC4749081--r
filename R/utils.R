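#' Meteorological season of a date
#'
#' Seasons follow the meteorological convention: DJF (winter), MAM (spring),
#' JJA (summer), SON (autumn), assigned by calendar month.
#'
#' @param date a `Date` vector.
#' @return character vector with levels `"DJF"`, `"MAM"`, `"JJA"`, `"SON"`.
#' @export
season_of <- function(date) {
  m <- as.integer(format(date, "%m"))
  c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
    "JJA", "JJA", "SON", "SON", "SON", "DJF")[m]
}

#' Season-year label (December rolls into the following winter)
#'
#' For seasonal aggregation a December belongs to the winter of the following
#' calendar year, so that DJF is a contiguous block.
#'
#' @param date a `Date` vector.
#' @return integer vector of season years.
#' @export
season_year <- function(date) {
  y <- as.integer(format(date, "%Y"))
  ifelse(as.integer(format(date, "%m")) == 12L, y + 1L, y)
}

SEASONS <- c("DJF", "MAM", "JJA", "SON")

#' Calendar month-day key used to transfer day-specific effects across years
#'
#' Day-specific random effects fitted in the model year are re-used in other
#' years by matching the calendar month and day; February 29 maps to
#' February 28.
#'
#' @param date a `Date` vector.
#' @return character vector like `"03-15"`.
#' @export
day_key <- function(date) {
  k <- format(date, "%m-%d")
  k[k == "02-29"] <- "02-28"
  k
}

#' Fractional year of a date (used as the trend time axis)
#' @param date a `Date` vector.
#' @return numeric years, e.g. 2013.492.
#' @export
year_fraction <- function(date) {
  y <- as.integer(format(date, "%Y"))
  start <- as.Date(paste0(y, "-01-01"))
  len <- as.numeric(as.Date(paste0(y + 1L, "-01-01")) - start)
  y + as.numeric(date - start) / len
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Gaussian low-pass filter of a matrix, used to turn white noise into a
# smooth random field. Separable kernel, reflected edges.
gauss_smooth_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  smooth_vec <- function(v) {
    n <- length(v)
    idx <- c(rev(seq_len(min(half, n))), seq_len(n),
             rev(n + 1L - seq_len(min(half, n))))
    # if the vector is shorter than the pad, recycle reflection
    while (length(idx) < n + 2L * half) idx <- c(idx[1L], idx, idx[length(idx)])
    padded <- v[idx]
    out <- stats::filter(padded, k, sides = 2)
    out[(half + 1L):(half + n)]
  }
  m2 <- apply(m, 2L, smooth_vec)
  t(apply(m2, 1L, smooth_vec))
}

# Smooth mean-zero unit-variance random field on an nr x nc lattice.
smooth_field <- function(nr, nc, sigma_cells) {
  f <- gauss_smooth_matrix(matrix(rnorm(nr * nc), nr, nc), sigma_cells)
  f <- f - mean(f)
  s <- sd(as.vector(f))
  if (s > 0) f <- f / s
  f
}
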