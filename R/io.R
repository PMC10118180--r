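#' Write a curve series to CSV
#'
#' Schema: header `x,t=<t1>,t=<t2>,...`; first column the x-grid, one column
#' per curve in the order of `t_values`. Values are rendered with 17
#' significant digits so that `read_series(write_series(s))` round-trips
#' bit-exactly.
#'
#' @param series a [curve_series()].
#' @param path output file path.
#' @param digits significant digits for rendering (default 17, the full
#'   precision of a double).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, digits = 17) {
  stopifnot(inherits(series, "curve_series"))
  fmt <- sprintf("%%.%dg", as.integer(digits))
  header <- paste(c("x", sprintf("t=%s", sprintf(fmt, series$t_values))),
                  collapse = ",")
  body <- cbind(sprintf(fmt, unclass(series$grid)),
                matrix(sprintf(fmt, t(series$intensities)),
                       nrow = length(series$grid)))
  lines <- c(header, apply(body, 1L, paste, collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a curve series from CSV
#'
#' Inverse of [write_series()]: expects the `x,t=...` header schema and
#' returns the series in row-per-curve orientation.
#'
#' @param path input file path.
#' @return A [curve_series()].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_series: file not found: %s", path), call. = FALSE)
  }
  tab <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "numeric")
  cn <- names(tab)
  if (length(cn) < 2L || cn[1] != "x") {
    stop("read_series: first column must be named 'x'", call. = FALSE)
  }
  bad <- cn[-1][!grepl("^t=", cn[-1])]
  if (length(bad) > 0L) {
    stop(sprintf("read_series: column '%s' lacks the 't=' prefix", bad[1]),
         call. = FALSE)
  }
  t_values <- as.numeric(sub("^t=", "", cn[-1]))
  if (any(is.na(t_values))) {
    stop("read_series: non-numeric t value in header", call. = FALSE)
  }
  x <- tab[[1]]
  if (any(diff(x) <= 0)) {
    stop("read_series: x column must be strictly increasing", call. = FALSE)
  }
  curve_series(curve_grid(x), t_values,
               t(as.matrix(tab[, -1, drop = FALSE])))
}

#' Write a correlation or phase map to CSV
#'
#' Square CSV with the x-grid values as first row header and first column,
#' full (17-significant-digit) precision.
#'
#' @param map a square numeric matrix (e.g. the `synchronous` slot of a
#'   `correlation_maps` object, or a `phase_angle_map`'s `theta`).
#' @param grid the [curve_grid()] labelling rows and columns.
#' @param path output file path.
#' @param digits significant digits (default 17).
#' @return `path`, invisibly.
#' @export
write_map <- function(map, grid, path, digits = 17) {
  stopifnot(is.matrix(map), nrow(map) == ncol(map))
  if (!inherits(grid, "curve_grid")) grid <- curve_grid(grid)
  if (nrow(map) != length(grid)) {
    stop("write_map: map size must match grid length", call. = FALSE)
  }
  fmt <- sprintf("%%.%dg", as.integer(digits))
  gv <- sprintf(fmt, unclass(grid))
  header <- paste(c("x", gv), collapse = ",")
  body <- vapply(seq_len(nrow(map)), function(i) {
    paste(c(gv[i], sprintf(fmt, map[i, ])), collapse = ",")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
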