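#' Shared x-grid of a curve or curve series
#'
#' The shaping variable `x` is the independent axis of every curve (for
#' spectra, typically a wavenumber axis). All curves of a series live on one
#' common grid; maps are labelled by its values.
#'
#' @param x numeric vector, strictly increasing, length >= 2, all finite.
#' @return An object of class `curve_grid` (a validated numeric vector).
#' @examples
#' g <- curve_grid(901:1099)
#' length(g)
#' @export
curve_grid <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) {
    stop("curve_grid: need at least 2 grid points", call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("curve_grid: all grid values must be finite", call. = FALSE)
  }
  if (any(diff(x) <= 0)) {
    stop("curve_grid: grid values must be strictly increasing", call. = FALSE)
  }
  structure(x, class = "curve_grid")
}

#' A series of curves over a perturbation
#'
#' Stacks `m` curves sampled on a shared grid into the dynamic matrix used by
#' 2D correlation analysis: row `j` holds the curve observed at perturbation
#' value `t_j`, column `i` the intensities at grid point `x_i`.
#'
#' @param grid a [curve_grid()] (or numeric vector coerced to one).
#' @param t_values numeric vector of perturbation values, one per curve.
#'   Neither equidistance nor ordering is required; duplicates are allowed.
#' @param intensities numeric matrix, `length(t_values)` rows by
#'   `length(grid)` columns, all finite.
#' @return An object of class `curve_series` with fields `grid`, `t_values`,
#'   `intensities`.
#' @seealso [curve_single()], [generate_series()]
#' @export
curve_series <- function(grid, t_values, intensities) {
  if (!inherits(grid, "curve_grid")) grid <- curve_grid(grid)
  t_values <- as.numeric(t_values)
  if (length(t_values) < 1L) {
    stop("curve_series: t_values must be nonempty", call. = FALSE)
  }
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (nrow(intensities) != length(t_values)) {
    stop("curve_series: intensity row count must equal length(t_values)",
         call. = FALSE)
  }
  if (ncol(intensities) != length(grid)) {
    stop("curve_series: intensity column count must equal grid length",
         call. = FALSE)
  }
  if (!all(is.finite(intensities))) {
    stop("curve_series: all intensities must be finite", call. = FALSE)
  }
  dimnames(intensities) <- NULL
  structure(list(grid = grid, t_values = t_values,
                 intensities = intensities),
            class = "curve_series")
}

#' A single curve on a grid
#'
#' Holds one measured or simulated curve for the two-trace losses; the `role`
#' is provenance metadata only and does not affect any computation.
#'
#' @param grid a [curve_grid()] (or numeric vector coerced to one).
#' @param intensities numeric vector, same length as the grid, all finite.
#' @param role `"measured"` or `"simulated"`.
#' @return An object of class `curve_single`.
#' @export
curve_single <- function(grid, intensities, role = c("measured", "simulated")) {
  role <- match.arg(role)
  if (!inherits(grid, "curve_grid")) grid <- curve_grid(grid)
  intensities <- as.numeric(intensities)
  if (length(intensities) != length(grid)) {
    stop("curve_single: intensity length must match grid length", call. = FALSE)
  }
  if (!all(is.finite(intensities))) {
    stop("curve_single: intensities must be finite", call. = FALSE)
  }
  structure(list(grid = grid, intensities = intensities, role = role),
            class = "curve_single")
}

#' @export
print.curve_series <- function(x, ...) {
  cat(sprintf("<curve_series> %d curves x %d grid points; x in [%g, %g]; t: %s\n",
              nrow(x$intensities), ncol(x$intensities),
              min(x$grid), max(x$grid),
              paste(signif(x$t_values, 6), collapse = ", ")))
  invisible(x)
}

#' @export
print.curve_single <- function(x, ...) {
  cat(sprintf("<curve_single:%s> %d grid points; x in [%g, %g]\n",
              x$role, length(x$intensities), min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
as.matrix.curve_series <- function(x, ...) x$intensities

# internal: extract curve j of a series as a curve_single
series_curve <- function(series, j, role = "measured") {
  curve_single(series$grid, series$intensities[j, ], role = role)
}

# internal: require two objects to share a grid
check_same_grid <- function(a, b) {
  ga <- unclass(a$grid); gb <- unclass(b$grid)
  if (length(ga) != length(gb) || !isTRUE(all.equal(ga, gb))) {
    stop("inputs must share the same x-grid", call. = FALSE)
  }
  invisible(TRUE)
}
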