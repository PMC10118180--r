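#' Hilbert-Noda transformation matrix
#'
#' The discrete Hilbert transform operator used to build asynchronous 2D
#' correlation maps: zero on the diagonal and `1 / (pi * (j - i))` elsewhere.
#' Antisymmetric by construction.
#'
#' @param m integer >= 2, number of curves in the series.
#' @return An `m x m` numeric matrix.
#' @examples
#' noda_matrix(2)  # [[0, 1/pi], [-1/pi, 0]]
#' @export
noda_matrix <- function(m) {
  if (length(m) != 1L || !is.finite(m) || m != round(m) || m < 2) {
    stop("noda_matrix: m must be a single integer >= 2", call. = FALSE)
  }
  m <- as.integer(m)
  d <- outer(seq_len(m), seq_len(m), function(i, j) j - i)
  ifelse(d == 0L, 0, 1 / (pi * d))
}

#' Prepare the dynamic matrix of a series
#'
#' Optionally removes a single scalar offset shared by all curves before 2D
#' correlation analysis. A common offset makes both the correlation maps and
#' the smart error sums ill-defined, so it must be removed when present; the
#' offset is estimated as the global minimum over all intensities (documented
#' estimator choice -- the method requires removal, not a specific estimator).
#'
#' @param series a [curve_series()].
#' @param remove_common_offset if `TRUE`, subtract the global minimum
#'   intensity from every entry. Default `FALSE` (identity).
#' @return A [curve_series()].
#' @export
build_dynamic_matrix <- function(series, remove_common_offset = FALSE) {
  stopifnot(inherits(series, "curve_series"))
  if (!isTRUE(remove_common_offset)) {
    return(series)
  }
  off <- min(series$intensities)
  curve_series(series$grid, series$t_values, series$intensities - off)
}

# internal: subtract the mean curve from each row (opt-in preprocessing)
mean_center_series <- function(series) {
  mu <- colMeans(series$intensities)
  curve_series(series$grid, series$t_values,
               sweep(series$intensities, 2L, mu))
}

# internal: shared validation + preprocessing for the series map builders
prep_series_pair <- function(y1, y2, remove_common_offset = FALSE,
                             mean_center = FALSE) {
  stopifnot(inherits(y1, "curve_series"), inherits(y2, "curve_series"))
  check_same_grid(y1, y2)
  if (nrow(y1$intensities) != nrow(y2$intensities)) {
    stop("series must have the same number of curves", call. = FALSE)
  }
  if (nrow(y1$intensities) < 2L) {
    stop("series maps need m >= 2 curves (normalization divides by m - 1)",
         call. = FALSE)
  }
  y1 <- build_dynamic_matrix(y1, remove_common_offset)
  y2 <- build_dynamic_matrix(y2, remove_common_offset)
  if (isTRUE(mean_center)) {
    y1 <- mean_center_series(y1)
    y2 <- mean_center_series(y2)
  }
  list(y1 = y1, y2 = y2)
}

# internal: conventional when the two series are the same data
series_kind <- function(y1, y2) {
  if (identical(y1$intensities, y2$intensities) &&
      identical(y1$t_values, y2$t_values)) "conventional" else "hybrid-series"
}

#' Synchronous 2D correlation map
#'
#' The variance-covariance map `Phi = Y1' Y2 / (m - 1)` between intensity
#' variations at every pair of grid positions. With `y2 = y1` (conventional
#' analysis) the map is symmetric about the diagonal; for two different
#' series (hybrid analysis, e.g. measured vs simulated) symmetry holds only
#' insofar as the series agree up to a scalar factor.
#'
#' @param y1,y2 [curve_series()] objects on the same grid with the same
#'   number of curves. `y2` defaults to `y1` (conventional map).
#' @param remove_common_offset,mean_center opt-in preprocessing flags, both
#'   default `FALSE`; see [build_dynamic_matrix()].
#' @return A `correlation_maps` object with the `synchronous` slot filled.
#' @seealso [asynchronous_map()], [series_maps()], [two_trace_maps()]
#' @export
synchronous_map <- function(y1, y2 = y1, remove_common_offset = FALSE,
                            mean_center = FALSE) {
  kind <- series_kind(y1, y2)
  p <- prep_series_pair(y1, y2, remove_common_offset, mean_center)
  m <- nrow(p$y1$intensities)
  phi <- crossprod(p$y1$intensities, p$y2$intensities) / (m - 1)
  correlation_maps(synchronous = phi, asynchronous = NULL, kind = kind,
                   grid = y1$grid, m_used = m)
}

#' Asynchronous 2D correlation map
#'
#' `Psi = Y1' N Y2 / (m - 1)` with `N` the Hilbert-Noda matrix. Captures
#' disproportionate (out-of-phase) intensity variations: any series whose
#' intensities factor as `g(t) h(x)` -- shape fixed, amplitude scaling with
#' the perturbation, however nonlinearly -- yields an identically zero map.
#'
#' @inheritParams synchronous_map
#' @return A `correlation_maps` object with the `asynchronous` slot filled.
#' @export
asynchronous_map <- function(y1, y2 = y1, remove_common_offset = FALSE,
                             mean_center = FALSE) {
  kind <- series_kind(y1, y2)
  p <- prep_series_pair(y1, y2, remove_common_offset, mean_center)
  m <- nrow(p$y1$intensities)
  psi <- crossprod(p$y1$intensities,
                   noda_matrix(m) %*% p$y2$intensities) / (m - 1)
  correlation_maps(synchronous = NULL, asynchronous = psi, kind = kind,
                   grid = y1$grid, m_used = m)
}

#' Both series-based maps at once
#'
#' @inheritParams synchronous_map
#' @return A `correlation_maps` object with both slots filled.
#' @export
series_maps <- function(y1, y2 = y1, remove_common_offset = FALSE,
                        mean_center = FALSE) {
  kind <- series_kind(y1, y2)
  p <- prep_series_pair(y1, y2, remove_common_offset, mean_center)
  m <- nrow(p$y1$intensities)
  phi <- crossprod(p$y1$intensities, p$y2$intensities) / (m - 1)
  psi <- crossprod(p$y1$intensities,
                   noda_matrix(m) %*% p$y2$intensities) / (m - 1)
  correlation_maps(synchronous = phi, asynchronous = psi, kind = kind,
                   grid = y1$grid, m_used = m)
}

#' Two-trace 2D correlation maps
#'
#' Correlation maps built from exactly two curves (typically one measured,
#' one simulated) instead of a series:
#' `Phi(j,k) = (s_j s_k + m_j m_k) / 2` and
#' `Psi(j,k) = (s_j m_k - m_j s_k) / 2`.
#' Phi is symmetric and Psi antisymmetric by construction; Psi vanishes
#' identically exactly when the two curves are linearly dependent, which is
#' what the two-trace losses exploit.
#'
#' @param s_curve,m_curve [curve_single()] objects on the same grid.
#' @return A `correlation_maps` object of kind `"two-trace"`.
#' @export
two_trace_maps <- function(s_curve, m_curve) {
  stopifnot(inherits(s_curve, "curve_single"), inherits(m_curve, "curve_single"))
  check_same_grid(s_curve, m_curve)
  s <- s_curve$intensities
  m <- m_curve$intensities
  phi <- (outer(s, s) + outer(m, m)) / 2
  psi <- (outer(s, m) - outer(m, s)) / 2
  correlation_maps(synchronous = phi, asynchronous = psi, kind = "two-trace",
                   grid = s_curve$grid, m_used = NA_integer_)
}

#' Container for paired synchronous/asynchronous maps
#'
#' @param synchronous,asynchronous square numeric matrices (either may be
#'   `NULL` when only one map was requested).
#' @param kind one of `"conventional"`, `"hybrid-series"`, `"two-trace"`.
#' @param grid the [curve_grid()] labelling rows and columns.
#' @param m_used number of curves behind the `1/(m-1)` normalization
#'   (`NA` for two-trace maps).
#' @return An object of class `correlation_maps`.
#' @export
correlation_maps <- function(synchronous, asynchronous, kind, grid,
                             m_used = NA_integer_) {
  kind <- match.arg(kind, c("conventional", "hybrid-series", "two-trace"))
  for (mp in list(synchronous, asynchronous)) {
    if (!is.null(mp) && (!is.matrix(mp) || nrow(mp) != ncol(mp))) {
      stop("correlation maps must be square matrices", call. = FALSE)
    }
  }
  structure(list(synchronous = synchronous, asynchronous = asynchronous,
                 kind = kind, grid = grid, m_used = m_used),
            class = "correlation_maps")
}

#' @export
print.correlation_maps <- function(x, ...) {
  have <- c(if (!is.null(x$synchronous)) "synchronous",
            if (!is.null(x$asynchronous)) "asynchronous")
  n <- nrow(if (is.null(x$synchronous)) x$asynchronous else x$synchronous)
  cat(sprintf("<correlation_maps:%s> %d x %d [%s]\n",
              x$kind, n, n, paste(have, collapse = " + ")))
  invisible(x)
}

#' Quadrant-adjusted phase-angle map
#'
#' Treats the synchronous/asynchronous pair as a complex map `Phi + i Psi`
#' and returns its phase `Theta = arctan(Psi / Phi)`, with two adjustments:
#'
#' * the denominator is regularized by a sign-matched epsilon,
#'   `Phi + sign(Phi) * epsilon` (with sign(0) taken as +1), so the 0/0 case
#'   resolves to `Theta = 0`;
#' * the principal arctangent branch `(-pi/2, pi/2)` is remapped to the
#'   physically meaningful range `(-pi/4, 3*pi/4]` by adding `pi` wherever the
#'   raw value falls in `(-pi/2, -pi/4]`.
#'
#' @param maps a `correlation_maps` object with both maps present.
#' @param epsilon positive regularizing constant (default `1e-10`, small
#'   enough to act only as a predictable substitute for bit noise).
#' @return An object of class `phase_angle_map` with fields `theta`
#'   (radians), `epsilon_used`, `branch_adjusted_count`.
#' @export
phase_angle_map <- function(maps, epsilon = 1e-10) {
  stopifnot(inherits(maps, "correlation_maps"))
  if (is.null(maps$synchronous) || is.null(maps$asynchronous)) {
    stop("phase_angle_map: need both synchronous and asynchronous maps",
         call. = FALSE)
  }
  if (length(epsilon) != 1L || !is.finite(epsilon) || epsilon <= 0) {
    stop("phase_angle_map: epsilon must be a positive real", call. = FALSE)
  }
  phi <- maps$synchronous
  psi <- maps$asynchronous
  if (!identical(dim(phi), dim(psi))) {
    stop("phase_angle_map: map shapes differ", call. = FALSE)
  }
  denom <- phi + ifelse(phi >= 0, epsilon, -epsilon)
  theta <- atan(psi / denom)
  adjust <- theta <= -pi / 4
  theta[adjust] <- theta[adjust] + pi
  structure(list(theta = theta, epsilon_used = epsilon,
                 branch_adjusted_count = sum(adjust), grid = maps$grid),
            class = "phase_angle_map")
}

#' @export
print.phase_angle_map <- function(x, ...) {
  cat(sprintf("<phase_angle_map> %d x %d; %d branch-adjusted entries\n",
              nrow(x$theta), ncol(x$theta), x$branch_adjusted_count))
  invisible(x)
}
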