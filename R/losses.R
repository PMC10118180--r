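#' Specification of a loss function
#'
#' Bundles the loss family with its tunable constants. Families:
#' \describe{
#'   \item{RSS}{conventional residual sum of squares (point-by-point).}
#'   \item{SES_SERIES}{series smart error sum `ln(SRSS + eps) + ln(ARSS + eps)`
#'     built from hybrid synchronous/asynchronous maps of measured vs
#'     simulated series.}
#'   \item{ASYNC_2T2D}{upper-triangle sum of squared two-trace asynchronous
#'     intensities (O(N^2) form).}
#'   \item{ASYNC_2T2D_FAST}{closed-form full-matrix equivalent,
#'     `[sum(s^2) sum(m^2) - (sum(s m))^2] / 2`, which scales O(N); exactly
#'     twice the upper-triangle form.}
#'   \item{PHASE_2T2D}{upper-triangle sum of squared two-trace phase angles.}
#'   \item{PHASE_SERIES}{upper-triangle sum of squared differences between
#'     the phase-angle maps of the measured and the simulated series.}
#'   \item{NEG_NCC}{negated normalized cross-correlation.}
#'   \item{NEG_ZNCC}{negated zero-mean normalized cross-correlation.}
#' }
#'
#' Every family except RSS attains its minimum whenever model and data agree
#' up to a positive scalar factor (NEG_ZNCC additionally up to an offset),
#' which is what makes them robust against multiplicative systematic errors.
#'
#' @param family one of the names above.
#' @param p positive even exponent; only `p = 2` has closed forms and is
#'   exercised by the test suite.
#' @param epsilon positive regularizer used inside the logarithms of
#'   SES_SERIES and in the phase-angle denominator; default `1e-10`.
#' @param remove_common_offset,mean_center opt-in preprocessing flags applied
#'   to series before map construction; both default `FALSE`.
#' @return An object of class `loss_spec`.
#' @export
loss_spec <- function(family = c("RSS", "SES_SERIES", "ASYNC_2T2D",
                                 "ASYNC_2T2D_FAST", "PHASE_2T2D",
                                 "PHASE_SERIES", "NEG_NCC", "NEG_ZNCC"),
                      p = 2, epsilon = 1e-10,
                      remove_common_offset = FALSE, mean_center = FALSE) {
  family <- match.arg(family)
  if (length(p) != 1L || !is.finite(p) || p != round(p) || p <= 0 ||
      p %% 2 != 0) {
    stop("loss_spec: p must be a positive even integer", call. = FALSE)
  }
  if (length(epsilon) != 1L || !is.finite(epsilon) || epsilon <= 0) {
    stop("loss_spec: epsilon must be positive", call. = FALSE)
  }
  structure(list(family = family, p = as.integer(p), epsilon = epsilon,
                 remove_common_offset = isTRUE(remove_common_offset),
                 mean_center = isTRUE(mean_center)),
            class = "loss_spec")
}

# internal: sum over the upper triangle (diagonal included) of x^p
upper_tri_power_sum <- function(x, p = 2) {
  sum(x[upper.tri(x, diag = TRUE)]^p)
}

#' Residual sum of squares
#'
#' The conventional point-by-point loss; the baseline every smart error sum
#' is compared against. Not invariant under scalar rescaling of either input.
#'
#' @param measured,simulated two [curve_single()] or two [curve_series()]
#'   objects of identical shape.
#' @return Nonnegative numeric scalar.
#' @export
rss <- function(measured, simulated) {
  if (inherits(measured, "curve_series") && inherits(simulated, "curve_series")) {
    check_same_grid(measured, simulated)
    if (!identical(dim(measured$intensities), dim(simulated$intensities))) {
      stop("rss: series shapes differ", call. = FALSE)
    }
    return(sum((measured$intensities - simulated$intensities)^2))
  }
  if (inherits(measured, "curve_single") && inherits(simulated, "curve_single")) {
    check_same_grid(measured, simulated)
    return(sum((measured$intensities - simulated$intensities)^2))
  }
  stop("rss: inputs must be two curves or two series of the same shape",
       call. = FALSE)
}

#' Synchronous residual sum of squares (SRSS)
#'
#' Measures how far a hybrid synchronous map deviates from the symmetry
#' `Phi(j,k) = Phi(k,j)` that a conventional (single-series) map obeys:
#' upper-triangle sum (diagonal included -- its terms are identically zero)
#' of `[Phi(j,k) - Phi(k,j)]^p`.
#'
#' @param maps a `correlation_maps` object with a synchronous map.
#' @param p positive even exponent, default 2.
#' @return Nonnegative numeric scalar; 0 iff the map is symmetric.
#' @export
srss <- function(maps, p = 2) {
  stopifnot(inherits(maps, "correlation_maps"))
  phi <- maps$synchronous
  if (is.null(phi)) stop("srss: no synchronous map present", call. = FALSE)
  check_even_p(p)
  upper_tri_power_sum(phi - t(phi), p)
}

#' Asynchronous residual sum of squares (ARSS)
#'
#' Deviation of a hybrid asynchronous map from the antisymmetry
#' `Psi(j,k) = -Psi(k,j)` of the conventional case: upper-triangle sum of
#' `[Psi(j,k) + Psi(k,j)]^p`.
#'
#' @param maps a `correlation_maps` object with an asynchronous map.
#' @param p positive even exponent, default 2.
#' @return Nonnegative numeric scalar; 0 iff the map is antisymmetric.
#' @export
arss <- function(maps, p = 2) {
  stopifnot(inherits(maps, "correlation_maps"))
  psi <- maps$asynchronous
  if (is.null(psi)) stop("arss: no asynchronous map present", call. = FALSE)
  check_even_p(p)
  upper_tri_power_sum(psi + t(psi), p)
}

check_even_p <- function(p) {
  if (length(p) != 1L || !is.finite(p) || p != round(p) || p <= 0 ||
      p %% 2 != 0) {
    stop("exponent p must be a positive even integer", call. = FALSE)
  }
  invisible(TRUE)
}

#' Series smart error sum
#'
#' `ln(SRSS + eps) + ln(ARSS + eps)` evaluated on the hybrid maps of
#' (measured series, simulated series). Both residual sums vanish exactly --
#' and the loss bottoms out at `2 * ln(eps)` -- whenever the simulated series
#' equals the measured one up to a scalar factor, which is precisely the
#' tolerance for multiplicative systematic errors.
#'
#' @param y1 measured [curve_series()].
#' @param y2 simulated [curve_series()] of the same shape.
#' @param spec a [loss_spec()]; its `p`, `epsilon` and preprocessing flags
#'   are honoured.
#' @return Numeric scalar with attribute `components = c(srss=, arss=)`.
#' @export
ses_series <- function(y1, y2, spec = loss_spec("SES_SERIES")) {
  maps <- series_maps(y1, y2,
                      remove_common_offset = spec$remove_common_offset,
                      mean_center = spec$mean_center)
  s <- srss(maps, spec$p)
  a <- arss(maps, spec$p)
  structure(log(s + spec$epsilon) + log(a + spec$epsilon),
            components = c(srss = s, arss = a))
}

#' Two-trace asynchronous smart error sum (O(N^2) form)
#'
#' Upper-triangle sum (diagonal included) of squared two-trace asynchronous
#' intensities. Zero exactly when the two curves are proportional.
#'
#' @param s_curve,m_curve [curve_single()] objects on the same grid.
#' @param p positive even exponent, default 2.
#' @return Nonnegative numeric scalar.
#' @export
async_2t2d <- function(s_curve, m_curve, p = 2) {
  check_even_p(p)
  maps <- two_trace_maps(s_curve, m_curve)
  upper_tri_power_sum(maps$asynchronous, p)
}

#' Two-trace asynchronous smart error sum (O(N) closed form)
#'
#' The full-matrix sum of squared two-trace asynchronous intensities admits
#' the closed form `[sum(s^2) sum(m^2) - (sum(s m))^2] / 2`, which scales
#' linearly in the number of points like the conventional RSS. Because the
#' full matrix double-counts the strict upper triangle and the diagonal is
#' zero, this equals exactly `2 * async_2t2d(s, m)`; the two share their
#' minimizer.
#'
#' @param s_curve,m_curve [curve_single()] objects on the same grid.
#' @return Nonnegative numeric scalar; 0 iff the curves are proportional
#'   (Cauchy-Schwarz equality case).
#' @export
async_2t2d_fast <- function(s_curve, m_curve) {
  stopifnot(inherits(s_curve, "curve_single"), inherits(m_curve, "curve_single"))
  check_same_grid(s_curve, m_curve)
  s <- s_curve$intensities
  m <- m_curve$intensities
  (sum(s^2) * sum(m^2) - sum(s * m)^2) / 2
}

#' Two-trace phase-angle smart error sum
#'
#' Upper-triangle sum of squared phase angles of the two-trace maps. When
#' model and data agree up to a factor, the asynchronous map -- and with it
#' every phase angle -- is zero.
#'
#' @param s_curve,m_curve [curve_single()] objects on the same grid.
#' @param spec a [loss_spec()]; `p` and `epsilon` are honoured.
#' @return Nonnegative numeric scalar.
#' @export
phase_2t2d <- function(s_curve, m_curve, spec = loss_spec("PHASE_2T2D")) {
  maps <- two_trace_maps(s_curve, m_curve)
  th <- phase_angle_map(maps, spec$epsilon)$theta
  upper_tri_power_sum(th, spec$p)
}

#' Series phase-angle smart error sum
#'
#' Compares the phase-angle maps of two series: each series is reduced to its
#' own conventional synchronous/asynchronous maps, the quadrant-adjusted
#' phase angles are taken, and the upper-triangle sum of squared differences
#' is returned. Individual maps may differ by multiplicative factors while
#' their phase angles agree, hence the scale invariance.
#'
#' @param y1 measured [curve_series()].
#' @param y2 simulated [curve_series()] of the same shape.
#' @param spec a [loss_spec()].
#' @return Nonnegative numeric scalar.
#' @export
phase_series_ses <- function(y1, y2, spec = loss_spec("PHASE_SERIES")) {
  m1 <- series_maps(y1, remove_common_offset = spec$remove_common_offset,
                    mean_center = spec$mean_center)
  m2 <- series_maps(y2, remove_common_offset = spec$remove_common_offset,
                    mean_center = spec$mean_center)
  th1 <- phase_angle_map(m1, spec$epsilon)$theta
  th2 <- phase_angle_map(m2, spec$epsilon)$theta
  upper_tri_power_sum(th1 - th2, spec$p)
}

#' Normalized cross-correlation
#'
#' `sum(s m) / sqrt(sum(s^2) sum(m^2))`; equals 1 exactly when `m = C s` for
#' some `C > 0`, otherwise lies in (-1, 1). Its negation serves as a
#' scale-invariant loss. Algebraically linked to the two-trace loss through
#' `NCC^2 = 1 - 2 * async_2t2d_fast / (sum(s^2) sum(m^2))`.
#'
#' @param s_curve,m_curve [curve_single()] objects on the same grid; neither
#'   may be all-zero.
#' @return Numeric scalar in `[-1, 1]`.
#' @export
ncc <- function(s_curve, m_curve) {
  stopifnot(inherits(s_curve, "curve_single"), inherits(m_curve, "curve_single"))
  check_same_grid(s_curve, m_curve)
  s <- s_curve$intensities
  m <- m_curve$intensities
  ss <- sum(s^2); mm <- sum(m^2)
  if (ss == 0 || mm == 0) {
    stop("ncc: degenerate input (all-zero curve)", call. = FALSE)
  }
  sum(s * m) / sqrt(ss * mm)
}

#' Zero-mean normalized cross-correlation
#'
#' Mean-centered, deviation-normalized cross-correlation; in its default
#' (matched-divisor, i.e. Pearson) form it lies in `[-1, 1]` and equals 1
#' exactly for `m = C s + O` with `C > 0` and any offset `O`. A
#' strict-as-printed mode with prefactor `1/(l+1)` and population standard
#' deviations is available but is not bounded by 1.
#'
#' @param s_curve,m_curve [curve_single()] objects on the same grid; both
#'   must have nonzero variance.
#' @param strict_printed if `TRUE`, use the `1/(l+1)` prefactor with
#'   population-sd normalization instead of the matched divisor.
#' @return Numeric scalar (in `[-1, 1]` unless `strict_printed`).
#' @export
zncc <- function(s_curve, m_curve, strict_printed = FALSE) {
  stopifnot(inherits(s_curve, "curve_single"), inherits(m_curve, "curve_single"))
  check_same_grid(s_curve, m_curve)
  s <- s_curve$intensities
  m <- m_curve$intensities
  l <- length(s)
  ds <- s - mean(s)
  dm <- m - mean(m)
  ss <- sum(ds^2); mm <- sum(dm^2)
  if (ss == 0 || mm == 0) {
    stop("zncc: degenerate input (zero-variance curve)", call. = FALSE)
  }
  if (isTRUE(strict_printed)) {
    sig_s <- sqrt(ss / l)
    sig_m <- sqrt(mm / l)
    return(sum(dm * ds) / ((l + 1) * sig_s * sig_m))
  }
  sum(dm * ds) / sqrt(ss * mm)
}

#' Evaluate a configured loss between data and model
#'
#' Dispatcher used by the fitting harness: maps a [loss_spec()] onto the
#' corresponding loss function. Correlation losses are returned negated where
#' needed so that smaller is always better.
#'
#' @param spec a [loss_spec()].
#' @param measured,simulated curves (for two-trace and point-wise families)
#'   or series (for RSS and the series families).
#' @return Numeric scalar loss (lower is better).
#' @export
evaluate_loss <- function(spec, measured, simulated) {
  stopifnot(inherits(spec, "loss_spec"))
  switch(spec$family,
    RSS = rss(measured, simulated),
    SES_SERIES = as.numeric(ses_series(measured, simulated, spec)),
    ASYNC_2T2D = async_2t2d(simulated, measured, spec$p),
    ASYNC_2T2D_FAST = async_2t2d_fast(simulated, measured),
    PHASE_2T2D = phase_2t2d(simulated, measured, spec),
    PHASE_SERIES = phase_series_ses(measured, simulated, spec),
    NEG_NCC = -ncc(simulated, measured),
    NEG_ZNCC = -zncc(simulated, measured)
  )
}

# internal: does this family compare whole series (joint fit) or single curves?
is_series_family <- function(family) {
  family %in% c("SES_SERIES", "PHASE_SERIES")
}
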