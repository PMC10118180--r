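#' Parameters of the Cauchy-type test band
#'
#' The synthetic band family used throughout the package:
#' `f(x, t) = t (1 + a t) * gamma / ((x - x0 -/+ b t)^2 + gamma^2)`.
#' `t` is the perturbation (the amplitude driver), `a` adds a nonlinear --
#' but still proportionate -- amplitude response, and `b` couples the peak
#' position to the perturbation, which is the disproportionate change the
#' smart error sums require. With `b = 0` the function is separable,
#' `g(t) h(x)`, and every asynchronous map vanishes regardless of `a`.
#'
#' @param x0 band position.
#' @param gamma half-width at half-maximum, > 0.
#' @param a amplitude-nonlinearity constant.
#' @param b peak-shift coupling constant.
#' @param shift_sign `"downshift"` (default) places the peak at `x0 - b t`,
#'   so the band moves to smaller x for increasing t; `"as-printed"` places
#'   it at `x0 + b t`.
#' @return An object of class `cauchy_params`.
#' @export
cauchy_params <- function(x0 = 1000, gamma = 30, a = 0, b = 0,
                          shift_sign = c("downshift", "as-printed")) {
  shift_sign <- match.arg(shift_sign)
  if (length(gamma) != 1L || !is.finite(gamma) || gamma <= 0) {
    stop("cauchy_params: gamma must be a positive real", call. = FALSE)
  }
  stopifnot(is.finite(x0), is.finite(a), is.finite(b))
  structure(list(x0 = x0, gamma = gamma, a = a, b = b,
                 shift_sign = shift_sign),
            class = "cauchy_params")
}

#' @export
print.cauchy_params <- function(x, ...) {
  cat(sprintf("<cauchy_params> x0=%g gamma=%g a=%g b=%g (%s)\n",
              x$x0, x$gamma, x$a, x$b, x$shift_sign))
  invisible(x)
}

#' Evaluate one Cauchy-type band
#'
#' @param params a [cauchy_params()].
#' @param grid a [curve_grid()] (or numeric vector coerced to one).
#' @param t perturbation value.
#' @param role provenance tag for the returned curve.
#' @return A [curve_single()] with peak height `t (1 + a t) / gamma` at the
#'   peak position (`x0 - b t` in downshift mode).
#' @examples
#' g <- curve_grid(901:1099)
#' crv <- cauchy_curve(cauchy_params(), g, t = 1)
#' max(crv$intensities)  # 1/30 at x = 1000
#' @export
cauchy_curve <- function(params, grid, t, role = "simulated") {
  stopifnot(inherits(params, "cauchy_params"))
  if (!inherits(grid, "curve_grid")) grid <- curve_grid(grid)
  peak <- if (params$shift_sign == "downshift") {
    params$x0 - params$b * t
  } else {
    params$x0 + params$b * t
  }
  y <- t * (1 + params$a * t) * params$gamma /
    ((unclass(grid) - peak)^2 + params$gamma^2)
  curve_single(grid, y, role = role)
}

#' Generate a Cauchy-type curve series
#'
#' Stacks one band per perturbation value into a [curve_series()], row order
#' following `t_values` (neither equidistance nor ordering is required for
#' the smart error sums, so arbitrary and duplicate t are accepted).
#'
#' @param params a [cauchy_params()].
#' @param grid a [curve_grid()].
#' @param t_values nonempty numeric vector of perturbation values.
#' @return A [curve_series()].
#' @export
generate_series <- function(params, grid, t_values) {
  if (!inherits(grid, "curve_grid")) grid <- curve_grid(grid)
  t_values <- as.numeric(t_values)
  if (length(t_values) < 1L) {
    stop("generate_series: t_values must be nonempty", call. = FALSE)
  }
  y <- t(vapply(t_values,
                function(tj) cauchy_curve(params, grid, tj)$intensities,
                numeric(length(grid))))
  curve_series(grid, t_values, y)
}

#' Multiplicative/additive systematic error model
#'
#' @param factor positive scalar, or a function of x returning positive
#'   factors, multiplying every intensity. `factor = 1.1` is the uniform 10%
#'   corruption of the reference experiment; a real measurement would have an
#'   x-dependent factor, which the function form emulates.
#' @param offset additive constant applied after scaling.
#' @return An object of class `error_model`.
#' @export
error_model <- function(factor = 1.1, offset = 0) {
  if (!is.function(factor)) {
    if (length(factor) != 1L || !is.finite(factor) || factor <= 0) {
      stop("error_model: constant factor must be a positive real",
           call. = FALSE)
    }
  }
  stopifnot(is.finite(offset))
  structure(list(factor = factor, offset = offset), class = "error_model")
}

#' Corrupt a series with a systematic error
#'
#' Multiplies each intensity by the (possibly x-dependent) factor, then adds
#' the offset. With `factor = 1` and `offset = 0` this is the identity.
#'
#' @param series a [curve_series()].
#' @param model an [error_model()].
#' @return The corrupted [curve_series()].
#' @export
apply_error <- function(series, model) {
  stopifnot(inherits(series, "curve_series"), inherits(model, "error_model"))
  fac <- if (is.function(model$factor)) {
    f <- model$factor(unclass(series$grid))
    if (length(f) != length(series$grid) || !all(is.finite(f)) || any(f <= 0)) {
      stop("apply_error: factor function must return positive finite values, one per grid point",
           call. = FALSE)
    }
    f
  } else {
    rep(model$factor, length(series$grid))
  }
  y <- sweep(series$intensities, 2L, fac, `*`) + model$offset
  curve_series(series$grid, series$t_values, y)
}

#' Pair of series differing only in their shape constants
#'
#' Builds two series from the same grid, perturbation values, position and
#' width but different (a, b) -- the setting in which hybrid maps lose their
#' antisymmetry and the misspecification diagnostic fires.
#'
#' @param params1,params2 [cauchy_params()] objects agreeing in `x0`,
#'   `gamma` and `shift_sign` (only `a` and/or `b` may differ).
#' @param grid a [curve_grid()].
#' @param t_values numeric vector of perturbation values.
#' @return A list of two [curve_series()].
#' @export
mixture_pair <- function(params1, params2, grid, t_values) {
  stopifnot(inherits(params1, "cauchy_params"), inherits(params2, "cauchy_params"))
  if (params1$x0 != params2$x0 || params1$gamma != params2$gamma ||
      params1$shift_sign != params2$shift_sign) {
    stop("mixture_pair: params may differ only in a and/or b", call. = FALSE)
  }
  list(generate_series(params1, grid, t_values),
       generate_series(params2, grid, t_values))
}

#' Transform series intensities before loss evaluation
#'
#' Hook for handling additive systematic errors via an exponential transform
#' (an additive error becomes multiplicative under exp, and the smart error
#' sums absorb multiplicative factors). Off by default; only the intensity
#' values are transformed, nothing else changes.
#'
#' @param series a [curve_series()].
#' @param transform `"identity"`, `"exp"`, or `"log"` (log requires strictly
#'   positive intensities).
#' @return A [curve_series()] with transformed intensities.
#' @export
transform_series <- function(series, transform = c("identity", "exp", "log")) {
  transform <- match.arg(transform)
  stopifnot(inherits(series, "curve_series"))
  y <- switch(transform,
              identity = series$intensities,
              exp = exp(series$intensities),
              log = {
                if (any(series$intensities <= 0)) {
                  stop("transform_series: log requires positive intensities",
                       call. = FALSE)
                }
                log(series$intensities)
              })
  curve_series(series$grid, series$t_values, y)
}

#' Default world of the reference corruption experiment
#'
#' Convenience constructor for the configuration exercised by
#' [reproduce_table1()] and the acceptance suite: five bands at
#' `t = 1, ..., 5`, `x0 = 1000`, `gamma = 30`, `a = 0`, `b = 1` (downshift)
#' on the unit grid 901..1099, corrupted by a uniform factor 1.1.
#'
#' @param factor multiplicative corruption factor (default 1.1).
#' @return A list with `params`, `grid`, `t_values`, `truth` (clean series)
#'   and `measured` (corrupted series).
#' @export
table1_world <- function(factor = 1.1) {
  params <- cauchy_params(x0 = 1000, gamma = 30, a = 0, b = 1,
                          shift_sign = "downshift")
  grid <- curve_grid(901:1099)
  t_values <- 1:5
  truth <- generate_series(params, grid, t_values)
  measured <- apply_error(truth, error_model(factor = factor, offset = 0))
  list(params = params, grid = grid, t_values = as.numeric(t_values),
       truth = truth, measured = measured)
}
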