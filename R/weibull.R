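#' Weibull cause-specific hazard specification
#'
#' The package parameterizes Weibull hazards as h(t; a, b) = a b t^(b-1)
#' with rate a > 0 and shape b > 0, so that the cumulative hazard is
#' A(t) = a t^b.  Shape b < 1 gives a decreasing ("early") hazard, b = 1 a
#' constant ("middle") hazard and b > 1 an increasing ("late") hazard.
#'
#' @param rate positive rate parameter a.
#' @param shape positive shape parameter b.
#' @return An object of class `"weibull_spec"`.
#' @examples
#' weibull_spec(1.198, 1)
#' @export
weibull_spec <- function(rate, shape) {
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate < 0)
    stop("'rate' must be a single nonnegative finite number")
  if (!is.numeric(shape) || length(shape) != 1 || !is.finite(shape) || shape <= 0)
    stop("'shape' must be a single positive finite number")
  structure(list(rate = rate, shape = shape), class = "weibull_spec")
}

#' @export
print.weibull_spec <- function(x, ...) {
  cat(sprintf("Weibull hazard h(t) = a b t^(b-1), a = %g, b = %g\n",
              x$rate, x$shape))
  invisible(x)
}

#' Weibull hazard and cumulative hazard
#'
#' `weibull_hazard()` evaluates h(t) = a b t^(b-1); `weibull_cumhaz()`
#' evaluates A(t) = a t^b.  For shape b < 1 the hazard diverges at t = 0;
#' evaluation there returns `Inf` (the cumulative hazard is always finite).
#'
#' @param t nonnegative times.
#' @param spec a [weibull_spec()].
#' @return Numeric vector of hazard (or cumulative hazard) values.
#' @examples
#' weibull_hazard(2, weibull_spec(0.479, 2))  # 1.916
#' @export
weibull_hazard <- function(t, spec) {
  stopifnot(inherits(spec, "weibull_spec"), all(t >= 0))
  a <- spec$rate; b <- spec$shape
  if (b == 1) rep(a, length(t)) else a * b * t^(b - 1)
}

#' @rdname weibull_hazard
#' @export
weibull_cumhaz <- function(t, spec) {
  stopifnot(inherits(spec, "weibull_spec"), all(t >= 0))
  spec$rate * t^spec$shape
}

#' Calibrate a Weibull rate to a survival target
#'
#' Finds the rate a such that a single-cause Weibull survival function
#' S(t) = exp(-a t^b) attains a given value at a given horizon:
#' a = -log(survival) / horizon^shape.
#'
#' @param shape positive shape parameter b.
#' @param horizon positive time at which the constraint holds.
#' @param survival target survival probability, strictly between 0 and 1.
#' @return The rate a (a single number).
#' @examples
#' # rates used for the early/middle/late hazards calibrated to S(2.5) = 0.05
#' round(solve_rate_for_survival(0.5, 2.5, 0.05), 3)  # 1.895
#' round(solve_rate_for_survival(1,   2.5, 0.05), 3)  # 1.198
#' round(solve_rate_for_survival(2,   2.5, 0.05), 3)  # 0.479
#' @export
solve_rate_for_survival <- function(shape, horizon, survival) {
  if (!is.numeric(shape) || length(shape) != 1 || shape <= 0)
    stop("'shape' must be a single positive number")
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon <= 0)
    stop("'horizon' must be a single positive number")
  if (!is.numeric(survival) || length(survival) != 1 ||
      survival <= 0 || survival >= 1)
    stop("'survival' must lie strictly between 0 and 1")
  -log(survival) / horizon^shape
}

#' Two-cause competing-risks model specification
#'
#' Bundles Weibull baseline cause-specific hazards for the cause of interest
#' (cause 1) and the competing cause (cause 2) with log hazard ratios
#' `beta1`, `beta2` for a scalar (typically binary 0/1) covariate acting
#' proportionally on each cause-specific hazard.  `p` records the covariate
#' mean used in simulation designs; it plays no role in the conditional
#' theory curves.
#'
#' @param baseline1,baseline2 [weibull_spec()] baselines for causes 1 and 2.
#' @param beta1,beta2 covariate log hazard ratios on the cause-specific
#'   hazards of causes 1 and 2.
#' @param p covariate mean (binary covariate success probability), recorded
#'   for simulation designs.
#' @return An object of class `"two_cause_spec"`.
#' @examples
#' two_cause_spec(weibull_spec(1.198, 1), weibull_spec(1.895, 0.5),
#'                beta1 = 0.5, beta2 = -0.5)
#' @export
two_cause_spec <- function(baseline1, baseline2, beta1 = 0, beta2 = 0,
                           p = 0.5) {
  stopifnot(inherits(baseline1, "weibull_spec"),
            inherits(baseline2, "weibull_spec"),
            is.finite(beta1), is.finite(beta2),
            is.numeric(p), p >= 0, p <= 1)
  structure(list(baseline1 = baseline1, baseline2 = baseline2,
                 beta1 = beta1, beta2 = beta2, p = p),
            class = "two_cause_spec")
}

#' @export
print.two_cause_spec <- function(x, ...) {
  cat("Two-cause competing risks model\n")
  cat(sprintf("  cause 1: a = %g, b = %g, beta1 = %g\n",
              x$baseline1$rate, x$baseline1$shape, x$beta1))
  cat(sprintf("  cause 2: a = %g, b = %g, beta2 = %g\n",
              x$baseline2$rate, x$baseline2$shape, x$beta2))
  invisible(x)
}

# rates for a two_cause_spec at covariate value x (NULL = baseline)
scaled_rates <- function(spec, covariate_value = NULL) {
  x <- if (is.null(covariate_value)) 0 else covariate_value
  list(a1 = spec$baseline1$rate * exp(spec$beta1 * x), b1 = spec$baseline1$shape,
       a2 = spec$baseline2$rate * exp(spec$beta2 * x), b2 = spec$baseline2$shape)
}
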