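#' Simulate competing-risks data under Weibull cause-specific hazards
#'
#' Draws, per subject: an optional binary covariate x ~ Bernoulli(p); a
#' latent event time by inverting the total cumulative hazard
#' A1(t|x) + A2(t|x) at a unit exponential deviate (closed form when both
#' shapes are equal, bracketed root-finding otherwise); the cause, equal to
#' 1 with probability alpha1(T|x) / \{alpha1(T|x) + alpha2(T|x)\}; and an
#' independent censoring time.  The random stream is seeded and consumed in
#' the fixed order covariates, event times, causes, censoring, so identical
#' seeds give identical datasets.
#'
#' @param n number of subjects.
#' @param spec a [two_cause_spec()]; its `beta1`, `beta2` act on a binary
#'   covariate, its `p` is the default covariate mean.
#' @param covariate `"binary"` or `"none"`.
#' @param censoring `list(type = "none")`,
#'   `list(type = "uniform", max = )`,
#'   `list(type = "exponential", rate = )` or
#'   `list(type = "admin", time = )` (administrative end of study: every
#'   subject still event-free at `time` is censored there, i.e. follow-up
#'   ends at the observation horizon with no censoring before it).  The
#'   `uniform` and `exponential` types accept an optional `admin` element
#'   for an additional end-of-study horizon.  The default, uniform on
#'   `[0, 3]` (1.2 x the 2.5 calibration horizon of the early/middle/late
#'   hazards), yields moderate censoring.
#' @param seed integer seed.
#' @return A [crdata()] object with columns `time`, `status` and (for a
#'   binary covariate) `x`.
#' @examples
#' spec <- two_cause_spec(weibull_spec(1.198, 1), weibull_spec(1.895, 0.5),
#'                        beta1 = 0.5, beta2 = -0.5)
#' d <- simulate_competing_risks(200, spec, seed = 7)
#' table(d$status)
#' @export
simulate_competing_risks <- function(n, spec, covariate = c("binary", "none"),
                                     censoring = list(type = "uniform", max = 3),
                                     seed = 1L) {
  stopifnot(inherits(spec, "two_cause_spec"), n >= 1)
  covariate <- match.arg(covariate)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  x <- if (covariate == "binary") stats::rbinom(n, 1, spec$p) else rep(0, n)
  a1 <- spec$baseline1$rate * exp(spec$beta1 * x)
  a2 <- spec$baseline2$rate * exp(spec$beta2 * x)
  b1 <- spec$baseline1$shape; b2 <- spec$baseline2$shape
  E <- stats::rexp(n)
  if (abs(b1 - b2) < 1e-12) {
    Tt <- (E / (a1 + a2))^(1 / b1)
  } else {
    Tt <- vapply(seq_len(n), function(i) {
      f <- function(t) a1[i] * t^b1 + a2[i] * t^b2 - E[i]
      hi <- 1
      while (f(hi) < 0) hi <- hi * 2
      stats::uniroot(f, c(0, hi), tol = 1e-12)$root
    }, numeric(1))
  }
  h1 <- a1 * b1 * Tt^(b1 - 1)
  h2 <- a2 * b2 * Tt^(b2 - 1)
  cause <- ifelse(stats::runif(n) < h1 / (h1 + h2), 1L, 2L)
  C <- draw_censoring(n, censoring)
  time <- pmin(Tt, C)
  status <- ifelse(Tt <= C, cause, 0L)
  if (covariate == "binary") crdata(time = time, status = status, x = x)
  else crdata(time = time, status = status)
}

draw_censoring <- function(n, censoring) {
  C <- switch(censoring$type,
              none = rep(Inf, n),
              admin = rep(censoring$time, n),
              uniform = stats::runif(n, 0, censoring$max),
              exponential = stats::rexp(n, censoring$rate),
              stop("unknown censoring type: ", censoring$type))
  if (!is.null(censoring$admin) && censoring$type != "admin")
    C <- pmin(C, censoring$admin)
  C
}

#' Fixed four-subject toy dataset
#'
#' Times (1, 2, 3, 4), statuses (1, 2, 1, 1), binary covariate (0, 0, 1, 1):
#' small enough that every estimator in the package can be checked by hand.
#' The overall reduction factor at the cause-1 event times (1, 3, 4) is
#' (1, 2/3, 1/2).
#'
#' @return A [crdata()] object.
#' @export
make_toy_dataset <- function() {
  crdata(time = c(1, 2, 3, 4), status = c(1L, 2L, 1L, 1L), x = c(0, 0, 1, 1))
}

# Simulation under an exactly proportional subdistribution hazard, used as a
# test utility for Fine-Gray parameter recovery.  Unit-exponential mixture
# construction: F1(t | x) = 1 - [1 - pmix(1 - exp(-t))]^exp(beta_fg x), so
# P(cause 1 | x) = 1 - (1 - pmix)^exp(beta_fg x); conditional on cause 2 the
# event time is exponential with rate exp(beta2 x).
simulate_fg_truth <- function(n, beta_fg, beta2 = 0, pmix = 0.3, p = 0.5,
                              censoring = list(type = "uniform", max = 3),
                              seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  x <- stats::rbinom(n, 1, p)
  ebx <- exp(beta_fg * x)
  u <- stats::runif(n)
  p1 <- 1 - (1 - pmix)^ebx
  cause <- ifelse(u <= p1, 1L, 2L)
  Tt <- numeric(n)
  i1 <- cause == 1L
  # solve F1(T | x) = u on the cause-1 branch
  Tt[i1] <- -log(1 - (1 - (1 - u[i1])^(1 / ebx[i1])) / pmix)
  i2 <- !i1
  Tt[i2] <- stats::rexp(sum(i2), exp(beta2 * x[i2]))
  C <- draw_censoring(n, censoring)
  time <- pmin(Tt, C)
  status <- ifelse(Tt <= C, cause, 0L)
  crdata(time = time, status = status, x = x)
}
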