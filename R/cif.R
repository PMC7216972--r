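# ---- cumulative incidence estimators ---------------------------------------

cif_estimate <- function(times, values, method, profile, extra = list()) {
  out <- data.frame(time = times, cif = values)
  attr(out, "method") <- method
  attr(out, "profile") <- profile
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("cif_estimate", "data.frame")
  out
}

#' Evaluate a cumulative incidence curve on a time grid
#'
#' Right-continuous step interpolation; 0 before the first event time.
#'
#' @param est a `"cif_estimate"`.
#' @param t evaluation times.
#' @export
cif_at <- function(est, t) {
  stopifnot(inherits(est, "cif_estimate"))
  idx <- findInterval(t, est$time)
  c(0, est$cif)[idx + 1L]
}

#' @export
print.cif_estimate <- function(x, ...) {
  cat(sprintf("Cumulative incidence (%s) at %d event times; F1 range [%.4f, %.4f]\n",
              attr(x, "method"), nrow(x), min(x$cif), max(x$cif)))
  invisible(x)
}

lp_for <- function(fit, profile) {
  if (length(fit$coefficients) == 0) return(0)
  drop(design_for(fit$design, profile) %*% fit$coefficients)
}

#' Cumulative incidence from two cause-specific Cox models (multistate)
#'
#' Plug-in estimator combining the Breslow baselines and coefficients of
#' proportional cause-specific hazards models for both causes:
#' \deqn{\hat F_1(t|x^*) = \sum_{s \le t} \hat\alpha_1(s|x^*)
#'       \exp[-\{\hat A_1(s|x^*) + \hat A_2(s|x^*)\}].}
#' Two discretization conventions are provided.  The default
#' `"exponential"` variant exponentiates the cumulative hazards between
#' event times, S(s) = exp(-A1(s) - A2(s)), and allocates each survival
#' drop S(s-) - S(s) to the causes proportionally to their hazard
#' increments; it conserves S + F1 + F2 = 1 exactly, agrees with the
#' continuous-time formula above as the increments shrink, and reduces to
#' 1 - exp(-A1-hat) exactly when the competing cause has no events.  The
#' `"product-limit"` variant replaces the survival factor by the left-limit
#' Aalen-Johansen product, also conserves mass exactly, and reduces to the
#' non-parametric Aalen-Johansen estimator when no covariates are modeled.
#'
#' @param fit1,fit2 `"cr_coxfit"` objects for causes 1 and 2 on the same
#'   data.
#' @param profile one-row data frame with the covariate values x*.
#' @param variant `"exponential"` or `"product-limit"`.
#' @return A `"cif_estimate"` on the pooled event times of both causes,
#'   with the companion `cif2` and `surv` curves attached as attributes.
#' @export
cif_multistate <- function(fit1, fit2, profile,
                           variant = c("exponential", "product-limit")) {
  stopifnot(inherits(fit1, "cr_coxfit"), inherits(fit2, "cr_coxfit"))
  variant <- match.arg(variant)
  times <- sort(unique(c(fit1$baseline$knots, fit2$baseline$knots)))
  dA1 <- numeric(length(times)); dA2 <- numeric(length(times))
  dA1[match(fit1$baseline$knots, times)] <- fit1$baseline$values * exp(lp_for(fit1, profile))
  dA2[match(fit2$baseline$knots, times)] <- fit2$baseline$values * exp(lp_for(fit2, profile))
  if (variant == "exponential") {
    S <- exp(-(cumsum(dA1) + cumsum(dA2)))
    drop <- c(1, S[-length(S)]) - S
    tot <- dA1 + dA2
    frac <- ifelse(tot > 0, dA1 / tot, 0)
    F1 <- cumsum(frac * drop)
    F2 <- cumsum((1 - frac) * drop)
  } else {
    # product-limit: cap the total jump at 1 (a jump past 1 would make the
    # survival product negative), rescaling the cause shares proportionally
    tot <- dA1 + dA2
    scale <- ifelse(tot > 1, 1 / tot, 1)
    Sminus <- cumprod(c(1, 1 - tot * scale))[seq_along(times)]
    F1 <- cumsum(dA1 * scale * Sminus)
    F2 <- cumsum(dA2 * scale * Sminus)
    S <- Sminus * (1 - tot * scale)
  }
  cif_estimate(times, F1, "multistate", profile,
               extra = list(cif2 = F2, surv = S, variant = variant))
}

#' Cumulative incidence via the cause-specific hazard and a reduction factor
#'
#' Multiplies the modeled cause-1 hazard increments by an estimated
#' reduction factor to form subdistribution hazard increments, then
#' transforms: lambda-hat(t|x*) = r-hat(t|x*) alpha1-hat(t|x*) and
#' F1-hat(t|x*) = 1 - exp(-sum of increments).
#'
#' @param fit1 `"cr_coxfit"` for the cause-1 cause-specific hazard.
#' @param rf an `"rf_np"` or `"rf_glm"` reduction-factor estimate.
#' @param profile one-row data frame with the covariate values x*.
#' @param carry_forward carry the last defined reduction-factor value over
#'   flagged (NA) time points instead of erroring.
#' @return A `"cif_estimate"` on the cause-1 event times.
#' @export
cif_subdist_via_rf <- function(fit1, rf, profile, carry_forward = FALSE) {
  stopifnot(inherits(fit1, "cr_coxfit"))
  times <- fit1$baseline$knots
  r <- predict_reduction(rf, times, profile)
  if (anyNA(r)) {
    if (!carry_forward)
      stop("reduction factor undefined at some event times; set carry_forward = TRUE to impute the last defined value")
    for (j in seq_along(r))
      if (is.na(r[j])) r[j] <- if (j == 1) 1 else r[j - 1]
  }
  lam <- r * fit1$baseline$values * exp(lp_for(fit1, profile))
  cif_estimate(times, 1 - exp(-cumsum(lam)), "subdist-rf", profile,
               extra = list(reduction = r))
}

#' Cumulative incidence from a Fine-Gray fit
#'
#' Accumulates the weighted Breslow subdistribution baseline scaled by
#' exp(beta-hat x*) and transforms:
#' F1-hat(t|x*) = 1 - exp(-sum_{t_j <= t} lambda0-hat(t_j) exp(beta x*)).
#'
#' @param fg a `"cr_coxfit"` from [fit_fine_gray()].
#' @param profile one-row data frame with the covariate values x*.
#' @return A `"cif_estimate"` on the cause-1 event times.
#' @export
cif_fine_gray <- function(fg, profile) {
  stopifnot(inherits(fg, "cr_coxfit"))
  lam <- fg$baseline$values * exp(lp_for(fg, profile))
  cif_estimate(fg$baseline$knots, 1 - exp(-cumsum(lam)), "fine-gray", profile)
}

#' Cumulative incidence from the offset route to the Fine-Gray model
#'
#' Uses the cause-specific risk-set denominator with reduction-factor
#' offsets:
#' \deqn{\hat\lambda(t_j|x^*) = \exp(\tilde\beta_{FG} x^*) /
#'   \sum_{k \in R_{CS}(t_j)} \exp[\tilde\beta_{FG} x_k - \log \hat r(t_j|x_k)]}
#' accumulated and transformed by 1 - exp(-sum).  The denominator is exactly
#' the Breslow baseline of the offset fit, so for a categorical covariate
#' with a saturated reduction factor this curve coincides with
#' [cif_fine_gray()].
#'
#' @param fit a `"cr_coxfit"` from [fit_fg_via_offset()].
#' @param profile one-row data frame with the covariate values x*.
#' @return A `"cif_estimate"` on the cause-1 event times.
#' @export
cif_fg_offset <- function(fit, profile) {
  stopifnot(inherits(fit, "cr_coxfit"))
  lam <- fit$baseline$values * exp(lp_for(fit, profile))
  cif_estimate(fit$baseline$knots, 1 - exp(-cumsum(lam)), "fg-offset", profile)
}

# ---- the full pipeline (shared by bootstrap and the illustration) ----------

# rf_spec: list(type = "saturated", by = <col>) or
#          list(type = "glm", link, family, structure, time_varying)
estimate_rf <- function(data, covariates, rf_spec) {
  weighted <- if (any(data$status == 0)) "ipcw" else NULL
  if (identical(rf_spec$type, "saturated")) {
    by <- rf_spec$by
    return(reduction_factor_np(data, by = by, weights = weighted))
  }
  fit_rf_glm(data, covariates = covariates,
             link = rf_spec$link %||% "log",
             family = rf_spec$family %||% "poisson",
             weights = weighted,
             structure = rf_spec$structure %||% "per_time",
             time_varying = isTRUE(rf_spec$time_varying))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cif_pipeline <- function(data, method, covariates, profile, cause = 1L,
                         rf_spec = NULL, variant = "exponential",
                         fixed_rf = NULL) {
  if (cause == 2L) {
    data <- swap_causes(data)
    cause <- 1L
  }
  switch(method,
    "multistate" = {
      f1 <- fit_cox_csh(data, covariates, cause = 1L)
      f2 <- fit_cox_csh(data, covariates, cause = 2L)
      cif_multistate(f1, f2, profile, variant = variant)
    },
    "subdist-rf" = {
      f1 <- fit_cox_csh(data, covariates, cause = 1L)
      rf <- fixed_rf %||% estimate_rf(data, covariates, rf_spec)
      cif_subdist_via_rf(f1, locf_rf(rf, f1$baseline$knots), profile)
    },
    "fine-gray" = {
      fg <- fit_fine_gray(data, covariates, cause = 1L)
      cif_fine_gray(fg, profile)
    },
    "fg-offset" = {
      rf <- fixed_rf %||% estimate_rf(data, covariates, rf_spec)
      fit <- fit_fg_via_offset(data, covariates,
                               rf = locf_rf(rf, event_time_grid(data, 1L)))
      cif_fg_offset(fit, profile)
    },
    stop("unknown method: ", method))
}

# re-express a reduction-factor estimate on a new event-time grid by
# right-continuous last-value-carried lookup (r = 1 before the first fitted
# time).  Needed when a fixed reduction factor is reused on resampled data
# whose event times differ from the original grid.  No-op when the grids
# already match.
locf_rf <- function(rf, times) {
  if (inherits(rf, "rf_np")) {
    if (isTRUE(all.equal(rf$event_times, times))) return(rf)
    idx <- findInterval(times, rf$event_times)
    vals <- cbind(1, rf$values)[, idx + 1L, drop = FALSE]
    res <- rf
    res$event_times <- times
    res$values <- matrix(vals, nrow = length(rf$levels),
                         dimnames = list(rf$levels, NULL))
    return(res)
  }
  if (inherits(rf, "rf_glm") && rf$structure == "per_time") {
    if (isTRUE(all.equal(rf$event_times, times))) return(rf)
    ok_t <- rf$event_times[rf$ok]
    ok_c <- rf$coef[rf$ok, , drop = FALSE]
    idx <- findInterval(times, ok_t)
    first <- c(0, rep(0, ncol(rf$coef) - 1)) # r = 1, no covariate effect
    if (rf$link != "log") first[1] <- stats::make.link(rf$link)$linkfun(1 - 1e-12)
    co <- rbind(first, ok_c)[idx + 1L, , drop = FALSE]
    res <- rf
    res$event_times <- times
    res$coef <- co
    res$ok <- rep(TRUE, length(times))
    return(res)
  }
  rf # pooled GLM evaluates anywhere
}

#' Bootstrap standard errors for a cumulative incidence curve
#'
#' Nonparametric subject-level resampling: draws B bootstrap samples of
#' subjects with replacement, re-runs the full estimation pipeline of the
#' chosen method in each (tie-breaking included), evaluates every replicate
#' curve on a fixed grid by right-continuous step interpolation, and
#' reports the pointwise standard deviation.  By default the
#' reduction-factor model (where the method uses one) is re-estimated
#' inside each replicate so its uncertainty is propagated;
#' `mode = "fixed-rf"` reuses the reduction factor estimated once on the
#' original data, mimicking analyses that treat it as known.
#'
#' @param data a tie-free [crdata()] object.
#' @param method `"multistate"`, `"subdist-rf"`, `"fine-gray"` or
#'   `"fg-offset"`.
#' @param covariates covariate column names for the hazard models.
#' @param profile one-row data frame of covariate values x*.
#' @param B number of bootstrap replicates (>= 2).
#' @param seed integer seed.
#' @param grid evaluation time grid; defaults to the cause-1 event times of
#'   the original data.
#' @param cause cause of interest.
#' @param rf_spec reduction-factor specification for methods that need one:
#'   `list(type = "saturated", by = <column>)` or `list(type = "glm",
#'   link =, family =, structure =, time_varying =)`.
#' @param variant multistate convention, see [cif_multistate()].
#' @param mode `"refit"` or `"fixed-rf"`.
#' @return A data frame `time`, `se`, with the replicate curves in attribute
#'   `"replicates"` and the number of failed replicates in `"n_failed"`.
#' @export
bootstrap_se <- function(data, method, covariates, profile, B = 200L,
                         seed = 1L, grid = NULL, cause = 1L, rf_spec = NULL,
                         variant = "exponential", mode = c("refit", "fixed-rf")) {
  stopifnot(inherits(data, "crdata"), B >= 2)
  mode <- match.arg(mode)
  if (is.null(grid)) {
    gd <- if (cause == 2L) swap_causes(data) else data
    grid <- event_time_grid(gd, 1L)
  }
  fixed <- NULL
  if (mode == "fixed-rf" && method %in% c("subdist-rf", "fg-offset")) {
    gd <- if (cause == 2L) swap_causes(data) else data
    fixed <- estimate_rf(gd, covariates, rf_spec)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, B)
  curves <- matrix(NA_real_, B, length(grid))
  failed <- 0L
  for (b in seq_len(B)) {
    rows <- sample.int(nrow(data), nrow(data), replace = TRUE)
    boot <- as_crdata(as.data.frame(data)[rows, , drop = FALSE])
    boot <- break_ties(boot, seed = rep_seeds[b])
    est <- tryCatch(
      cif_pipeline(boot, method, covariates, profile, cause = cause,
                   rf_spec = rf_spec, variant = variant, fixed_rf = fixed),
      error = function(e) NULL)
    if (is.null(est)) failed <- failed + 1L else curves[b, ] <- cif_at(est, grid)
  }
  if (failed > 0.1 * B)
    stop(sprintf("bootstrap failed in %d of %d replicates", failed, B))
  out <- data.frame(time = grid,
                    se = apply(curves, 2, stats::sd, na.rm = TRUE))
  attr(out, "replicates") <- curves
  attr(out, "n_failed") <- failed
  out
}
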