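# ---- design-matrix helpers -------------------------------------------------

# covariate design without intercept, remembering factor codings so that
# profiles and bootstrap resamples are coded identically
build_design <- function(data, covariates) {
  if (length(covariates) == 0) {
    return(list(X = matrix(0, nrow(data), 0), terms = NULL, xlev = NULL))
  }
  miss <- setdiff(covariates, names(data))
  if (length(miss))
    stop(sprintf("covariate column(s) not found: %s", paste(miss, collapse = ", ")))
  df <- as.data.frame(data)[covariates]
  mf <- stats::model.frame(~ ., data = df)
  tm <- attr(mf, "terms")
  X <- stats::model.matrix(tm, mf)
  list(X = X[, -1, drop = FALSE], terms = tm, xlev = stats::.getXlevels(tm, mf))
}

design_for <- function(design, newdata) {
  if (is.null(design$terms)) return(matrix(0, nrow(newdata), 0))
  mf <- stats::model.frame(stats::delete.response(design$terms),
                           as.data.frame(newdata), xlev = design$xlev)
  stats::model.matrix(stats::delete.response(design$terms), mf,
                      xlev = design$xlev)[, -1, drop = FALSE]
}

# ---- offset models ---------------------------------------------------------

#' Offset model from a reduction-factor estimate
#'
#' Wraps a saturated non-parametric reduction factor ([reduction_factor_np()])
#' or a fitted GLM ([fit_rf_glm()]) as the time- and covariate-dependent
#' offset o(t, x) = -log r(t | x) used by the cause-specific partial
#' likelihood route to the Fine-Gray coefficient.
#'
#' @param rf an `"rf_np"` or `"rf_glm"` object.
#' @return An object of class `"offset_model"` whose `eval(t, newdata)`
#'   method returns the offset for each row of `newdata` at time `t`.
#' @export
as_offset_model <- function(rf) {
  if (inherits(rf, "offset_model")) return(rf)
  if (inherits(rf, "rf_np")) {
    if (is.null(rf$by))
      return(structure(list(
        eval = function(t, newdata) {
          j <- match(t, rf$event_times)
          if (is.na(j)) stop("offset requested off the reduction-factor grid")
          rep(-log(rf$values[1, j]), nrow(newdata))
        }, provenance = "saturated"), class = "offset_model"))
    return(structure(list(
      eval = function(t, newdata) {
        j <- match(t, rf$event_times)
        if (is.na(j)) stop("offset requested off the reduction-factor grid")
        v <- rf_np_value(rf, newdata[[rf$by]], rep(j, nrow(newdata)))
        if (anyNA(v) || any(v <= 0))
          stop("reduction factor undefined or zero where an offset is needed")
        -log(v)
      }, provenance = "saturated"), class = "offset_model"))
  }
  if (inherits(rf, "rf_glm")) {
    return(structure(list(
      eval = function(t, newdata) {
        v <- predict_reduction(rf, t, newdata)
        if (anyNA(v) || any(v <= 0))
          stop("reduction factor undefined or zero where an offset is needed")
        -log(v)
      }, provenance = "glm"), class = "offset_model"))
  }
  stop("cannot build an offset model from an object of class ",
       paste(class(rf), collapse = "/"))
}

# ---- the partial-likelihood engine ----------------------------------------

# Generic risk-set pass: Breslow-type partial likelihood over precomputed
# risk sets (list(idx, w, off) per event time, ev_pos the event row's
# position inside idx).  Used whenever a time- and covariate-dependent
# offset makes the denominators irreducible; O(m n) per evaluation.
riskset_pass <- function(X, risksets, ev_pos) {
  p <- ncol(X)
  m <- length(risksets)
  function(beta, derivs = TRUE) {
    ll <- 0
    U <- numeric(p); I <- matrix(0, p, p)
    S0v <- numeric(m)
    for (j in seq_len(m)) {
      rs <- risksets[[j]]
      xs <- X[rs$idx, , drop = FALSE]
      eta <- if (p > 0) drop(xs %*% beta) + rs$off else rs$off
      z <- rs$w * exp(eta)
      S0 <- sum(z)
      S0v[j] <- S0
      ll <- ll + unname(eta[ev_pos[j]]) - log(S0)
      if (derivs && p > 0) {
        S1 <- colSums(z * xs)
        m1 <- S1 / S0
        U <- U + xs[ev_pos[j], ] - m1
        I <- I + crossprod(xs, z * xs) / S0 - tcrossprod(m1)
      }
    }
    list(ll = ll, U = U, I = I, S0 = S0v)
  }
}

# Fast pass via cumulative sums, O(n p^2) per evaluation.  The denominator
# at cause-1 event time t_j is
#   S0(t_j) = sum_{T_i >= t_j} z_i + G(t_j) * sum_{competing, T_i < t_j} z_i / G(T_i-)
# (the second term only for the Fine-Gray extended risk sets); both terms
# are suffix/prefix sums over time-sorted subjects, and the same structure
# holds for the score (S1) and information (S2) numerators.
#
# D: cause-1 event times (ascending); ev_x: covariate rows of the subjects
# failing at D; Ts/Xs: all subjects sorted by time; T2s/X2s/invG2: competing
# subjects sorted by time with 1/G(T-); Gt: G at D (1 when censoring-free).
fast_pl_structures <- function(data, X, D, extended = FALSE, G = NULL) {
  ord <- order(data$time)
  Ts <- data$time[ord]
  Xs <- X[ord, , drop = FALSE]
  ev_rows <- event_rows_for(data, D)
  st <- list(Ts = Ts, Xs = Xs, ev_x = X[ev_rows, , drop = FALSE],
             pos = findInterval(D, Ts, left.open = TRUE) + 1L,
             n = nrow(X), p = ncol(X), m = length(D),
             extended = extended)
  if (extended) {
    comp <- which(data$status == 2)
    comp <- comp[order(data$time[comp])]
    st$T2s <- data$time[comp]
    st$X2s <- X[comp, , drop = FALSE]
    st$invG2 <- if (is.null(G)) rep(1, length(comp))
                else 1 / eval_step(G, st$T2s, side = "left")
    st$k2 <- findInterval(D, st$T2s, left.open = TRUE) # competing with T < t
    st$Gt <- if (is.null(G)) rep(1, length(D)) else eval_step(G, D)
  }
  st
}

rev_cumsum <- function(x) rev(cumsum(rev(x)))

# row index of the cause-1 event at each event time; censored observations
# may share an event's time, so the lookup is restricted to cause-1 rows
event_rows_for <- function(data, D) {
  e <- which(data$status == 1L)
  e[match(D, data$time[e])]
}

fast_pass <- function(st) {
  p <- st$p
  # upper-triangle index pairs for the information matrix
  ut <- which(upper.tri(diag(max(p, 1)), diag = TRUE), arr.ind = TRUE)
  function(beta, derivs = TRUE) {
    eta <- if (p > 0) drop(st$Xs %*% beta) else numeric(st$n)
    z <- exp(eta)
    S0 <- rev_cumsum(z)[st$pos]
    S1 <- NULL; S2 <- NULL
    if (derivs && p > 0) {
      S1 <- vapply(seq_len(p),
                   function(k) rev_cumsum(z * st$Xs[, k])[st$pos],
                   numeric(st$m))
      S2 <- vapply(seq_len(nrow(ut)), function(i)
        rev_cumsum(z * st$Xs[, ut[i, 1]] * st$Xs[, ut[i, 2]])[st$pos],
        numeric(st$m))
      S1 <- matrix(S1, st$m, p)
      S2 <- matrix(S2, st$m, nrow(ut))
    }
    if (st$extended && length(st$T2s) > 0) {
      z2 <- exp(if (p > 0) drop(st$X2s %*% beta) else numeric(length(st$T2s))) *
        st$invG2
      add <- st$Gt * c(0, cumsum(z2))[st$k2 + 1L]
      S0 <- S0 + add
      if (derivs && p > 0) {
        for (k in seq_len(p))
          S1[, k] <- S1[, k] +
            st$Gt * c(0, cumsum(z2 * st$X2s[, k]))[st$k2 + 1L]
        for (i in seq_len(nrow(ut)))
          S2[, i] <- S2[, i] +
            st$Gt * c(0, cumsum(z2 * st$X2s[, ut[i, 1]] * st$X2s[, ut[i, 2]]))[st$k2 + 1L]
      }
    }
    ev_eta <- if (p > 0) drop(st$ev_x %*% beta) else numeric(st$m)
    ll <- sum(ev_eta) - sum(log(S0))
    U <- numeric(p); I <- matrix(0, p, p)
    if (derivs && p > 0) {
      M1 <- S1 / S0
      U <- colSums(st$ev_x) - colSums(M1)
      Ifull <- matrix(0, p, p)
      s2sums <- colSums(S2 / S0)
      for (i in seq_len(nrow(ut))) {
        Ifull[ut[i, 1], ut[i, 2]] <- s2sums[i]
        Ifull[ut[i, 2], ut[i, 1]] <- s2sums[i]
      }
      I <- Ifull - crossprod(M1)
    }
    list(ll = ll, U = U, I = I, S0 = S0)
  }
}

# Newton-Raphson with step-halving on any partial-likelihood pass
newton_cox <- function(pass, p, init = NULL,
                       tol_score = 1e-9, tol_loglik = 1e-12, max_iter = 50L) {
  beta <- if (is.null(init)) numeric(p) else init
  if (p == 0) {
    return(list(coefficients = numeric(0), vcov = matrix(0, 0, 0),
                loglik = pass(beta, derivs = FALSE)$ll, iterations = 0L,
                converged = TRUE, flag = "none", pass = pass))
  }
  cur <- pass(beta)
  flag <- "none"; converged <- FALSE; iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(cur$U)) <= tol_score) { converged <- TRUE; break }
    step <- tryCatch(solve(cur$I, cur$U), error = function(e) NULL)
    if (is.null(step)) { flag <- "singular-information"; break }
    hal <- 0
    repeat {
      cand <- beta + step
      nxt <- pass(cand)
      if (is.finite(nxt$ll) && nxt$ll >= cur$ll - 1e-12) break
      step <- step / 2; hal <- hal + 1
      if (hal > 30) { flag <- "step-halving-failed"; break }
    }
    if (flag != "none") break
    rel <- abs(nxt$ll - cur$ll) / (abs(cur$ll) + 1e-12)
    beta <- cand; cur <- nxt
    if (max(abs(beta)) > 15) { flag <- "monotone-likelihood"; break }
    if (rel <= tol_loglik && max(abs(cur$U)) <= tol_score) {
      converged <- TRUE; break
    }
  }
  if (!converged && flag == "none" && max(abs(cur$U)) <= tol_score)
    converged <- TRUE
  vc <- tryCatch(solve(cur$I), error = function(e) matrix(NA_real_, p, p))
  list(coefficients = beta, vcov = vc, loglik = cur$ll, iterations = iter,
       converged = converged, flag = flag, pass = pass)
}

# fit on a cause with zero observed events: empty baseline, null coefficients
empty_coxfit <- function(des, cause, type) {
  p <- ncol(des$X)
  cf <- stats::setNames(rep(0, p), colnames(des$X))
  structure(list(coefficients = cf,
                 vcov = matrix(NA_real_, p, p,
                               dimnames = list(colnames(des$X), colnames(des$X))),
                 baseline = step_function(numeric(0), numeric(0), left_value = 0),
                 loglik = 0, iterations = 0L, converged = TRUE,
                 flag = "no-events", type = type, design = des, cause = cause),
            class = "cr_coxfit")
}

cr_coxfit <- function(nr, D, S0, cf_names, type, extra = list()) {
  cf <- nr$coefficients
  names(cf) <- cf_names
  vc <- nr$vcov
  if (length(cf)) dimnames(vc) <- list(cf_names, cf_names)
  structure(c(list(coefficients = cf, vcov = vc,
                   baseline = step_function(D, 1 / S0, left_value = 0),
                   loglik = nr$loglik, iterations = nr$iterations,
                   converged = nr$converged, flag = nr$flag, type = type),
              extra),
            class = "cr_coxfit")
}

#' @export
print.cr_coxfit <- function(x, ...) {
  cat(sprintf("%s partial-likelihood fit (%s)\n", x$type,
              if (x$converged) sprintf("converged in %d iterations", x$iterations)
              else paste("NOT converged:", x$flag)))
  if (length(x$coefficients)) {
    se <- sqrt(diag(x$vcov))
    print(data.frame(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
                     se = se, z = x$coefficients / se, check.names = FALSE))
  }
  cat("log partial likelihood:", format(x$loglik), "\n")
  invisible(x)
}

# ---- cause-specific Cox model (with optional time-dependent offset) --------

#' Cox model for a cause-specific hazard, with optional reduction-factor offset
#'
#' Maximizes the cause-specific partial likelihood over the usual risk sets
#' \{T_i >= t\}, censoring the competing events, by Newton-Raphson with
#' step-halving (score tolerance 1e-9).  An optional offset o(t, x), re-
#' evaluated for every risk-set member at every event time, enters the
#' linear predictor; with o = -log r(t|x) from an estimated reduction
#' factor this turns the cause-specific fit into an estimator of the
#' Fine-Gray coefficient (see [fit_fg_via_offset()]).
#'
#' @param data a tie-free [crdata()] object.
#' @param covariates character vector of covariate column names (factors are
#'   dummy-coded against their first level).
#' @param cause the cause whose hazard is modeled (1 or 2).
#' @param offset an `"offset_model"` (see [as_offset_model()]), or `NULL`.
#' @param weights optional [ipcw_weights()] matrix applied to the risk-set
#'   denominator terms (rarely needed for the cause-specific fit).
#' @param init optional starting coefficients.
#' @return A `"cr_coxfit"`: coefficients, inverse-information covariance,
#'   Breslow baseline hazard increments
#'   1 / sum_k exp(beta x_k + o(t_j, x_k)), log partial likelihood and
#'   convergence information.
#' @export
fit_cox_csh <- function(data, covariates = character(0), cause = 1L,
                        offset = NULL, weights = NULL, init = NULL) {
  stopifnot(inherits(data, "crdata"), cause %in% c(1L, 2L))
  stop_if_ties(data, "fit_cox_csh")
  if (cause == 2L) data <- swap_causes(data)
  des <- build_design(data, covariates)
  D <- event_time_grid(data, 1L)
  if (length(D) == 0) return(empty_coxfit(des, cause, "cause-specific Cox"))
  ev_rows <- event_rows_for(data, D)
  om <- if (is.null(offset)) NULL else as_offset_model(offset)
  if (is.null(om) && is.null(weights)) {
    # plain cause-specific PL: cumulative-sum fast path
    pass <- fast_pass(fast_pl_structures(data, des$X, D))
  } else {
    risksets <- vector("list", length(D))
    ev_pos <- integer(length(D))
    for (j in seq_along(D)) {
      t <- D[j]
      idx <- which(data$time >= t)
      w <- rep(1, length(idx))
      if (inherits(weights, "weight_matrix")) {
        jj <- match(t, weights$event_times)
        if (!is.na(jj)) w <- weights$w[idx, jj]
      }
      off <- if (is.null(om)) rep(0, length(idx))
             else om$eval(t, data[idx, , drop = FALSE])
      risksets[[j]] <- list(idx = idx, w = w, off = off)
      ev_pos[j] <- match(ev_rows[j], idx)
    }
    pass <- riskset_pass(des$X, risksets, ev_pos)
  }
  nr <- newton_cox(pass, ncol(des$X), init = init)
  S0 <- pass(nr$coefficients, derivs = FALSE)$S0
  cr_coxfit(nr, D, S0, colnames(des$X),
            type = if (is.null(om)) "cause-specific Cox"
                   else "cause-specific Cox with reduction-factor offset",
            extra = list(design = des, cause = cause,
                         offset_provenance = if (is.null(om)) NULL else om$provenance))
}

# ---- weighted Fine-Gray fit ------------------------------------------------

#' Fine-Gray model by IPCW-weighted partial likelihood on extended risk sets
#'
#' Maximizes the Fine-Gray partial likelihood in which subjects with an
#' observed competing event remain in the risk set after their event, with
#' inverse-probability-of-censoring weights G(t)/G(T_i-) (reverse
#' Kaplan-Meier G) discounting them for unobservable censoring.  Without
#' censoring all weights are 1 and the fit is the classic extended-risk-set
#' partial likelihood; without competing events it coincides with the
#' cause-specific Cox fit.
#'
#' @inheritParams fit_cox_csh
#' @return A `"cr_coxfit"` whose baseline increments are the weighted
#'   Breslow subdistribution baseline
#'   1 / sum_i Y_FG,i(t_j) w_i(t_j) exp(beta x_i).
#' @export
fit_fine_gray <- function(data, covariates = character(0), cause = 1L,
                          init = NULL) {
  stopifnot(inherits(data, "crdata"), cause %in% c(1L, 2L))
  stop_if_ties(data, "fit_fine_gray")
  if (cause == 2L) data <- swap_causes(data)
  des <- build_design(data, covariates)
  D <- event_time_grid(data, 1L)
  if (length(D) == 0)
    return(empty_coxfit(des, cause, "Fine-Gray (weighted extended risk sets)"))
  G <- if (any(data$status == 0)) reverse_km(data) else NULL
  pass <- fast_pass(fast_pl_structures(data, des$X, D, extended = TRUE, G = G))
  nr <- newton_cox(pass, ncol(des$X), init = init)
  S0 <- pass(nr$coefficients, derivs = FALSE)$S0
  cr_coxfit(nr, D, S0, colnames(des$X), type = "Fine-Gray (weighted extended risk sets)",
            extra = list(design = des, cause = cause))
}

#' Fine-Gray coefficient via the cause-specific partial likelihood with offset
#'
#' Estimates the Fine-Gray coefficient without ever forming the extended
#' risk set: plugs o(t, x) = -log r-hat(t | x) from an estimated reduction
#' factor into the cause-specific partial likelihood as a time-dependent
#' offset.  When `rf` is a saturated (per-level, IPCW-weighted when
#' censored) estimate for a categorical covariate, the maximizer is exactly
#' the Fine-Gray partial-likelihood estimate.  The identity presumes every
#' covariate level represented in the extended risk set is still
#' represented in the cause-specific risk set at each cause-1 event time
#' (equivalently, the saturated r-hat is strictly positive wherever
#' defined); when a level's cause-specific risk set empties first the
#' required offset -log(0) is degenerate and the fit refuses with an
#' error.  The condition holds whenever follow-up ends, administratively
#' or by censoring, while all levels are still represented.
#'
#' @inheritParams fit_cox_csh
#' @param rf a saturated `"rf_np"` estimate, an `"rf_glm"` fit, or an
#'   `"offset_model"`.
#' @return A `"cr_coxfit"`; its baseline increments are the offset-adjusted
#'   Breslow increments, which estimate the subdistribution baseline hazard.
#' @export
fit_fg_via_offset <- function(data, covariates, rf, cause = 1L, init = NULL) {
  if (inherits(rf, "rf_np") && any(rf$values == 0, na.rm = TRUE))
    stop("degenerate offset: the saturated reduction factor is 0 at some ",
         "event time/level (a covariate level has left the cause-specific ",
         "risk set while remaining in the extended risk set)")
  fit <- fit_cox_csh(data, covariates, cause = cause,
                     offset = as_offset_model(rf), init = init)
  fit$type <- "Fine-Gray via cause-specific PL with offset"
  fit$rf <- rf
  fit
}

#' Fine-Gray vs offset-route agreement
#'
#' Fits [fit_fine_gray()] and [fit_fg_via_offset()] (with the saturated,
#' IPCW-weighted reduction factor for the given categorical covariate) on
#' the same data and reports the largest absolute coefficient discrepancy.
#' The two routes maximize algebraically identical criteria, so the
#' discrepancy is solver noise; this function is used as a regression
#' (equivalence) check.
#'
#' @param data a tie-free [crdata()] object.
#' @param covariate name of a categorical (factor or character) column.
#' @return The sup-norm coefficient difference, with both fits attached as
#'   attributes `"fg"` and `"offset"`.
#' @export
equivalence_report <- function(data, covariate) {
  stopifnot(inherits(data, "crdata"))
  x <- data[[covariate]]
  if (is.null(x)) stop(sprintf("column '%s' not found", covariate))
  if (!(is.factor(x) || is.character(x) || is.logical(x)))
    stop("the offset-route equivalence holds for categorical covariates; refusing a continuous covariate")
  data[[covariate]] <- factor(x)
  weighted <- if (any(data$status == 0)) "ipcw" else NULL
  rf <- reduction_factor_np(data, by = covariate, weights = weighted)
  fg <- fit_fine_gray(data, covariates = covariate)
  off <- fit_fg_via_offset(data, covariates = covariate, rf = rf)
  d <- max(abs(fg$coefficients - off$coefficients))
  attr(d, "fg") <- fg
  attr(d, "offset") <- off
  d
}

# ---- GLM models for the reduction factor ----------------------------------

#' GLM models for the reduction factor
#'
#' Within the extended risk set at each cause-1 event time t_j, the
#' indicator Y_i = 1\{T_i >= t_j\} has mean r(t_j | x_i), so r can be
#' modeled by binomial (or, following the working-likelihood trick, Poisson)
#' GLMs with log, logit or cloglog links, with IPCW case weights.  Two
#' structures are available: `"per_time"` fits one weighted GLM per event
#' time (separate intercept and covariate effects gamma_j, the richest
#' model short of saturation), `"pooled"` stacks all risk sets into one fit
#' with a natural cubic spline in log t for the baseline gamma_0(t)
#' (interior knots at the 0.25/0.5/0.75 quantiles of the event times) and,
#' optionally, spline-by-covariate interactions for time-varying effects.
#' Pooled risk sets are treated as independent (GEE working independence);
#' robust (sandwich, clustered on subject) standard errors are attached when
#' `robust = TRUE` and the sandwich package is installed.
#'
#' @param data a tie-free [crdata()] object.
#' @param covariates character vector of covariate columns (possibly empty).
#' @param link `"log"`, `"logit"` or `"cloglog"`.
#' @param family `"poisson"` (log link only, tolerates fitted means above 1)
#'   or `"binomial"`.
#' @param weights `NULL` (censoring-free data only) or `"ipcw"`.
#' @param structure `"per_time"` or `"pooled"`.
#' @param time_varying for `"pooled"`, interact covariates with the spline
#'   basis.
#' @param robust attach cluster-robust coefficient covariances (pooled fit).
#' @return An object of class `"rf_glm"`; use [predict_reduction()] to
#'   evaluate fitted r-hat(t | x) (clipped to (0, 1]).
#' @export
fit_rf_glm <- function(data, covariates = character(0),
                       link = c("log", "logit", "cloglog"),
                       family = c("poisson", "binomial"),
                       weights = NULL,
                       structure = c("per_time", "pooled"),
                       time_varying = FALSE, robust = FALSE) {
  stopifnot(inherits(data, "crdata"))
  stop_if_ties(data, "fit_rf_glm")
  link <- match.arg(link)
  family <- match.arg(family)
  struct <- match.arg(structure)
  if (family == "poisson" && link != "log")
    stop("the Poisson working likelihood is used with the log link")
  censored <- any(data$status == 0)
  if (censored && is.null(weights))
    stop("data contain censored observations; use weights = \"ipcw\"")
  fam <- if (family == "poisson") stats::poisson(link = "log")
         else stats::binomial(link = link)
  tj <- event_time_grid(data, 1L)
  G <- if (identical(weights, "ipcw")) reverse_km(data) else NULL
  Gt <- if (is.null(G)) rep(1, length(tj)) else eval_step(G, tj)
  Gleft <- if (is.null(G)) rep(1, nrow(data))
           else eval_step(G, data$time, side = "left")
  des <- build_design(data, covariates)
  p <- ncol(des$X)

  member_w <- function(j) {
    t <- tj[j]
    atrisk <- data$time >= t
    past2 <- data$status == 2 & data$time < t
    idx <- which(atrisk | past2)
    w <- ifelse(atrisk[idx], 1, Gt[j] / Gleft[idx])
    keep <- w > 0
    list(idx = idx[keep], w = w[keep], y = as.numeric(atrisk[idx][keep]))
  }

  if (struct == "per_time") {
    coef <- matrix(NA_real_, length(tj), p + 1,
                   dimnames = list(NULL, c("(Intercept)", colnames(des$X))))
    ok <- logical(length(tj))
    for (j in seq_along(tj)) {
      mw <- member_w(j)
      Xj <- cbind(1, des$X[mw$idx, , drop = FALSE])
      fit <- tryCatch(
        suppressWarnings(stats::glm.fit(Xj, mw$y, weights = mw$w, family = fam)),
        error = function(e) NULL)
      if (!is.null(fit) && fit$converged && all(is.finite(fit$coefficients))) {
        coef[j, ] <- fit$coefficients
        ok[j] <- TRUE
      }
    }
    if (!all(ok))
      warning(sprintf("%d of %d per-time reduction-factor fits failed; their coefficients are NA",
                      sum(!ok), length(ok)))
    res <- list(structure = "per_time", link = link, family = family,
                event_times = tj, coef = coef, ok = ok,
                design = des, weighted = censored)
    class(res) <- "rf_glm"
    return(res)
  }

  # pooled fit: stacked risk sets with spline baseline in log t
  rows <- lapply(seq_along(tj), member_w)
  nrow_j <- vapply(rows, function(r) length(r$idx), integer(1))
  idx_all <- unlist(lapply(rows, `[[`, "idx"))
  y_all <- unlist(lapply(rows, `[[`, "y"))
  w_all <- unlist(lapply(rows, `[[`, "w"))
  t_all <- rep(tj, nrow_j)
  knots <- stats::quantile(tj, c(0.25, 0.5, 0.75), names = FALSE)
  bknots <- range(log(tj))
  basis <- splines::ns(log(t_all), knots = log(knots), Boundary.knots = bknots)
  Xc <- des$X[idx_all, , drop = FALSE]
  M <- cbind(1, basis, Xc)
  nm <- c("(Intercept)", paste0("ns", seq_len(ncol(basis))), colnames(des$X))
  if (time_varying && p > 0) {
    for (k in seq_len(p)) {
      M <- cbind(M, basis * Xc[, k])
      nm <- c(nm, paste0(colnames(des$X)[k], ":ns", seq_len(ncol(basis))))
    }
  }
  colnames(M) <- nm
  fit <- suppressWarnings(stats::glm.fit(M, y_all, weights = w_all, family = fam))
  vcov_rob <- NULL
  if (robust) {
    if (requireNamespace("sandwich", quietly = TRUE)) {
      gf <- suppressWarnings(stats::glm(y_all ~ M - 1, family = fam,
                                        weights = w_all))
      vcov_rob <- sandwich::vcovCL(gf, cluster = idx_all)
      rownames(vcov_rob) <- colnames(vcov_rob) <- nm
    } else {
      warning("package 'sandwich' not available; robust covariances omitted")
    }
  }
  res <- list(structure = "pooled", link = link, family = family,
              event_times = tj, coef = stats::setNames(fit$coefficients, nm),
              knots = knots, bknots = bknots, time_varying = time_varying,
              design = des, weighted = censored, vcov_robust = vcov_rob)
  class(res) <- "rf_glm"
  res
}

#' @export
print.rf_glm <- function(x, ...) {
  cat(sprintf("Reduction-factor GLM (%s, %s family, %s link%s)\n",
              x$structure, x$family, x$link,
              if (x$weighted) ", IPCW-weighted" else ""))
  if (x$structure == "per_time")
    cat(sprintf("  %d event times, %d fits converged\n",
                length(x$event_times), sum(x$ok)))
  else
    print(round(x$coef, 4))
  invisible(x)
}

#' Evaluate a fitted reduction-factor model
#'
#' Returns r-hat(t | x) for rows of `newdata` at the requested cause-1 event
#' times, clipped to (0, 1].  For per-time fits `t` must lie on the event
#' time grid the model was fitted on; flagged (failed) time points give `NA`.
#'
#' @param object an `"rf_glm"` or `"rf_np"` object.
#' @param t event time(s) at which to evaluate.
#' @param newdata data frame with the covariate columns (one row, or one row
#'   per element of `t`).
#' @return Numeric vector of fitted reduction factors.
#' @export
predict_reduction <- function(object, t, newdata) {
  UseMethod("predict_reduction")
}

#' @export
predict_reduction.rf_np <- function(object, t, newdata) {
  j <- match(t, object$event_times)
  if (anyNA(j)) stop("time off the reduction-factor grid")
  if (is.null(object$by)) return(object$values[1, j])
  lv <- newdata[[object$by]]
  if (nrow(newdata) == 1) lv <- rep(lv, length(j))
  rf_np_value(object, lv, j)
}

#' @export
predict_reduction.rf_glm <- function(object, t, newdata) {
  linkinv <- stats::make.link(object$link)$linkinv
  Xn <- design_for(object$design, newdata)
  # broadcast: either one profile over many times, or one time over many rows
  if (nrow(Xn) == 1 && length(t) > 1)
    Xn <- Xn[rep(1, length(t)), , drop = FALSE]
  if (length(t) == 1 && nrow(Xn) > 1)
    t <- rep(t, nrow(Xn))
  if (length(t) != nrow(Xn))
    stop("'t' and 'newdata' lengths are incompatible")
  if (object$structure == "per_time") {
    j <- match(t, object$event_times)
    if (anyNA(j)) stop("time off the reduction-factor grid")
    eta <- object$coef[j, 1] +
      if (ncol(Xn)) rowSums(object$coef[j, -1, drop = FALSE] * Xn) else 0
    return(pmin(linkinv(eta), 1))
  }
  basis <- splines::ns(log(t), knots = log(object$knots),
                       Boundary.knots = object$bknots)
  M <- cbind(1, basis, Xn)
  if (object$time_varying && ncol(Xn) > 0)
    for (k in seq_len(ncol(Xn))) M <- cbind(M, basis * Xn[, k])
  pmin(linkinv(drop(M %*% object$coef)), 1)
}
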