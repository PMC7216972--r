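#' Reverse Kaplan-Meier estimate of the censoring distribution
#'
#' Product-limit estimator of G(t) = P(C > t) obtained by swapping the roles
#' of events and censorings: censored records (status 0) act as "events",
#' observed events of either cause act as "censorings".  Computed with
#' [survival::survfit()] and wrapped as a right-continuous
#' [step_function()], so both G(t) and the left limit G(t-) needed by the
#' censoring weights are available.
#'
#' @param data a [crdata()] object with at least one observation.
#' @return A [step_function()] with G(0) = 1.
#' @export
reverse_km <- function(data) {
  stopifnot(inherits(data, "crdata"))
  if (nrow(data) == 0) stop("empty data")
  if (!any(data$status == 0))
    return(step_function(numeric(0), numeric(0), left_value = 1))
  fit <- survival::survfit(survival::Surv(time, status == 0) ~ 1,
                           data = as.data.frame(data))
  keep <- fit$n.event > 0
  step_function(fit$time[keep], fit$surv[keep], left_value = 1)
}

# sorted distinct event times for a cause (tie-free data: all times distinct)
event_time_grid <- function(data, cause = 1L) {
  sort(data$time[data$status == cause])
}

#' Inverse probability of censoring weights
#'
#' Time-dependent weights w_i(t) = delta_i(t) G(t) / G(min(T_i-, t)) that
#' upweight subjects with an observed competing event so the weighted
#' extended (Fine-Gray) risk set represents what would be observed without
#' censoring: w_i(t) = 1 while subject i is still under observation
#' (T_i >= t), w_i(t) = G(t) / G(T_i-) after an observed competing event,
#' and w_i(t) = 0 after censoring (and after an observed cause-1 event,
#' whose subject leaves the extended risk set).
#'
#' @param data a [crdata()] object.
#' @param G censoring survival curve from [reverse_km()]; computed from
#'   `data` when `NULL`.
#' @param event_times evaluation grid, by default the observed cause-1 event
#'   times.
#' @return An object of class `"weight_matrix"`: subjects in rows, event
#'   times in columns.
#' @export
ipcw_weights <- function(data, G = NULL, event_times = NULL) {
  stopifnot(inherits(data, "crdata"))
  if (is.null(G)) G <- reverse_km(data)
  if (is.null(event_times)) event_times <- event_time_grid(data, 1L)
  m <- length(event_times)
  n <- nrow(data)
  Gt <- eval_step(G, event_times)
  Gleft <- eval_step(G, data$time, side = "left")
  if (any(data$status == 2 & Gleft == 0))
    stop("degenerate censoring tail: G(Ti-) = 0 for an observed competing event")
  w <- matrix(0, n, m)
  for (j in seq_len(m)) {
    t <- event_times[j]
    atrisk <- data$time >= t
    w[atrisk, j] <- 1
    past2 <- data$status == 2 & data$time < t
    w[past2, j] <- Gt[j] / Gleft[past2]
  }
  structure(list(event_times = event_times, w = w), class = "weight_matrix")
}

#' Cause-specific Nelson-Aalen hazard increments
#'
#' Increment 1 / #\{T_i >= t\} at each observed event time of the requested
#' cause (tie-free data), i.e. the jumps of the Nelson-Aalen estimator of
#' the cause-specific cumulative hazard.
#'
#' @param data a tie-free [crdata()] object.
#' @param cause 1 or 2.
#' @return A [step_function()] whose `values` are the increments
#'   (use [cumulate_step()] for the cumulative hazard).
#' @export
nelson_aalen_cs <- function(data, cause = 1L) {
  stopifnot(inherits(data, "crdata"), cause %in% c(1L, 2L))
  stop_if_ties(data, "nelson_aalen_cs")
  tj <- event_time_grid(data, cause)
  if (length(tj) == 0)
    return(step_function(numeric(0), numeric(0), left_value = 0))
  atrisk <- vapply(tj, function(t) sum(data$time >= t), numeric(1))
  step_function(tj, 1 / atrisk, left_value = 0)
}

# shared machinery: cause-specific and weighted extended risk-set totals per
# level on the cause-1 event-time grid.  G == NULL means censoring-free
# (all weights 1).  O(n log n) via sorted cumulative counts.
risk_set_totals <- function(data, tj, level_idx, n_levels, G = NULL) {
  m <- length(tj)
  num <- matrix(0, n_levels, m)   # sum Y_CS,ic(t) (weights all 1)
  extra <- matrix(0, n_levels, m) # sum over past competing events of w_i(t)
  Gt <- if (is.null(G)) rep(1, m) else eval_step(G, tj)
  for (c in seq_len(n_levels)) {
    rows <- level_idx == c
    Tc <- sort(data$time[rows])
    num[c, ] <- length(Tc) - findInterval(tj, Tc, left.open = TRUE)
    comp <- rows & data$status == 2
    if (any(comp)) {
      ord <- order(data$time[comp])
      T2 <- data$time[comp][ord]
      invG <- if (is.null(G)) rep(1, length(T2))
              else 1 / eval_step(G, T2, side = "left")
      cs <- cumsum(invG)
      k <- findInterval(tj, T2, left.open = TRUE) # competing events with T < t
      extra[c, ] <- Gt * c(0, cs)[k + 1L]
    }
  }
  list(num = num, den = num + extra)
}

#' Non-parametric reduction factor
#'
#' Estimates r(t) at each cause-1 event time as the ratio of the
#' cause-specific risk-set size to the (weighted) extended Fine-Gray
#' risk-set size, overall or separately per level of a categorical
#' covariate (the saturated model):
#' \deqn{\hat r(t_j | x = c) = \sum_i Y_{CS,ic}(t_j) w_i(t_j) /
#'       \sum_i Y_{FG,ic}(t_j) w_i(t_j).}
#' Members of the cause-specific risk set always have weight 1, so the
#' numerator is a plain count; with right censoring the denominator adds
#' G(t_j)/G(T_i-) for each past competing event (IPCW), and without
#' censoring it reduces exactly to the unweighted ratio of risk-set sizes.
#'
#' @param data a tie-free [crdata()] object.
#' @param by name of a categorical covariate column for per-level
#'   (saturated) estimates, or `NULL` for the overall estimate.
#' @param weights `NULL` for censoring-free data, the string `"ipcw"` to
#'   compute reverse-Kaplan-Meier censoring weights internally, or a
#'   [ipcw_weights()] matrix.
#' @return An object of class `"rf_np"`: event times, level labels and an
#'   L x m matrix of estimates in `[0, 1]` (`NA` where a level's weighted
#'   extended risk set is empty).
#' @examples
#' toy <- make_toy_dataset()
#' reduction_factor_np(toy)$values  # 1, 2/3, 1/2
#' @export
reduction_factor_np <- function(data, by = NULL, weights = NULL) {
  stopifnot(inherits(data, "crdata"))
  stop_if_ties(data, "reduction_factor_np")
  censored <- any(data$status == 0)
  if (censored && is.null(weights))
    stop("data contain censored observations; supply weights = \"ipcw\" or an ipcw_weights() matrix")
  tj <- event_time_grid(data, 1L)
  if (length(tj) == 0) stop("no cause-1 events in the data")
  if (is.null(by)) {
    level_idx <- rep(1L, nrow(data)); levels_lab <- "overall"
  } else {
    if (!by %in% names(data)) stop(sprintf("column '%s' not found", by))
    f <- factor(data[[by]])
    level_idx <- as.integer(f); levels_lab <- levels(f)
  }
  if (inherits(weights, "weight_matrix")) {
    if (!isTRUE(all.equal(weights$event_times, tj)))
      stop("weight matrix event times do not match the cause-1 event times")
    m <- length(tj); L <- length(levels_lab)
    num <- matrix(0, L, m); den <- matrix(0, L, m)
    YCS <- outer(data$time, tj, ">=")
    YFG <- YCS | (data$status == 2)
    for (c in seq_len(L)) {
      rows <- level_idx == c
      num[c, ] <- colSums(YCS[rows, , drop = FALSE] * weights$w[rows, , drop = FALSE])
      den[c, ] <- colSums(YFG[rows, , drop = FALSE] * weights$w[rows, , drop = FALSE])
    }
  } else {
    G <- if (identical(weights, "ipcw")) reverse_km(data) else NULL
    tot <- risk_set_totals(data, tj, level_idx, length(levels_lab), G)
    num <- tot$num; den <- tot$den
  }
  vals <- ifelse(den > 0, num / den, NA_real_)
  if (anyNA(vals))
    warning("empty weighted extended risk set for some level/time; values set to NA")
  structure(list(event_times = tj, levels = levels_lab,
                 values = matrix(vals, nrow = length(levels_lab),
                                 dimnames = list(levels_lab, NULL)),
                 by = by, weighted = censored),
            class = "rf_np")
}

#' @export
print.rf_np <- function(x, ...) {
  cat(sprintf("Non-parametric reduction factor at %d cause-1 event times (%s%s)\n",
              length(x$event_times),
              if (is.null(x$by)) "overall" else paste("by", x$by),
              if (x$weighted) ", IPCW-weighted" else ""))
  invisible(x)
}

# evaluate a saturated rf at arbitrary levels / event-time indices
rf_np_value <- function(rf, level, j) {
  i <- match(as.character(level), rf$levels)
  if (anyNA(i)) stop("covariate level not present in the reduction-factor estimate")
  rf$values[cbind(i, j)]
}

#' Non-parametric subdistribution hazard increments
#'
#' Nelson-Aalen-type increments 1 / (weighted extended risk-set size) at
#' each cause-1 event time.  Identical to the product of
#' [reduction_factor_np()] and the cause-1 [nelson_aalen_cs()] increments,
#' and to the plain extended-risk-set Nelson-Aalen estimator when there is
#' no censoring.
#'
#' @inheritParams reduction_factor_np
#' @return A [step_function()] of increments at the cause-1 event times.
#' @export
subdist_hazard_np <- function(data, weights = NULL) {
  stopifnot(inherits(data, "crdata"))
  stop_if_ties(data, "subdist_hazard_np")
  censored <- any(data$status == 0)
  if (censored && is.null(weights))
    stop("data contain censored observations; supply weights = \"ipcw\" or an ipcw_weights() matrix")
  tj <- event_time_grid(data, 1L)
  if (inherits(weights, "weight_matrix")) {
    YFG <- outer(data$time, tj, ">=") | (data$status == 2)
    den <- colSums(YFG * weights$w)
  } else {
    G <- if (identical(weights, "ipcw")) reverse_km(data) else NULL
    den <- risk_set_totals(data, tj, rep(1L, nrow(data)), 1L, G)$den[1, ]
  }
  step_function(tj, 1 / den, left_value = 0)
}
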