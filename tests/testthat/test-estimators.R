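test_that("break_ties makes event times distinct and is reproducible", {
  d <- crdata(time = c(1, 1, 2), status = c(1, 2, 0))
  b <- break_ties(d, seed = 42)
  et <- b$time[b$status != 0]
  expect_equal(length(unique(et)), 2)
  expect_equal(b$time[3], 2)            # censored record untouched
  expect_true(all(et < 2) && all(et >= 1)) # relative order preserved
  expect_identical(break_ties(d, seed = 42), b) # same seed, same output
  expect_false(identical(break_ties(d, seed = 43)$time, b$time))
  # no ties: returned unchanged
  d2 <- make_toy_dataset()
  expect_identical(break_ties(d2, seed = 1), d2)
})

test_that("reverse Kaplan-Meier estimates the censoring distribution", {
  # no censoring: G identically 1
  expect_equal(eval_step(reverse_km(make_toy_dataset()), c(0.5, 2, 4)),
               rep(1, 3))
  # hand product-limit: censorings at 1 and 3, risk sets 3 and 1
  d <- crdata(time = c(1, 2, 3), status = c(0, 1, 0))
  G <- reverse_km(d)
  expect_equal(eval_step(G, c(0.5, 1, 2, 2.9, 3)), c(1, 2/3, 2/3, 2/3, 0))
  expect_equal(eval_step(G, 1, side = "left"), 1) # left limit before the drop
  expect_equal(eval_step(G, 3, side = "left"), 2/3)
  expect_error(reverse_km(crdata(time = numeric(0), status = integer(0))),
               "empty")
})

test_that("IPCW weights follow the G(t)/G(Ti-) construction", {
  # censoring at 1.5 with 2 of 3 subjects at risk: G(1.5) = 1/2
  d <- crdata(time = c(1, 1.5, 2), status = c(2, 0, 1))
  W <- ipcw_weights(d)
  expect_equal(W$event_times, 2)
  # subject 1 (competing at 1): weight G(2)/G(1-) = 0.5
  # subject 2 (censored):      weight 0
  # subject 3 (event at 2):    weight 1 at its own event time
  expect_equal(W$w[, 1], c(0.5, 0, 1))
  # censoring-free data: all weights are 0/1 risk-set indicators
  W0 <- ipcw_weights(make_toy_dataset())
  expect_true(all(W0$w %in% c(0, 1)))
  expect_equal(W0$w, outer(c(1, 2, 3, 4), c(1, 3, 4), ">=") * 1
               + outer(c(FALSE, TRUE, FALSE, FALSE), c(1, 3, 4) > c(2, 2, 2), "&") * 1,
               ignore_attr = TRUE)
})

test_that("cause-specific Nelson-Aalen increments count risk sets correctly", {
  toy <- make_toy_dataset()
  na1 <- nelson_aalen_cs(toy, cause = 1)
  expect_equal(na1$knots, c(1, 3, 4))
  expect_equal(na1$values, c(1/4, 1/2, 1))
  na2 <- nelson_aalen_cs(toy, cause = 2)
  expect_equal(na2$knots, 2)
  expect_equal(na2$values, 1/3)
  # single subject with the event
  one <- crdata(time = 5, status = 1)
  expect_equal(nelson_aalen_cs(one, 1)$values, 1)
  # no events of a cause: empty (valid) step function
  expect_length(nelson_aalen_cs(one, 2)$values, 0)
  expect_error(nelson_aalen_cs(crdata(time = c(1, 1), status = c(1, 2)), 1),
               "tie-free")
})

test_that("non-parametric reduction factor reproduces hand counts on the toy data", {
  toy <- make_toy_dataset()
  rf <- reduction_factor_np(toy)
  expect_equal(rf$event_times, c(1, 3, 4))
  expect_equal(unname(rf$values[1, ]), c(1, 2/3, 1/2))
  # per-level saturated estimates: level 0's cause-specific risk set empties
  # after t = 1 while its competing event keeps it in the extended risk set,
  # so r-hat(t | 0) drops to 0; level 1 never loses a member to cause 2
  rfx <- reduction_factor_np(toy, by = "x")
  expect_equal(rfx$levels, c("0", "1"))
  expect_equal(unname(rfx$values["0", ]), c(1, 0, 0))
  expect_equal(unname(rfx$values["1", ]), c(1, 1, 1))
  # weight-matrix route agrees with the counting route
  W <- ipcw_weights(toy)
  rfm <- reduction_factor_np(toy, weights = W)
  expect_equal(rfm$values, rf$values)
})

test_that("overall and per-level estimates match direct risk-set enumeration", {
  spec <- el_spec("middle", "early", beta1 = 0.4, beta2 = -0.2)
  d <- simulate_competing_risks(80, spec, censoring = list(type = "none"),
                                seed = 5)
  d$x <- factor(d$x)
  tj <- sort(d$time[d$status == 1])
  rf <- reduction_factor_np(d)
  rfx <- reduction_factor_np(d, by = "x")
  for (lev in c(NA, "0", "1")) {
    sel <- if (is.na(lev)) rep(TRUE, nrow(d)) else d$x == lev
    num <- vapply(tj, function(t) sum(sel & d$time >= t), numeric(1))
    den <- vapply(tj, function(t) sum(sel & (d$time >= t | d$status == 2)),
                  numeric(1))
    got <- if (is.na(lev)) rf$values[1, ] else rfx$values[lev, ]
    expect_equal(unname(got), ifelse(den > 0, num / den, NA_real_))
  }
  # the overall estimate pools the per-level numerators and denominators
  num_c <- sapply(c("0", "1"), function(lev)
    vapply(tj, function(t) sum(d$x == lev & d$time >= t), numeric(1)))
  den_c <- sapply(c("0", "1"), function(lev)
    vapply(tj, function(t) sum(d$x == lev & (d$time >= t | d$status == 2)),
           numeric(1)))
  expect_equal(unname(rf$values[1, ]), rowSums(num_c) / rowSums(den_c))
})

test_that("the pointwise identity lambda-hat = r-hat * alpha1-hat is exact", {
  toy <- make_toy_dataset()
  lam <- subdist_hazard_np(toy)
  expect_equal(lam$values, c(1/4, 1/3, 1/2))
  rf <- reduction_factor_np(toy)
  na1 <- nelson_aalen_cs(toy, 1)
  expect_identical(lam$values, unname(rf$values[1, ]) * na1$values)
  # and on seeded simulated data, censoring-free and censored
  spec <- el_spec("middle", "early", beta1 = 0.3, beta2 = -0.3)
  for (s in 1:5) {
    d <- simulate_competing_risks(150, spec, censoring = list(type = "none"),
                                  seed = s)
    lam <- subdist_hazard_np(d)
    rf <- reduction_factor_np(d)
    na1 <- nelson_aalen_cs(d, 1)
    expect_equal(lam$values, unname(rf$values[1, ]) * na1$values,
                 tolerance = 1e-12)
  }
  d <- simulate_competing_risks(200, spec, seed = 7)
  lam <- subdist_hazard_np(d, weights = "ipcw")
  rf <- reduction_factor_np(d, weights = "ipcw")
  na1 <- nelson_aalen_cs(d, 1)
  expect_equal(lam$values, unname(rf$values[1, ]) * na1$values,
               tolerance = 1e-12)
})

test_that("explicit weight matrices and the internal IPCW fast path agree", {
  spec <- el_spec("middle", "late", beta1 = 0.5, beta2 = 0.2)
  d <- simulate_competing_risks(120, spec, seed = 3)
  d$x <- factor(d$x)
  W <- ipcw_weights(d)
  rf_fast <- reduction_factor_np(d, by = "x", weights = "ipcw")
  rf_mat <- reduction_factor_np(d, by = "x", weights = W)
  expect_equal(rf_fast$values, rf_mat$values, tolerance = 1e-12)
  expect_equal(subdist_hazard_np(d, weights = "ipcw")$values,
               subdist_hazard_np(d, weights = W)$values, tolerance = 1e-12)
  # censored data without weights is refused
  expect_error(reduction_factor_np(d), "censored")
  expect_error(subdist_hazard_np(d), "censored")
})

test_that("subdistribution increments reproduce the non-parametric CIF", {
  spec <- el_spec("middle", "early")
  d <- simulate_competing_risks(400, spec, covariate = "none",
                                censoring = list(type = "none"), seed = 21)
  lam <- subdist_hazard_np(d)
  # product-limit transform equals the empirical cause-1 CIF exactly
  # (censoring-free: the subdistribution "Kaplan-Meier" is the ecdf)
  F1_pl <- 1 - cumprod(1 - lam$values)
  F1_emp <- vapply(lam$knots,
                   function(t) mean(d$time <= t & d$status == 1), numeric(1))
  expect_equal(F1_pl, F1_emp, tolerance = 1e-12)
  # the exponential transform agrees up to second-order increment terms
  expect_lt(max(abs((1 - exp(-cumsum(lam$values))) - F1_emp)), 0.02)
  # independent oracle: Aalen-Johansen state occupation from survfit
  aj <- survival::survfit(survival::Surv(time, factor(status, 0:2)) ~ 1,
                          data = as.data.frame(d))
  F1_aj <- aj$pstate[match(lam$knots, aj$time), match("1", aj$states)]
  expect_equal(F1_pl, F1_aj, tolerance = 1e-10)
})

test_that("reduction-factor estimates are consistent for the true curve", {
  spec <- el_spec("middle", "early")
  d <- simulate_competing_risks(20000, spec, covariate = "none",
                                censoring = list(type = "none"), seed = 99)
  rf <- reduction_factor_np(d)
  truth <- compute_curves(spec, grid = default_grid(horizon = max(d$time) * 1.01))
  r_true <- stats::approx(truth$time, truth$reduction, rf$event_times,
                          rule = 2)$y
  central <- rf$event_times >= stats::quantile(rf$event_times, 0.05) &
             rf$event_times <= stats::quantile(rf$event_times, 0.95)
  expect_lt(max(abs(rf$values[1, central] - r_true[central])), 0.03)
})
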