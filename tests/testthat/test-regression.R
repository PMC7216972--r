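test_that("cause-specific Cox fit matches survival::coxph", {
  spec <- el_spec("middle", "early", beta1 = 0.5, beta2 = -0.5)
  for (s in 1:3) {
    d <- simulate_competing_risks(250, spec, seed = 30 + s)
    f <- fit_cox_csh(d, "x")
    o <- survival::coxph(survival::Surv(time, status == 1) ~ x,
                         data = as.data.frame(d), ties = "breslow")
    expect_equal(unname(f$coefficients), unname(coef(o)), tolerance = 1e-7)
    expect_equal(unname(sqrt(diag(f$vcov))),
                 unname(sqrt(diag(vcov(o)))), tolerance = 1e-6)
    # Breslow baseline increments against coxph's cumulative baseline hazard
    bh <- survival::basehaz(o, centered = FALSE)
    expect_equal(cumsum(f$baseline$values),
                 bh$hazard[match(f$baseline$knots, bh$time)],
                 tolerance = 1e-6)
    # cause 2 as the cause of interest
    f2 <- fit_cox_csh(d, "x", cause = 2)
    o2 <- survival::coxph(survival::Surv(time, status == 2) ~ x,
                          data = as.data.frame(d), ties = "breslow")
    expect_equal(unname(f2$coefficients), unname(coef(o2)), tolerance = 1e-7)
  }
})

test_that("monotone likelihood (separation) is flagged", {
  d <- crdata(time = c(1, 2), status = c(1, 1), x = c(1, 0))
  f <- suppressWarnings(fit_cox_csh(d, "x"))
  expect_false(f$converged)
  expect_identical(f$flag, "monotone-likelihood")
})

test_that("a constant offset does not move the coefficient", {
  spec <- el_spec("middle", "middle", beta1 = 0.4, beta2 = 0)
  d <- simulate_competing_risks(200, spec, seed = 8)
  plain <- fit_cox_csh(d, "x")
  const_off <- structure(list(
    eval = function(t, newdata) rep(0.7, nrow(newdata)),
    provenance = "test"), class = "offset_model")
  shifted <- fit_cox_csh(d, "x", offset = const_off)
  expect_equal(shifted$coefficients, plain$coefficients, tolerance = 1e-9)
  # the baseline absorbs the constant: increments scale by exp(-0.7)
  expect_equal(shifted$baseline$values, plain$baseline$values * exp(-0.7),
               tolerance = 1e-9)
})

test_that("Fine-Gray fit matches cmprsk::crr and a brute-force maximizer", {
  skip_if_not_installed("cmprsk")
  spec <- el_spec("middle", "early", beta1 = 0.5, beta2 = -0.5)
  for (s in 1:3) {
    d <- simulate_competing_risks(250, spec, seed = 60 + s)
    fg <- fit_fine_gray(d, "x")
    cr <- cmprsk::crr(d$time, d$status, cov1 = matrix(d$x))
    expect_equal(unname(fg$coefficients), unname(cr$coef), tolerance = 1e-6)
  }
  # brute force: golden-section maximization of the same weighted partial
  # likelihood, written independently of the Newton engine
  d <- simulate_competing_risks(150, spec, seed = 71)
  fg <- fit_fine_gray(d, "x")
  G <- reverse_km(d)
  tj <- sort(d$time[d$status == 1])
  pl <- function(beta) {
    s <- 0
    for (t in tj) {
      jrow <- which(d$time == t & d$status == 1)
      atrisk <- d$time >= t
      past2 <- d$status == 2 & d$time < t
      w <- ifelse(atrisk, 1,
                  ifelse(past2,
                         eval_step(G, t) / eval_step(G, d$time, side = "left"),
                         0))
      s <- s + beta * d$x[jrow] - log(sum(w * exp(beta * d$x)))
    }
    s
  }
  opt <- stats::optimize(pl, c(-3, 3), maximum = TRUE, tol = 1e-10)
  expect_equal(unname(fg$coefficients), opt$maximum, tolerance = 1e-6)
  expect_equal(fg$loglik, opt$objective, tolerance = 1e-9)
})

test_that("without competing events the Fine-Gray and cause-specific fits coincide", {
  spec <- two_cause_spec(weibull_spec(el_rates[["middle"]], 1),
                         weibull_spec(0, 1), beta1 = 0.5)
  d <- simulate_competing_risks(200, spec, seed = 4)
  fg <- fit_fine_gray(d, "x")
  cs <- fit_cox_csh(d, "x")
  expect_equal(fg$coefficients, cs$coefficients, tolerance = 1e-10)
  expect_equal(fg$baseline$values, cs$baseline$values, tolerance = 1e-12)
  # and r-hat = 1 everywhere makes the offset route collapse to the plain fit
  rf <- reduction_factor_np(d, weights = "ipcw")
  expect_true(all(rf$values == 1))
  off <- fit_fg_via_offset(d, "x", rf)
  expect_equal(off$coefficients, cs$coefficients, tolerance = 1e-10)
})

test_that("the saturated offset route reproduces the Fine-Gray estimate exactly", {
  for (s in 1:4) {
    d <- equivalence_dataset(200 + s, random_censoring = s %% 2 == 0)
    disc <- equivalence_report(d, "x")
    expect_lt(as.numeric(disc), 1e-8)
  }
  # continuous covariates are refused
  d <- equivalence_dataset(99)
  d$age <- rnorm(nrow(d))
  expect_error(equivalence_report(d, "age"), "continuous")
  # when a level's cause-specific risk set empties first, the offset is
  # degenerate and the fit refuses rather than returning a different answer
  toy <- make_toy_dataset()
  toy$x <- factor(toy$x)
  rfx <- reduction_factor_np(toy, by = "x")
  expect_error(fit_fg_via_offset(toy, "x", rfx), "degenerate")
})

test_that("per-time saturated GLM reproduces the closed-form ratios", {
  d <- equivalence_dataset(301, random_censoring = TRUE)
  rf_np <- reduction_factor_np(d, by = "x", weights = "ipcw")
  rf_glm <- fit_rf_glm(d, "x", link = "log", family = "poisson",
                       weights = "ipcw", structure = "per_time")
  tj <- rf_glm$event_times
  for (lev in c("0", "1")) {
    nd <- data.frame(x = factor(lev, levels = c("0", "1")))
    expect_equal(predict_reduction(rf_glm, tj, nd),
                 unname(rf_np$values[lev, ]), tolerance = 1e-8)
  }
  # per-time log-link coefficient is the log ratio of the level estimates
  expect_equal(unname(rf_glm$coef[, "x1"]),
               unname(log(rf_np$values["1", ] / rf_np$values["0", ])),
               tolerance = 1e-8)
  # when the first cause-1 event precedes every competing event, the whole
  # extended risk set is still event-free there: r-hat = 1 and the per-time
  # log-link fit has intercept and effect 0
  h <- crdata(time = 1:6, status = c(1L, 2L, 1L, 1L, 2L, 1L),
              x = factor(c(0, 0, 1, 1, 0, 1)))
  rf_h <- reduction_factor_np(h, by = "x")
  expect_equal(unname(rf_h$values[, 1]), c(1, 1))
  glm_h <- fit_rf_glm(h, "x", link = "log", family = "poisson",
                      structure = "per_time")
  expect_equal(unname(glm_h$coef[1, ]), c(0, 0), tolerance = 1e-10)
})

test_that("pooled spline GLM fits and predicts sensibly", {
  spec <- el_spec("middle", "early", beta1 = 0.5, beta2 = -0.5)
  d <- simulate_competing_risks(300, spec, seed = 17)
  d$x <- factor(d$x)
  rf <- fit_rf_glm(d, "x", weights = "ipcw", structure = "pooled")
  tj <- rf$event_times
  r0 <- predict_reduction(rf, tj, data.frame(x = factor("0", levels = c("0", "1"))))
  expect_true(all(r0 > 0 & r0 <= 1))
  # the pooled curve tracks the saturated one
  rf_np <- reduction_factor_np(d, by = "x", weights = "ipcw")
  central <- tj >= quantile(tj, 0.1) & tj <= quantile(tj, 0.9)
  expect_lt(max(abs(r0 - rf_np$values["0", ])[central]), 0.15)
  # time-varying pooled fit runs and stays in range
  rf_tv <- fit_rf_glm(d, "x", weights = "ipcw", structure = "pooled",
                      time_varying = TRUE)
  r1 <- predict_reduction(rf_tv, tj, data.frame(x = factor("1", levels = c("0", "1"))))
  expect_true(all(r1 > 0 & r1 <= 1))
})

test_that("per-time log-link effects track the implied coefficient difference", {
  # gamma(t) from the saturated per-level estimate approximates
  # betaFG(t) - betaCS on a large sample
  spec <- el_spec("middle", "early", beta1 = 0.5, beta2 = -0.5)
  d <- simulate_competing_risks(20000, spec,
                                censoring = list(type = "none", admin = NULL),
                                seed = 123)
  d$x <- factor(d$x)
  rfx <- reduction_factor_np(d, by = "x")
  tj <- rfx$event_times
  gamma_hat <- log(rfx$values["1", ] / rfx$values["0", ])
  truth <- beta_fg_curve(spec, grid = c(0, sort(unique(pmin(tj, 4)))))
  b_rf <- truth$beta_fg - 0.5
  b_rf_at <- stats::approx(truth$time, b_rf, pmin(tj, 4), rule = 2)$y
  central <- tj >= stats::quantile(tj, 0.05) & tj <= stats::quantile(tj, 0.95)
  expect_lt(max(abs(gamma_hat - b_rf_at)[central], na.rm = TRUE), 0.1)
})
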