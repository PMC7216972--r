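---
title: "Reduction-factor methods for competing risks: models, estimators and design choices"
author: "redfac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduction-factor methods for competing risks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redfac)
```

## The model

With two competing causes of failure, the cause-specific hazards
$\alpha_1(t)$ and $\alpha_2(t)$ determine the event-free survival
$S(t) = \exp\{-A_1(t) - A_2(t)\}$ and the cumulative incidence functions
$F_k(t) = \int_0^t \alpha_k(s)\,S(s)\,ds$.  The subdistribution hazard of
cause 1, $\lambda(t) = -\,d\log\{1 - F_1(t)\}/dt$, is the hazard a
Fine–Gray proportional model is placed on.  The two hazards are linked by
the **reduction factor**

$$r(t) \;=\; \frac{S(t)}{1 - F_1(t)} \;=\; \frac{\lambda(t)}{\alpha_1(t)},$$

the proportion of the extended (Fine–Gray) risk set — subjects event-free
*or* already failed from the competing cause — that is still truly at
risk.  It satisfies $r(0) = 1$, decreases over time, and obeys the
differential equation

$$-\frac{d\log r(t)}{dt} \;=\; \alpha_1(t)\{1 - r(t)\} + \alpha_2(t),$$

so that near $t = 0$ it behaves like a survival function with cumulative
hazard $A_2(t)$.  With a covariate acting proportionally on both
cause-specific hazards ($\beta_1$, $\beta_2$), the implied subdistribution
log hazard ratio is time-varying,
$\beta_{FG}(t) = \beta_1 + \log r(t|1) - \log r(t|0)$, with
$\beta_{FG}(0) = \beta_1$ and initial slope
$\alpha_{20}(0)\{1 - e^{\beta_2}\}$: an adverse effect on the competing
cause pulls $\beta_{FG}(t)$ *below* $\beta_1$ and a protective one pushes
it above.  (Only $\beta_1 = \beta_2 = 0$ makes $\beta_{FG}$
time-constant.)

The central estimation fact the package is built around: for a categorical
covariate, plugging the *saturated* non-parametric estimate
$\hat r(t \mid x)$ into the **cause-specific** partial likelihood as the
offset $-\log \hat r(t|x)$ yields *exactly* the Fine–Gray
partial-likelihood estimate — the extended risk set is never formed.  The
reduction factor is thus the adjustment that justifies the Fine–Gray
likelihood on natural risk sets.

## Parametric theory curves

`compute_curves()`, `reduction_factor_ode()` and `beta_fg_curve()` evaluate
these quantities for Weibull cause-specific hazards
$h(t; a, b) = a\,b\,t^{b-1}$.  The stock parameterization calibrates the
rate so each hazard reaches $S(2.5) = 0.05$: $a = 1.895$ ($b = 0.5$,
"early" risk), $a = 1.198$ ($b = 1$, "middle"), $a = 0.479$ ($b = 2$,
"late").  Two deliberately independent numerical routes to $r(t)$ are
provided, and tested against each other to $10^{-5}$ sup-norm:

* **Ratio route.** $S$ is exact; $F_1, F_2$ are accumulated as
  [cause fraction at the interval midpoint] × [exact survival drop] on an
  internal grid uniform in $t^{c}$, $c = \min(b_1, b_2, 1)$.  The
  transformation concentrates quadrature points where a shape $b < 1$
  hazard is singular; the drop-sharing rule is exact for equal shapes and
  second-order otherwise, and makes $S + F_1 + F_2 = 1$ hold to machine
  precision by construction.  A plain cumulative trapezoid of
  $\alpha_1 S$ was rejected because the $t^{-1/2}$ endpoint singularity
  costs ~$10^{-3}$ absolute error on a 2001-point grid.
* **ODE route.** Classical fixed-step fourth-order Runge–Kutta on
  $u(t) = \log r(t) + A_2(t)$ with $A_2$ absorbed in closed form (default
  10 substeps per grid interval).  Solving on the log scale keeps $r$
  positive; absorbing $A_2$ removes the singular $\alpha_2$ term from the
  stepped integrand, whose remaining part $\alpha_1(t)\{1 - r(t)\}$ is
  bounded whenever $b_1 + b_2 \ge 1$.

Hazard-valued outputs at $t = 0$ use an evaluation guard
$\varepsilon = 10^{-6}$ (a shape $b<1$ hazard is infinite there);
probability-valued outputs are exact at 0.  The default grid is 2001
points on $[0, 2.5]$, the calibration horizon.  The covariate mean
$p = 0.5$ of the stock design is recorded in `two_cause_spec()` but plays
no role in the conditional curves; it only parameterizes the simulator.

## Estimation

* `reverse_km()` – product-limit estimate of the censoring distribution
  $G$ (computed with `survival::survfit`, wrapped so the left limit
  $G(t-)$ is first-class).
* `ipcw_weights()` – $w_i(t) = 1$ under observation,
  $G(t)/G(T_i-)$ after an observed competing event, 0 after censoring.
  A subject censored exactly at $t$ is treated as still observed at $t$
  (closed inequality in $\delta_i(t)$).
* `reduction_factor_np()` – saturated per-level (or overall) ratio of
  cause-specific to weighted extended risk-set totals.  Members of the
  cause-specific set always have weight one, so only the past competing
  events carry $G$-ratios; without censoring everything reduces to plain
  counts.  Implemented with sorted cumulative sums ($O(n\log n)$), so
  consistency checks at $n = 20{,}000$ are cheap.
* `fit_cox_csh()`, `fit_fine_gray()`, `fit_fg_via_offset()` –
  Newton–Raphson with step-halving on the respective partial likelihoods
  (score tolerance $10^{-9}$, relative log-likelihood change
  $10^{-12}$, at most 50 iterations; tight so the exact-equivalence tests
  bite).  The plain cause-specific and IPCW Fine–Gray denominators are
  suffix/prefix cumulative sums over time-sorted subjects ($O(np^2)$ per
  Newton pass); a time-and-covariate-dependent offset makes the
  denominator irreducible, so the offset path evaluates each risk set
  explicitly.  Estimates with $|\hat\beta| > 15$ are flagged as monotone
  likelihood.  Variances are inverse observed information; for the
  Fine–Gray fit these are naive (they ignore the weight estimation) and
  the bootstrap is recommended.
* `fit_rf_glm()` – binomial or Poisson working-likelihood GLMs for
  $r(t|x)$ on the stacked extended risk sets, per event time (the richest
  model) or pooled with a natural cubic spline in $\log t$ (interior
  knots at the 0.25/0.5/0.75 quantiles of the event times).  The Poisson
  log link is the default: combined with proportional cause-specific
  hazards it keeps the subdistribution model proportional, and it
  tolerates fitted means above one, which the binomial log link does not.
  The constraint $\beta_{RF}(0) = 0$ (i.e. $r(0|x) = 1$ for every $x$) is
  *not* enforced in pooled fits; fitted values are clipped to $(0, 1]$.
  Pooled fits treat risk sets as independent (GEE working independence);
  cluster-robust standard errors are available via the sandwich package.

### When the saturated-offset identity can fail

The exact equivalence between `fit_fine_gray()` and `fit_fg_via_offset()`
holds whenever every covariate level present in the extended risk set
still has members in the cause-specific risk set at each cause-1 event
time.  If a level's last observation precedes another level's last
cause-1 event — easy to arrange with near-complete follow-up, e.g. the
stock hazards run to $t = 2.5$ where only 0.25% remain event-free — the
saturated $\hat r(t|c)$ is 0 there, the required offset $-\log 0$ is
degenerate, and `fit_fg_via_offset()` refuses with an error rather than
silently returning a different estimate.  The package's equivalence
demonstrations therefore end follow-up administratively at $t = 0.25$
(about 13% of the higher-risk group still event-free), half of the
datasets with additional uniform censoring on $[0, 1]$; administrative
end-of-study is the data-level expression of estimating "before the
observation horizon", and under it the identity holds to machine
precision on every dataset.

## Cumulative incidence estimators

Four covariate-conditional estimators of $F_1(t|x^*)$:

1. **Multistate**: proportional models on both cause-specific hazards,
   plug-in with Breslow baselines.  Two discretizations are offered.  The
   default exponential convention exponentiates cumulative hazards at
   event times and allocates each survival drop across causes
   proportionally to their increments — this conserves
   $S + F_1 + F_2 = 1$ exactly and collapses to $1 - e^{-\hat A_1}$ when
   the competing cause is empty.  The product-limit variant
   (`variant = "product-limit"`) uses the left-limit Aalen–Johansen
   product and reduces to the classical non-parametric estimator under
   null covariate effects; total jumps above one are capped with
   proportional rescaling.
2. **Subdistribution through r**: $\hat\lambda = \hat r \hat\alpha_1$
   accumulated and transformed by $1 - e^{-\Sigma}$; the reduction-factor
   model makes no proportionality assumption of its own.
3. **Fine–Gray**: weighted Breslow subdistribution baseline scaled by
   $e^{\hat\beta_{FG} x^*}$.
4. **Fine–Gray with cause-specific partial likelihood**: the offset fit's
   Breslow denominator over natural risk sets; for saturated categorical
   $\hat r$ its curve coincides with method 3.

`bootstrap_se()` resamples subjects with replacement, re-runs the chosen
pipeline per replicate (tie-breaking included) and reports pointwise
standard deviations on a fixed grid.  By default the reduction-factor
model is re-estimated inside every replicate, so its uncertainty is
propagated; `mode = "fixed-rf"` freezes it at the original estimate for
analyses that prefer to treat it as known.  Replicate failures are
dropped; more than 10% failing is an error.

## The simulator

`simulate_competing_risks()` draws, in a fixed seeded order (covariates,
latent times, causes, censoring): a Bernoulli($p = 0.5$) covariate; a
latent time by inverting $A_1 + A_2$ at a unit exponential deviate
(closed form for equal shapes, bracketed root-finding otherwise); cause 1
with probability $\alpha_1/(\alpha_1 + \alpha_2)$ at the drawn time; and
independent censoring — none, uniform, exponential, or administrative
end-of-study (everyone event-free at $\tau$ censored there), the last
also available as a horizon on top of the random schemes.  The default,
uniform on $[0, 3]$ (1.2× the calibration horizon), yields moderate
censoring under the stock hazards.  What the generator does *not*
emulate: covariate-dependent censoring, non-Weibull baselines, more than
two causes, and tied recording of times — so passing tests say nothing
about those features of real registry data; the EBMT cross-check in the
test suite is the package's only contact with a real table.  A
non-exported helper simulates under an exactly proportional
subdistribution hazard (unit-exponential mixture construction) for
parameter-recovery checks.

## Numerical and design choices, in brief

* Status codes are fixed at 0/1/2 internally; `as_crdata()` maps other
  codings.  All estimators refuse tied event times and direct the user to
  `break_ties()` (seeded jitter smaller than half the smallest gap;
  censored records untouched).
* The estimand grid is exactly the observed cause-1 event times.
* $G$ is right-continuous; $G(\min\{T_i-, t\})$ is the left limit at
  $T_i$ when $T_i \le t$.  A vanished censoring tail cannot produce an
  infinite weight: $G(T_i-) = 0$ for an observed competing event is
  impossible (that subject was at risk through $T_i$), and a guard errors
  if it is ever requested; $G(t_j) = 0$ simply zeroes the past-competing
  contributions.
* Reference level for factors is the first level (alphabetical unless the
  factor says otherwise); profiles must use the same factor coding as the
  data.
* Per-time GLM failures at individual event times are flagged and left
  `NA`, never silently interpolated; curve evaluation offers explicit
  last-value carry-forward.
* Problem sizes in the test suite: consistency at $n = 20{,}000$ (one
  dataset), simulator-versus-theory at $n = 50{,}000$, parameter recovery
  over 50 replications at $n = 2{,}000$, bootstrap calibration at
  $n = 300$ with 100 replicates against 100 independent datasets.

## Known limitations

* No closed-form standard errors for the four curve estimators; the
  bootstrap substitutes.  Fine–Gray coefficient variances ignore the
  estimated censoring weights.
* The censoring distribution is modeled unconditionally; covariate-
  dependent censoring $G(t|x)$ is out of scope, as are landmark/dynamic
  conditional cumulative incidences and tie corrections (data are made
  tie-free instead).
* The saturated-offset identity requires the risk-set support condition
  above; the package errors rather than approximates when it fails.
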