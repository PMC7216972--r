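# shared fixtures: the early/middle/late Weibull hazards calibrated so each
# reaches S(2.5) = 0.05, and dataset builders used across test files

el_shapes <- c(early = 0.5, middle = 1, late = 2)
el_rates <- vapply(el_shapes, solve_rate_for_survival,
                   numeric(1), horizon = 2.5, survival = 0.05)

el_spec <- function(shape1, shape2, beta1 = 0, beta2 = 0) {
  two_cause_spec(weibull_spec(el_rates[[shape1]], el_shapes[[shape1]]),
                 weibull_spec(el_rates[[shape2]], el_shapes[[shape2]]),
                 beta1 = beta1, beta2 = beta2)
}

# the covariate setting used for the implied time-varying subdistribution
# log hazard ratio: middle-risk baseline for cause 1, competing baseline and
# coefficients varied
beta_grid <- expand.grid(beta1 = c(-0.5, 0, 0.5), beta2 = c(-0.5, 0, 0.5))

# datasets for the saturated-offset equivalence demonstration: follow-up
# ends administratively at t = 0.25 (roughly 13% of the higher-risk group
# still event-free) so that both covariate levels stay represented in the
# cause-specific risk sets -- the regularity condition of the identity;
# half of the datasets add uniform random censoring on top
equivalence_dataset <- function(seed, random_censoring = FALSE, n = 200) {
  spec <- el_spec("middle", "early", beta1 = 0.5, beta2 = -0.5)
  cens <- if (random_censoring) list(type = "uniform", max = 1, admin = 0.25)
          else list(type = "admin", time = 0.25)
  d <- simulate_competing_risks(n, spec, censoring = cens, seed = seed)
  d$x <- factor(d$x)
  d
}

# numerical derivative of a curve at its left end
left_slope <- function(time, value) (value[2] - value[1]) / (time[2] - time[1])
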