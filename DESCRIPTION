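Package: redfac
Title: Reduction-Factor Methods for Competing Risks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying and exploiting the reduction factor
    r(t) = S(t)/(1 - F1(t)) that links the cause-specific hazard of an event
    of interest to its subdistribution (Fine-Gray) hazard in competing-risks
    data. Provides closed-form and numerical theory curves under Weibull
    cause-specific hazards (survival, cumulative incidences, reduction factor,
    implied time-varying subdistribution log hazard ratios), non-parametric
    and censoring-weighted (IPCW) estimators of the reduction factor, partial
    likelihood fitters for cause-specific hazards with time- and
    covariate-dependent offsets, a weighted Fine-Gray fitter on extended risk
    sets, per-time and pooled GLM models for the reduction factor, four
    covariate-conditional estimators of the cumulative incidence function with
    bootstrap standard errors, and a seeded competing-risks simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cmprsk,
    mstate,
    sandwich,
    optparse,
    withr
Config/testthat/edition: 3
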