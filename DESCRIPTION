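Package: twosexlt
Title: Age-Stage Two-Sex Life Table Analysis for Insect Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes age-stage, two-sex life tables from per-individual
    insect life-history records: age-stage survival rates (sxj),
    age-specific survival (lx) and fecundity (mx), net reproductive rate
    (R0), intrinsic rate of increase (r) via the Euler-Lotka equation,
    finite rate of increase (lambda), mean generation time (T), age-stage
    life expectancy (exj) and reproductive value (vxj). Provides bootstrap
    standard errors and confidence intervals for the population parameters
    and a paired bootstrap test for comparing two rearing treatments, a
    stochastic cohort simulator with closed-form expected schedules for
    validation, one-way ANOVA with Tukey HSD compact letter displays for
    developmental-trait tables, and cost comparisons across artificial
    diet formulations used in insect mass rearing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
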