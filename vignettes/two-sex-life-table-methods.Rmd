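---
title: "Methods: age-stage two-sex life table analysis in twosexlt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-stage two-sex life table analysis in twosexlt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twosexlt)
```

## The model and its assumptions

The age-stage, two-sex life table describes a rearing cohort followed
individually from entry (age 0, day of hatching into the first instar)
to death, with stage membership and daily egg counts recorded every day.
Its central object is the age-stage survival matrix
$s_{xj} = n_{xj}/n_{01}$, the probability that one of the $n_{01}$
newborns is alive *and in stage $j$* at age $x$. Summing over the
$\beta$ stages gives age-specific survival $l_x = \sum_j s_{xj}$, and
the fecundity schedule pools both sexes:
$m_x = \sum_j s_{xj} f_{xj} / \sum_j s_{xj}$, where $f_{xj}$ is the mean
daily egg count of the individuals in cell $(x, j)$. Keeping males and
individuals that died before sex determination (sex `"U"`) in every
denominator is the point of the two-sex method: survival and the pace of
development are cohort properties, not female properties, and a
female-only table overstates them whenever male and female schedules
differ.

The derived parameters are the standard quartet:

* $R_0 = \sum_x l_x m_x$, offspring per newborn;
* $r$, the root of the Euler–Lotka equation
  $\sum_{x=0}^{\infty} e^{-r(x+1)} l_x m_x = 1$ (per day);
* $\lambda = e^r$ (per day) and $T = \ln R_0 / r$ (days).

The $(x+1)$ exponent reflects the one-day census interval with ages
starting at zero; the same convention is used everywhere, including the
reproductive-value recursion, so the identities $\lambda = e^r$,
$T = \ln R_0/r$ and $v_{0,1} = \lambda$ hold to numerical precision
rather than approximately.

Two further matrices interpret the cohort cell by cell. The life
expectancy $e_{xj}$ is the expected remaining days of an individual
currently at $(x, j)$, obtained by forward accumulation of the empirical
conditional survival of the cell's members; the convention here counts
the current day, so an individual on its last day has expectancy 1 and
$e_{0,1}$ equals the cohort's mean lifespan. The reproductive value is

$$v_{xj} = \frac{e^{r(x+1)}}{s_{xj}} \sum_{i \ge x} e^{-r(i+1)}
  \sum_y s'_{iy|xj} \, f_{iy},$$

with $s'_{iy|xj}$ the survival to $(i, y)$ conditional on being alive at
$(x, j)$, estimated from the same individuals. Neither recursion is
universally printed alongside the parameter definitions in the applied
literature; the forms above are the standard age-stage formulations and
are treated here as definitions. Conditioning on a newborn collapses the
sum to the Euler–Lotka equation, which is why $v_{0,1} = \lambda$
exactly — the test suite asserts this identity on every analyzed cohort.

Entry stage is configurable. The default order (L1…L6, pupa, adult
female, adult male) matches protocols that enroll freshly hatched first
instars, so the egg stage is outside the table while eggs still count as
offspring; a `stage_order()` beginning at an egg stage expresses the
other convention.

## Bootstrap inference

The resampling unit is the individual: a replicate draws $n_{01}$ whole
life histories with replacement and recomputes $r$, $\lambda$, $R_0$,
$T$. This is the only unit consistent with the life table — resampling
individual-days would break the within-individual dependence that the
table summarizes. Replicates in which no reproducing female was drawn
leave $r$ undefined; they are flagged invalid and excluded from means,
standard errors and percentile intervals (treating them as
$r = -\infty$ would make the moments meaningless), and the number of
valid replicates is always reported.

The paired test records, per iteration, the difference
$d_b = \theta_{A,b} - \theta_{B,b}$ between independently resampled
cohorts, and reports the two-sided sign-count p-value
$p = 2\min(\#\{d_b \le 0\}, \#\{d_b \ge 0\})/B_{\mathrm{valid}}$,
clamped at 1. The applied literature that popularized this test does not
define its p-value; the sign-count form is the common implementation
choice and is exactly symmetric in the two cohorts. Implementation
detail with a visible consequence: each iteration's resampling indices
come from a substream seeded deterministically from the run seed, and a
cohort's substream is keyed to a content fingerprint rather than to
argument position — so `paired_bootstrap_test(a, b)` and
`paired_bootstrap_test(b, a)` return exactly negated differences and
identical p-values, and results do not depend on iteration order.

$B = 100{,}000$ iterations is the convention in rearing studies and is
the CLI default; standard errors stabilize far earlier, so the package
functions default to $B = 2000$, which is also the scale used in the
validation suite.

## The cohort simulator

Per-individual rearing records are rarely deposited, so validation rests
on a simulator that generates cohorts with exactly the structure the
analysis assumes: independent per-stage durations (fixed, or shifted
negative-binomial $1 + \mathrm{NB}$ so stages last at least a day),
stage-specific *daily* survival (geometric within-stage mortality), sex
assigned at pupation with probability `female_fraction`, and for females
a unimodal daily egg schedule — a discretized Gaussian kernel over the
oviposition window, scaled by largest-remainder rounding so a fully
surviving female lays exactly the configured total. The kernel is
deterministic given a female's lifespan; stochasticity in fecundity
enters through survival and the adult-duration distribution.

The defaults portray a plausible noctuid rearing phenotype — larval span
near 19.5 d, pupal span near 10.5 d, survival to pupation near 0.84,
total fecundity 2650 eggs over a 14-day window peaking on day 5 after a
2-day pre-oviposition period, cohort size 100 (five groups of 20) — and
were fixed once as a realistic fixture, not fitted to any data set.

For configurations with fixed durations the expected schedules have a
closed form (`expected_schedules()`): $l_x$ is the running product of
daily survival along the sex-specific deterministic stage path, mixed by
the sex ratio, and $m_x$ weights the female egg kernel by female
survivorship. Feeding these schedules to the same estimators yields the
true parameters, enabling parameter-recovery tests
(at $n = 2000$, $\hat r$ falls within 3 bootstrap SEs of the truth) and
type-I-error calibration of the paired test (200 null pairs at
$n = 100$, $B = 500$).

What the simulator does *not* emulate: between-individual heterogeneity
in fecundity beyond lifespan truncation, correlations between
development speed and survival or fecundity, egg-viability differences,
and any diet-specific mechanism. Passing tests therefore demonstrate
correctness of the estimators on data satisfying the life-table
assumptions, not fidelity of any particular biological claim.

## Trait statistics and diet costs

Developmental-trait tables (durations, masses, rates per diet) are
one-way ANOVAs followed by all pairwise Tukey comparisons and a compact
letter display. The Tukey–Kramer form is used so unequal group sizes are
handled; letters are built by insert-and-absorb and assigned in
descending-mean order ("a" on the largest mean — conventions differ
across publications, so the choice is documented rather than inferred).
Two degenerate cases are defined, not errors: all groups identical gives
$F = 0$, $p = 1$, one shared letter; zero within-group variance with
unequal means is flagged as $F = \infty$ with all-distinct letters.

Formulation costs are bundled data (ingredient unit prices are not
available, so cost cannot be recomputed from composition); comparisons
report the absolute saving rounded to two decimals (yuan) and the
relative reduction to one decimal (%), the precision at which such
figures are quoted. Cost-tier labels (high/medium/low) are part of the
fixture.

## Numerical choices

* `solve_r()`: bracketed bisection, initial bracket doubled outward from
  $[-1, 1]$, terminating at residual $\le 10^{-12}$; the residual is
  strictly decreasing in $r$, so the root is unique and the method
  cannot be fooled by spiky $l_x m_x$ schedules.
* $m_x$ at ages with no survivors is 0 (the 0/0 cell), contributing
  nothing to $R_0$ or the Euler–Lotka sum.
* $T$ at $r = 0$ is returned as `NA` ($\ln R_0 / r$ is 0/0 there);
  $r = 0$ occurs exactly when $R_0 = 1$.
* Stage on a molt day is taken from the input as recorded; the reader
  never infers molts.
* Floating-point assertions in the test suite use absolute tolerance
  $10^{-9}$ unless a tighter closed form is available.

## Validation scale

The suite validates against independent brute-force loop
implementations on 20 simulated cohorts of up to 50 individuals,
runs parameter recovery on 50 replicates of $n = 2000$ with $B = 500$
bootstrap iterations, calibrates the paired test on 200 null pairs, and
checks the ANOVA null rejection rate on 1000 simulated data sets —
sizes chosen to make sampling noise negligible relative to the tested
tolerances while keeping the whole suite fast.

## Known limitations

* The bootstrap treats the cohort as the population of interest;
  group/replicate structure within a treatment (e.g. rearing containers)
  is not modeled.
* The paired test's sign-count p-value has the granularity $2/B$; at
  small $B$ it cannot be small.
* `exj`/`vxj` cells visited by very few individuals are noisy; the
  package reports them as computed and leaves smoothing to the user.
* The CLI covers the pipeline's file-based workflow; programmatic use
  should call the functions directly.
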