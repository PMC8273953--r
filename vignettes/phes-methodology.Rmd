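---
title: "PHES normalisation: model, conventions and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PHES normalisation: model, conventions and synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phesnorm)
```

## The scoring model

PHES screens for minimal hepatic encephalopathy (MHE) by comparing five raw
psychometric results with age- and education-matched normative expectations.
The package's model has three layers.

**Normative layer.** For each test the expected raw result is a linear
function of age and education (years):
`E[y] = b0 + b1*age + b2*education`, estimated by ordinary least squares on a
healthy-volunteer sample. The residual SD — the estimate used to standardise
deviations — is the unbiased regression estimate with denominator `n - 3`
(intercept plus two slopes), the standard multiple-regression convention; the
source tables report SDs without naming the estimator, so this is a
documented assumption. The line tracing test is always fitted and scored on
its error-adjusted composite `(1 + LTTe/100) * LTTt`, never on the raw time,
because the composite is how the test result is defined.

**Standardisation layer.** The deficit Z is the standardised residual with
its sign oriented so that positive always means worse than expected; the
digit symbol test (the only points-scored, higher-is-better test) is
sign-flipped. Banding follows the SD-unit ladder (0 within one SD; −1, −2,
−3 for each further SD; +1 for better than one SD above expectation). Two
conventions the source description leaves open:

* *Boundary ownership.* A deficit of exactly 1, 2 or 3 SDs takes the less
  pathological band (0, −1, −2 respectively), and the +1 bonus requires a
  strictly better-than-1-SD result. This extends the strictness of the
  "less than −1 SD" clause symmetrically to every boundary.
* *Reversed banding block.* The published banding text attaches the reversed
  (lower-is-worse) block to "SDT", but SDT is a timed test expressed in
  seconds — scoring it lower-is-worse would reward slowness. Standard PHES
  methodology reverses only the DST, and that is what the package does.

Deficit Z values are kept at full floating precision; nothing is rounded
before banding. PHES is the integer sum of the five component points and is
bounded in [−15, +5] by construction.

**Classification layer.** The cut-off is the reference-sample mean − 2 SD,
floored to the nearest integer (PHES is integer-valued and flooring is the
conservative, always-defined generalisation of the published "−2.64 → −3"
step). MHE is classified when PHES is *strictly below* the cut-off; an
inclusive `less_equal` rule is exposed as an option because cut-off phrasing
is ambiguous across reports, but `strict_less` is the default and matches
the classification sentence in the source methods.

## Cohort epidemiology conventions

* Odds ratios are cross-product ratios at full internal precision. The
  *reporting* layer truncates (not rounds) to two decimals: the five
  published cohort ORs are consistent with truncation (4.6875 → 4.68,
  2.029 → 2.02) and not with half-up rounding. Percentages render to one
  decimal, half-up.
* Confidence intervals use the Woolf log-OR construction
  `exp(ln OR ± z * sqrt(1/a + 1/b + 1/c + 1/d))`. The source never names its
  interval method; Woolf intervals reproduce the printed male-sex interval
  ([0.1–2.0]) at one-decimal rendering, which is why they were chosen. Zero
  cells make the OR undefined (`NA` with a warning); the Haldane–Anscombe
  0.5 correction is available but off by default.
* Group comparisons are complete-case per variable: each variable's
  denominators count only subjects with that variable recorded. Quantitative
  variables are gated by Shapiro–Wilk normality (both groups) and Levene
  variance homogeneity at α = 0.05 to choose between the equal-variance
  t-test and the Mann–Whitney U-test; with fewer than 3 observations in a
  group the normality gate cannot run and the rank test is used directly.
  Categorical variables use the chi-squared test unless any expected cell is
  below 5, then Fisher's exact test. All p values are two-sided; no
  multiple-testing correction is applied, matching the univariate design of
  the analysis this package supports.

## The synthetic-cohort generator

No raw subject data are published for this standardisation, so the package
generates cohorts with the statistical structure the analysis assumes; every
pipeline stage is tested against them.

**Volunteers** (`gen_volunteers()`). Ages are drawn by band with the
reference cohort's weights (29/31/19/17/6 over 20–30, 30–40, 40–50, 50–60,
60–72 years), uniformly within the band — the source gives only band counts,
so uniform is the least-informative within-band choice. Education is a
truncated Gaussian per band using each band's reported mean, SD and range;
age and education are therefore dependent through the band structure but
conditionally independent within a band. Each raw result is its normative
expectation plus Gaussian noise at the test's residual SD. Three realism
floors keep Gaussian tails from producing impossible values: timed results
are truncated below at 10 s, DST is rounded to a non-negative integer, and
the LTT composite is drawn from its linear model and then split into a
Poisson(5) error count and a back-solved time — only the composite's
distribution is contractual. These constants are documented arguments, not
hidden behaviour.

**Cirrhotic patients** (`gen_cirrhotics()`). The same demography shifted by
offsets chosen once from the printed group means (+11.2 years of age, −2.0
years of education). Each patient carries a performance deficit in
residual-SD units applied to all five tests in the pathological direction.
The deficit is heterogeneous: subject-level shifts are drawn from
`N(deficit_shift, shift_sd)` truncated at zero, with defaults
`deficit_shift = 2`, `shift_sd = 1`. A homogeneous 2-SD shift reproduces the
reported cirrhotic mean PHES (≈ −7.5) but would push classified prevalence
near 100%; a 1-SD between-subject spread is the simplest mechanism that also
yields the reported dispersion (PHES range down to −14, prevalence near
three-quarters). Clinical covariates (Child–Pugh class, ascites, jaundice,
prior GI haemorrhage) are drawn independently at the cohort's marginal
prevalences with configurable missingness (Child–Pugh missing in 7/50 by
default); their joint distribution with the deficit is *not* modelled.

**What passing tests do and do not show.** The generator emulates the
measurement model the scoring assumes — linear age/education effects with
homoscedastic Gaussian residuals and independent tests given demographics.
Real batteries have correlated residuals across tests, skewed timing
distributions, practice effects and demographically clustered missingness;
none of these are simulated. Green tests therefore validate the arithmetic
and the statistical plumbing, not the clinical validity of the norms.

## Numerical choices and problem sizes

* Banding is verified against a brute-force interval-membership oracle on a
  0.001-step grid over [−5, 5], and the PHES bound over all 5^5 component
  combinations.
* Parameter recovery runs 100 replicate synthetic cohorts of n = 2000 and
  requires every coefficient within 3 standard errors in at least 95 of
  them; self-normalisation scores a seeded n = 1000 cohort against norms
  fitted on itself and expects a mean PHES in [−0.6, 0.4] (the reference
  cohort observed −0.08 at n = 102). These sizes give stable checks in a few
  seconds on one CPU.
* Rank-deficient designs (constant age or education) abort the fit naming
  the collinear predictor; fits require at least 10 usable volunteers per
  test. A noise-free fit would give a zero residual SD, which is replaced by
  machine epsilon so the norm object stays valid — scoring against such a
  degenerate norm is meaningful only for exact-identity checks.
* Seeds are handled locally: generators accept a `seed` argument, restore
  the caller's RNG state afterwards, and identical `(n, config, seed)`
  triples produce identical cohorts.

## Known limitations

* The built-in constants are the printed two-decimal coefficients; the
  authors' unrounded estimates are unavailable, so scored Z values can
  differ from theirs in the third decimal.
* Whether the published per-test SDs are residual SDs from the fit is not
  stated; the `n − 3` convention is an assumption recorded above.
* Alternate population norms (e.g. the Spanish reference equations) are
  supported only through the JSON model format; the package does not
  re-estimate or embed them, and no cross-population score comparison is
  implemented.
* No imputation: missing demographics exclude a subject from fitting, and a
  missing battery value is a scoring error rather than a partial score.
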