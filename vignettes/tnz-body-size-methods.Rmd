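---
title: "Methods: thermoneutral zones, temperature gradients, and rodent body size"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermoneutral zones, temperature gradients, and rodent body size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnzsize)
```

## The scientific problem

Bergmann's rule predicts that endotherms are larger in colder climates,
yet many rodents do the opposite: they grow *larger* as their habitat
warms. One proposed mechanism runs through thermophysiology. Every
endotherm has a thermoneutral zone (TNZ) — the range of ambient
temperatures, bounded by a lower limit temperature (LLT) and an upper
limit temperature (ULT), within which no extra metabolic energy is spent
on thermoregulation. Populations of one species can evolve different TNZs
along a thermal gradient, and a population that spends more time inside
its TNZ can divert energy from heat production to growth. Testing this
idea requires chaining four analyses: (1) estimating population-specific
TNZs from respirometry, (2) aggregating daily climate series into an
annual site covariate, (3) fitting body-size regressions with the right
error structure, and (4) comparing causal pathway structures among
temperature, TNZ breadth and body size. `tnzsize` implements that chain,
plus a synthetic-data generator with known ground truth so that every
stage can be validated by parameter recovery.

## TNZ estimation from respirometry traces

Oxygen consumption is recorded at one-minute intervals at each chamber
temperature of the schedule 37.5, 35, 32.5, 30, 27.5, 25, 20, 15, 10,
5 degC (2.5-degree steps over the warm range, where the metabolic curve
bends, and 5-degree steps in the cold, where it is close to linear).
Temperature-specific resting metabolic rate (RMR) is the minimal oxygen
consumption sustained for at least five minutes — operationally, the
minimum over all contiguous five-minute windows of the window mean
(`min_window_rmr()`). Because a mean over a longer window can never fall
below the best window of minimal length, the five-minute window is the
operative case. The value is divided by body mass to give mass-specific
RMR in mL O2 g^-1 h^-1.

All animals of a site are pooled and a single polynomial of RMR on
temperature is fit per population (`fit_rmr_curve()`). Pooling (rather
than averaging per-animal curves) matches the reporting of one LLT/ULT
per population and is the numerically sensible choice at roughly six
animals per site. The fit minimises the residual sum of squares by
Nesterov-accelerated gradient descent on a mean-centred, unit-variance
temperature axis with norm-scaled monomial columns; the step size is the
reciprocal of the largest eigenvalue of the preconditioned normal matrix,
so the objective decreases monotonically and the optimum is the ordinary
least-squares solution (the test suite checks agreement with the
closed-form solution to 1e-6 in fitted values). Coefficients are mapped
back to the degC scale.

Limits are derived from the fitted curve's derivative
(`derive_tnz()`): the curve minimum (the basal metabolic rate, BMR) is
located first, then the LLT is the largest temperature below it where
dRMR/dT = -delta, and the ULT the smallest temperature above it where
dRMR/dT = +delta, each refined by root finding to 1e-6 degC. TNZ breadth
is `ult - llt` exactly.

### Why degree 6 and delta = 0.07

The true metabolic curve is, to a good approximation, a flat-bottomed U
with steep straight limbs (the Scholander-Irving form). A polynomial of
low degree cannot hold a flat bottom against two sharp shoulders: on
noiseless piecewise-linear data with limits at 29 and 31 degC and limb
slopes of ±0.22 mL O2 g^-1 h^-1 per degC, a quartic places its
threshold crossings no closer than about 0.65 degC (LLT) and 0.8 degC
(ULT) from the truth for *any* threshold delta. A degree-6 fit with
delta = 0.07 lands within about 0.1 degC of both limits, and delta
values of 0.05-0.10 all stay within 0.5 degC, so the defaults sit in
the middle of a stable plateau. Both knobs are arguments
(`degree` 2-6, `delta`), and the calibration is itself checked by the
recovery tests: noiseless traces must recover limits within 0.5 degC and
noisy traces (reading SD 0.05) must keep the median absolute limit error
below 0.5 degC over 200 replicates.

### A known limitation: attenuation of breadth differences

Because the polynomial smooths the shoulders, *between-population
differences* in TNZ breadth are compressed: populations generated with
breadths spanning 1.2-2.4 degC come back with estimated breadths
spanning a few tenths of a degree. The sign and ordering of the
breadth-temperature relationship survive (the effect-model slope on
estimated breadths is reliably negative, and the standardized SEM path
is strongly negative), but its natural-scale magnitude is biased toward
zero. Tests therefore check sign and significance on estimated
breadths, and magnitude recovery on true breadths. Any user comparing
breadth slopes across studies should treat the per-degC magnitude from
this estimator as conservative.

## Climate covariates

The annual mean minimum temperature (AnnMinTemp) of a site-year is the
arithmetic mean of its daily minimum temperatures over the calendar year
(January-December; the capture-year convention). A completeness guard
(default 300 days) refuses site-years whose missing days could bias the
seasonal mean. The spatial, site-level covariate is the mean of the 2022
and 2023 annual values. Trend models (AnnMinTemp against latitude,
longitude, altitude, year) and effect models (ULT, LLT, TNZ breadth
against AnnMinTemp) are ordinary least-squares fits with t tests on the
slope. Continuous predictors are standardized (mean 0, SD 1, n-1
denominator) for comparability; because headline slopes are usually
quoted per natural unit, every fit is reported on both scales.

## Body-size models

Individuals are assigned to five ontogenetic stages by body mass:
juvenile below 16 g, sub-adult 16-23 g, adult I above 23 up to 29 g,
adult II above 29 up to 37 g, old above 37 g. The published band wording
gives adult I a lower bound of 16 g, which would overlap sub-adult; the
package resolves this as a typographical slip (adult I starts above
23 g) and exposes `adult1_lower` for the literal reading, which assigns
the overlap to sub-adult and is therefore operationally identical.
Juveniles, old individuals and pregnant females are excluded from
modelling (`filter_records()`), with per-reason counts logged.

Body length and mass are positive and right-skewed, so the models are
gamma GLMMs with an *identity* link: the mean is
`intercept + slope * predictor + sex + stage + (1 | site or year)`,
keeping slopes on interpretable mm or g scales. Estimation is by Laplace
approximation (via `glmmTMB`), started from an intercept-only mean so
every initial fitted value is positive. Reference levels are female and
sub-adult; the choice only moves the intercept. The gamma distribution
uses the (mean, shape) parameterisation with scale = mean/shape, so the
identity-link mean is the distribution mean.

Wald tests use a t reference with between-within denominator degrees of
freedom: a predictor that is constant within grouping levels (site-level
AnnMinTemp, TNZ breadth, latitude, and so on) is effectively estimated
from as many points as there are groups, so its statistic is referred to
`n_groups` minus the number of group-level fixed terms (e.g. 9 - 2 = 7
for a site-level slope with intercept), while observation-level terms
(sex, stage) use residual degrees of freedom. With nine sites a normal
reference would reject a true null site-level slope roughly twice too
often; the package's calibration tests (type-I error 5% ± 2% over 500
null replicates) are run against the study's own design of nine sites,
so the df correction is part of the method, not a test convenience.

## Piecewise structural equation models

Three causal pathway structures relate site AnnMinTemp, TNZ breadth and
body length (sex and stage ride along as exogenous covariates of body
length):

1. AnnMinTemp -> body length and AnnMinTemp -> TNZ breadth only;
2. pathway 1 plus TNZ breadth -> body length;
3. pathway 1 plus a bidirectional (correlated-error) relation between
   TNZ breadth and body length.

Each component model keeps the error structure of the main analyses:
body-length components are gamma identity-link GLMMs with sex + stage
and a site random intercept; the TNZ-breadth component is a site-level
linear model, deliberately fit on the nine-site table rather than on
individuals to avoid pseudo-replication of a site-level response.

Goodness of fit uses the d-separation logic of piecewise SEM. The basis
set (`basis_set()`) contains one independence claim per pair of nodes
joined by neither an edge nor a correlated-error term, with the
causally downstream node as response, conditioned on that node's
parents. Conditioning on the response's parents (rather than on the
union of both nodes' parents) mirrors exactly how each claim is tested —
the claimed-independent variable is added to the downstream component
model and its Wald/F p-value taken — and every emitted claim is provably
d-separated by the local Markov property (a node is independent of its
non-descendants given its parents); the suite verifies this against a
brute-force moralization oracle on every DAG structure up to five nodes.
Claims between two exogenous nodes are untestable regressions of inputs
on inputs and are excluded, as is standard. Claims whose
claimed-independent variable is individual-level but whose response is
site-level (sex or stage against TNZ breadth) are tested on the
site-level table using composition shares (proportion male, stage
proportions), keeping the claim test at the level where the response
varies; this is what makes the Fisher's C null calibration achievable
with nine sites.

Claim p-values combine into Fisher's C = -2 * sum(log p), chi-square
with 2k degrees of freedom under the hypothesised graph, and pathways
are ranked by AIC = C + 2K, where K counts every estimated parameter
across component models: fixed effects, the random-intercept variance
and the gamma shape of the GLMM, the linear-model coefficients and
residual variance, plus one per correlated-error term. That makes
K = 10, 11, 11 for pathways 1-3. The correlated error of pathway 3 is
estimated as the Pearson correlation between site-aggregated residuals
of the two component models, with a t test on nine sites. Degenerate
claims whose component model has zero residual variance have an
undefined F statistic and are recorded as uninformative (p = 1);
underflowed p-values are floored at 1e-12 so a decisively violated
claim yields a huge but finite C. Standardized path estimates are
`slope * sd(predictor) / sd(response)` on the observation scale of the
component model.

## The synthetic-data generator

The generator (`synth_config()`, `simulate_study()`) encodes the study
conditions as its defaults: nine sites spanning about three degrees of
longitude and 1.15 km of elevation, sampled in 2022-2023 with ten
captures per site-year; AnnMinTemp rising 0.89 degC per degE, falling
2.32 degC per km, warming 0.26 degC per year, with 0.3 degC of residual
site-level scatter; body length rising 0.99 mm per degC of AnnMinTemp
around a 90 mm female sub-adult baseline, with a +2 mm male offset,
stage offsets, 1 mm site and 0.5 mm year random intercepts, and gamma
shape 400 (a 5% coefficient of variation, i.e. roughly 5 mm of residual
scatter); TNZ limits moving +0.15 (LLT) and -0.19 (ULT) degC per degC
so breadth narrows 0.34 degC per degC; and a Scholander curve with BMR
1.8 mL O2 g^-1 h^-1 and limb slopes ±0.22 (the cold limb from the
classical extrapolation-to-body-temperature rule, BMR divided by the
roughly 8 degC gap between body temperature and the LLT). Respirometry
traces are ten minutes per chamber temperature — long enough that the
five-minute window search has work to do — with N(0, 0.05) mass-specific
reading noise; trace durations are not standardised in the field
literature, so the length is a configurable assumption.

Stage is drawn first and body mass second, constrained to the stage's
band (gamma draws accepted only if they classify back to the assigned
stage, with a uniform in-band fallback), so stage classification
round-trips exactly on synthetic data. The cost is that the
mass-temperature slope is attenuated by the banding; mass-model tests
therefore check sign, not magnitude. Daily minimum temperatures are a
single seasonal sinusoid (amplitude 8 degC, coldest mid-January) plus
daily noise, re-centred so the annual mean equals the site-year truth
exactly — only the annual mean matters downstream, so no attempt is made
to emulate weather autocorrelation, and 365-day years are used
throughout. Randomness flows from one root seed through labelled child
streams (`child_seed()`), so generating one table never perturbs
another and identical configurations are bitwise reproducible.

What the generator does *not* emulate — spatial autocorrelation between
sites, measurement error in body length, trap-induced selection,
seasonal body-mass cycles, real ERA5 grid structure — bounds what
passing recovery tests show: they demonstrate that the estimators are
consistent and calibrated under the stated generating model, not that
field data meet that model.

## Numerical choices and degenerate inputs

* Gradient descent: preconditioned Nesterov iterations, step 1/L,
  convergence when the max-abs preconditioned gradient falls below
  1e-11, cap 100000 iterations; non-convergence returns a flagged fit
  with a warning rather than an error.
* `derive_tnz()` errors on monotone curves (no interior minimum) and
  returns boundary-clipped, flagged limits when the derivative never
  reaches ±delta inside the fitted temperature range.
* Identity-link positivity: fits start at an all-intercept mean;
  a fit whose final conditional means are not all positive is flagged
  unconverged.
* `fit_lm()` refuses constant predictors and fewer than three points;
  the GLMM refuses non-positive responses and fewer than two groups
  (pointing to a plain GLM instead).
* Ties in the AIC ranking are broken by smaller K.

## Problem sizes used in validation

The recovery and calibration experiments in the test suite use: 200
replicates for TNZ limit recovery under reading noise; 50 random point
sets for the optimizer-against-oracle check; 1000 random traces for the
window oracle; 100 replicates of roughly 2000 individuals across nine
sites for slope recovery; 500 null replicates of 225 individuals for
Wald calibration; and 500 nine-site replicates for the Fisher's C
calibration. These sizes give Monte-Carlo standard errors comfortably
inside the tolerance bands while keeping a full run of the suite in the
minutes range on a single core.

## A worked run

```{r pipeline, eval = FALSE}
res <- run_all(list(out_dir = tempfile(), seed = 42, synthetic = list()))
res$sem_results
res$tnz_estimates
report(res)
```

The same chain is scriptable from a shell via
`inst/scripts/tnzsize.R all --config config.yaml`, and
`scripts/acceptance.R` recomputes the package's checkable headline
numbers into JSON.
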