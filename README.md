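# tnzsize

Tools for linking ambient temperature, population-specific thermoneutral
zones (TNZ), and body size in small endotherms — built for the analysis
pattern of rodent monitoring studies in which Bergmann's rule fails and
animals grow *larger* as their habitat warms.

## What it does

A TNZ is the range of ambient temperatures, bounded by a lower (LLT) and
upper (ULT) limit temperature, within which an endotherm spends no extra
metabolic energy on thermoregulation; its breadth is
TNZ_b = ULT − LLT. `tnzsize` implements the full analysis chain around
that quantity:

* **TNZ estimation** (`estimate_population_tnz`): minute-resolution
  oxygen-consumption traces → minimal 5-minute sustained RMR per chamber
  temperature → mass-specific conversion → per-population polynomial
  RMR–temperature curve fit by (Nesterov-accelerated) gradient descent →
  LLT/ULT as the temperatures where the curve's derivative crosses
  ∓δ around the curve minimum (the BMR).
* **Climate covariates** (`annual_min_temp`, `spatial_ann_min_temp`):
  daily minimum temperature series → AnnMinTemp (annual mean of daily
  minima) per site-year, with a completeness guard; linear trend models
  (AnnMinTemp ~ latitude / longitude / altitude / year) and effect
  models (ULT / LLT / TNZ_b ~ AnnMinTemp) with slope t tests
  (`fit_lm`, `climate_trend_models`, `tnz_effect_models`).
* **Body-size models** (`fit_gamma_glmm`, `trend_and_effect_suite`):
  stage classification by body-mass bands, exclusion filters
  (juvenile / old / pregnant), and gamma GLMMs with an *identity* link —
  mean body size = α + slope·predictor + Sex + Stage + (1 | Site or
  Year) — so slopes stay in mm or g per unit.
* **Piecewise SEM** (`fit_pathways`, `basis_set`, `fishers_c`,
  `sem_aic`): three causal pathway structures among AnnMinTemp, TNZ_b
  and body length, evaluated by d-separation independence claims,
  Fisher's C = −2 Σ ln p (χ², df = 2k), and ranked by AIC = C + 2K.
* **Synthetic data** (`synth_config`, `simulate_study`): a generator
  with known ground truth (site climate, gamma body sizes with sex /
  stage / random-intercept structure, Scholander-type RMR curves) so
  every stage is testable by parameter recovery without any field data.

## Worked example

Simulate the default nine-site study and run the whole chain:

```r
library(tnzsize)
res <- run_all(list(out_dir = tempfile(), seed = 42, synthetic = list()))

res$sem_results
#>   pathway fisher_c df       c_p  K      aic rank
#> 1       1 6.246317  6 0.3961709 10 26.24632    1
#> 2       2 4.800029  4 0.3084379 11 26.80003    2
#> 3       3 4.800029  4 0.3084379 11 26.80003    3

head(res$tnz_estimates[, c("site", "llt", "ult", "tnz_b")], 3)
#>   site      llt      ult    tnz_b
#> 1  S01 29.45160 31.47580 2.024195
#> 2  S02 29.43506 31.31638 1.881320
#> 3  S03 29.45511 31.48251 2.027398
```

Reading this: every candidate pathway is consistent with the simulated
data (all Fisher's C p > 0.05); pathway 1 (direct temperature effects
only — the structure the generator actually uses) ranks first by AIC,
and pathways 2 and 3 share one Fisher's C because, once TNZ_b and body
length are linked, the same two independence claims remain. The
estimated limit temperatures sit near the generating values (LLT ≈
29.2–29.8 °C, ULT ≈ 31.0–31.6 °C across sites). The body-size battery
(`res$model_fits`) recovers a positive body-length–AnnMinTemp slope
(here 1.07 ± 0.64 mm °C⁻¹ against a generating 0.99) and a negative
TNZ-breadth–AnnMinTemp effect.

Each stage is also callable on its own (e.g.
`estimate_population_tnz(read.csv("rmr_traces.csv"))`), and a thin CLI
wrapper lives at `inst/scripts/tnzsize.R`.

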