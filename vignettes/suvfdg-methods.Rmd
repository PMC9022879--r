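---
title: "Methods: the FDG body-habitus normalizer, its evaluation, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the FDG body-habitus normalizer, its evaluation, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suvfdg)
```

## The model and its assumptions

PET tissue concentrations are first dose-normalized to %ID/ml
(`pct_id_per_ml()`, after decay correction to injection time with
`decay_correct()`; F-18 half-life 109.77 min, overridable). An SUV
metric multiplies %ID/ml by a body-habitus normalizer so that values can
be compared across patients. The package's central object is the
FDG-specific normalizer

$$\mathrm{BHN}(h, w) = 100\, e^{a h^3 + b h^2 + c h + d w + e}
\quad[\mathrm{ml}],$$

a third-order polynomial of height $h$ (m) plus a linear weight term $w$
(kg) in the exponent. It is derived under two assumptions:

1. **Normal liver is itself a good normalizer.** FDG uptake kinetics of
   a normal liver are assumed to lie in the same normal range across
   patients regardless of habitus, age or sex; liver %ID/ml is then
   roughly inversely proportional to an effective distribution volume,
   which the BHN estimates from height and weight alone.
2. **Confounding only inflates variance.** Any residual dependence of a
   metric on habitus adds variance on top of the tissue's intrinsic
   normal range, so among candidate normalizers the one producing the
   smallest coefficient of variation (CoV) in a normal tissue is the
   least confounded.

The model is fit on $\log(\mathrm{ml}/\%\mathrm{ID})$ — the *natural*
log, forced by the $e^{(\cdot)}$ form of the normalizer — which targets
percent accuracy and guarantees positivity. `SUVfdg = %ID/ml · BHN /
100` is then unitless and calibrated so normal liver averages 1.0.

The model family (`model_specs()`) brackets this choice: pure height
polynomials of order 2–4 (`H2`, `H3`, `H4`), height cubic plus weight
(`A`, the selected form), height quadratic plus weight (`B`), and weight
cubic plus height (`C`, the form that fails for small patients because
weight alone extrapolates poorly into the pediatric range).

## Fitting and model selection

`fit_model()` solves the ordinary least-squares problem via QR
(`stats::lm.fit`), with all patients weighted equally; coefficient
standard errors come from $\hat\sigma^2 (X'X)^{-1}$ and confidence
intervals use t-quantiles on $n-p$ degrees of freedom at the fixed 95%
level. A rank-deficient design (e.g. constant height) is refused with
the collinear columns named rather than silently dropped.

Information criteria (`information_criteria()`) use the Gaussian
profile-likelihood convention with the residual variance counted as a
parameter, $K = p + 1$:

$$\mathrm{AIC} = n \log(\mathrm{RSS}/n) + 2K, \qquad
\mathrm{BIC} = n \log(\mathrm{RSS}/n) + K \log n.$$

Additive likelihood constants are dropped, so absolute values are
toolbox-specific and only *differences between models on the same data*
are meaningful; the package's tests therefore assert orderings (model A
preferred on model-A data), never absolute criterion values. An exact
fit (RSS = 0) is flagged degenerate rather than given a finite score.

Residual diagnostics (`residual_correlation()`) test the fit residuals
against height or weight with the Pearson R→t conversion; an optional
age exclusion (typically under 12 y) prevents the few small patients
from dominating the correlation.

## Evaluation statistics

- **CoV** uses the sample (n−1) standard deviation over the mean
  throughout (the denominator convention is not dictated by the source
  material; n−1 is the package's fixed choice).
- **CoV about a fitted line** (`cov_about_fit()`) uses the regression
  residual variance RSS/(n−2); with a constant covariate it falls back
  to the plain CoV with a flag.
- **Pearson tests** (`pearson_test()`) convert R to
  $t = R\sqrt{n-2}/\sqrt{1-R^2}$ with two-tailed p on $n-2$ df. |R|
  within 1e−12 of 1 is reported as degenerate with p = 0.
- **Multiplicity**: significance in cross-validation reports is assessed
  at `bonferroni_alpha(0.05, 5) = 0.01` — matching the five-test family
  of the reference analysis — regardless of the chosen `k`; the
  threshold is overridable.
- **Welch t-test** wraps `stats::t.test(var.equal = FALSE)`
  (Welch–Satterthwaite df), used for the adult vs pediatric brain
  comparison.

`kfold_cross_validate()` shuffles patients once with the supplied seed,
splits them into k near-equal folds (remainders distributed one per
fold, deterministically), fits the model on each fold's complement, and
evaluates all four SUV metrics on the held-out patients — SUVfdg with
the fold-out coefficients. Correlations are computed *per fold and then
summarized* (mean ± sd across folds), matching the fold-wise
presentation of the reference analysis; pooling all validation patients
into a single correlation is the other defensible reading and was not
chosen. With the same seed the report is bit-reproducible.

`test_cohort_report()` fits once on the training cohort and tabulates
CoV and correlations to weight, height *and age* per tissue × metric on
an independent test cohort.

## Extrapolation policy

With the published coefficients the BHN is strictly increasing in both
height (the height derivative $6.09h^2 - 18.14h + 13.94$ has negative
discriminant) and weight ($d > 0$), so evaluation outside the training
envelope is mathematically safe — but monotonicity is *not* guaranteed
for refitted coefficients. `bhn_evaluate()` therefore computes outside
the plausibility envelope (default 0.6–2.1 m, 5–200 kg) with a warning
rather than refusing.

The LBM formula behind SUVlbm is ambiguous in the source citation; the
sex-specific Janmahasatian form (the PERCIST choice) is the default,
with the older James form selectable, and the choice is recorded in the
panel's metadata. All reported statistics (CoV, R) are invariant to the
scale of a metric, which also makes the SUVbsa convention (BSA in m²
times %ID/ml ÷ 100, no extra constant) a documentation issue rather
than a numerical one.

## The synthetic cohort generator

No clinical data ships with the package (the reference cohort was
retrospective and is not released), so `generate_cohort()` produces
cohorts with the *statistical structure the analysis assumes*:

- **Composition**: 330 training (153 adult women / 116 adult men / 61
  pediatric), 86 test (45/31/10), 65 brain-only (14/29/22). Group
  counts use deterministic largest-remainder allocation, because the
  reference composition is a fixed fact of the cohort rather than a
  draw; sampling it multinomially would only add nuisance variance.
- **Demographics**: truncated-normal heights per group (women
  1.62 ± 0.07 m, men 1.74 ± 0.09 m, pediatric 1.17 ± 0.20 m; bounds at
  roughly ±4 group sd keep truncation distortion negligible). Only
  marginal weight moments are published, so the height–weight coupling
  is a modeling choice: adults use weight = BMI · h² with lognormal BMI
  whose two parameters are solved in closed form from the truncated
  height moments to reproduce the printed weight mean ± sd (70 ± 19 kg
  women, 83 ± 20 kg men); pediatric weight is an allometric power law
  k·h^2.5 times lognormal noise, with k and the noise CoV solved
  numerically to give 23 ± 11 kg. The positive coupling matters: it is
  what makes weight-only models (C) fail and model A win on synthetic
  data, mirroring the clinical finding. Ages are uniform (adults
  13–91 y, pediatric 0.75–12 y, matching the roughly uniform enriched
  sampling of the reference cohort); pediatric sex is 50/50.
- **Tissues**: liver log(ml/%ID) equals the model-A polynomial at the
  published coefficients plus N(0, 0.16²) noise, so the
  true-coefficient liver SUVfdg is lognormal with mean
  $e^{\sigma^2/2} \approx 1.013$ and CoV
  $\sqrt{e^{\sigma^2}-1} \approx 0.161$. Blood SUVfdg is lognormal with
  mean 0.8 and **sd 0.11** (the printed 0.8 ± 0.11 is mean ± sd, i.e.
  CoV ≈ 0.14 — consistent with the independently printed blood CoV of
  0.14). Spleen uses mean 0.9 with CoV 0.16; the spleen *mean* is an
  assumption (only its CoV is printed) and is configurable. Brain
  SUVfdg is normal, 3.1 ± 0.6 for adults and 4.7 ± 0.9 for pediatric
  patients with the brain-specific cut at ≤ 18 y (the demographic
  pediatric cut, 12 y, is a separate named constant).
- **Dose rule**: 3.7 MBq/kg with ±10% uniform jitter. This is not
  stated in the source material; it cancels out of every SUV by
  construction and exists only to exercise the %ID/ml pathway. It is
  applied when demographics are sampled, since it depends on weight
  alone. Uptake times are uniform in the 55–75 min window.
- **Truth sidecar**: the generating coefficients and each measurement's
  true SUVfdg are returned (and serializable via
  `write_truth_sidecar()`) so recovery tests never have to re-derive
  the truth from the data.

Every sampler takes an explicit seed, uses inverse-CDF truncated-normal
draws, and restores the caller's RNG state, so cohorts are reproducible
bit for bit.

### What the generator does *not* emulate

No FDG kinetics (no compartment models or input functions), no scanner
effects or ROI delineation noise, no fatty-liver or other morbidity
correlated with habitus, no non-uniform age–height–weight joint
distribution beyond the group structure described above, and no
between-tissue within-patient correlation. A green test on synthetic
data therefore establishes that the *pipeline* is correct and
well-calibrated under the stated population model — not that the
published coefficient values are clinically optimal, which only the
unreleased cohort could show. For the same reason the package asserts
reproduction of printed *population parameters* (calibration means,
CoVs, orderings) rather than the clinical tables' exact cells.

## Numerical choices collected

- natural log response; canonical units m, kg, Bq, minutes;
- AIC/BIC with K = p + 1, profile Gaussian likelihood, constants
  dropped;
- 95% CIs everywhere; sample (n−1) sd; RSS/(n−2) for CoVf;
- fold remainders one-per-fold; per-fold-then-summarize correlations;
- |R| ≥ 1 − 1e−12 treated as degenerate; residual sd ≤ 1e−10 treated
  as an exact fit in diagnostics;
- seeds: 32-bit integers; derived sub-seeds stay below 2³¹;
- BHN evaluation outside the envelope warns, never refuses; refitted
  coefficients are not assumed monotone.

## Known limitations

The normalizer is a function of height and weight only; tracer
metabolism or excretion differences between patients are outside its
reach, as are blood-glucose corrections and direct body-composition
measurements. The polynomial family was selected among a small manual
set of forms, not an exhaustive search. The package reproduces the
methodology and its calibration targets; clinical re-validation of
coefficient values on local populations remains the user's
responsibility.
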