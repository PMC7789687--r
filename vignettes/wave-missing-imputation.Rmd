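---
title: "Recovering a wave-missing survey item: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering a wave-missing survey item: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavegap)
```

## The validation design

A questionnaire item dropped from one assessment of a longitudinal cohort is
missing for every respondent at that wave — *planned wave missingness*. In
wide format (one row per person) nothing identifies the conditional
distribution of the missing item, because it has no observed values at all.
Stacked in long format (one row per person per wave), the same variable has
a complete wave and a missing wave, and fully conditional specification
(FCS) multiple imputation can transport the item–item associations learned
at the complete wave to the missing one. The implicit assumption is
*measurement stability*: the conditional distribution of the item given its
predictors is the same at both waves. The synthetic generator satisfies this
by construction (same loadings and thresholds at both waves), so the
pipeline measures the procedure's behaviour under its own stated
assumptions; on real data, wave-to-wave drift would add bias that this
validation cannot see.

The validation itself is a masking experiment: generate (or load) a complete
two-wave cohort, set the target item to missing at wave 2 while keeping the
true values aside, impute `m` completed datasets, then score the imputations
against the held-out truth (confusion-matrix diagnostics) and check whether
regression associations with related constructs survive the substitution of
imputed for true values.

## The synthetic cohort generator

`generator_params()` / `generate_cohort()` produce the study conditions. The
construction is a graded-response (ordinal-probit) model, the minimal model
that yields correlated ordinal items with controllable rare-category
prevalence:

* Latent depression severity `z` per person-wave, bivariate normal across
  waves with correlation `cross_wave_rho` (default 0.6 — a plausible 3-year
  stability for a trait-like severity score).
* Item `j` at a wave scores `sum(loading_j * z + e > thresholds_j)` with
  standard-normal item noise. Depression items are 4-level (coded 0–3; the
  instrument defines response labels, not numeric codes, so the conventional
  0-origin coding is a package choice). Default loadings are 1 for items
  1–8 and 1.2 for the ideation item (ideation is among the most
  severity-saturated depression symptoms).
* Default thresholds are set analytically from target endorsement rates:
  `t_k = qnorm(1 - p_k) * sqrt(loading^2 + 1)`. Item 9's dichotomized
  ("several days" or more, i.e. code ≥ 1) wave-2 prevalence defaults to
  4.05%; item 4 ("feeling tired") uses 42.66% so the alternate-target
  experiment has a realistic common item; the remaining items use plausible
  screening-survey endorsement rates (12–45%).
* A PTSD latent correlated `ptsd_rho` (default 0.6) with the depression
  latent drives 17 PCL-C items coded 0–4 with "moderate or greater" = code
  ≥ 2; the screening composite requires moderate+ on ≥ 1 intrusion (items
  1–5), ≥ 3 avoidance (6–12) and ≥ 2 hyperarousal (13–17) items — the
  DSM-IV cluster partition (5/7/5) is the conventional item grouping, a
  package choice where only the rule itself is given. Physical-functioning
  (10 three-level items) and alcohol-problem (5 binary items) latents are
  handled the same way with correlations −0.35 and 0.35.
* Demographics (sex, age group, race/ethnicity, marital status, education)
  are drawn from configurable marginals. Their additive effects on latent
  severity default to **zero**: the default conditions isolate the
  imputation mechanism, keep the analytic threshold calibration exact, and
  make adjusted and unadjusted odds ratios coincide, so the configured
  outcome effects are the estimands without further bookkeeping. Nonzero
  effects are supported; after changing them (or any loading), re-run
  `calibrate_ideation_threshold()`, which bisects the ninth item's first
  cutpoint until the simulated prevalence is within ±0.1 percentage points
  of target (200,000 calibration draws by default, so the Monte-Carlo step
  size is far below the tolerance).
* Smoking status (never/former/current) and sleep category (≤5, 6, 7–9, ≥10
  hours) are drawn per wave from multinomial-logit models whose
  dichotomized-ideation coefficients are the logs of the configured odds
  ratios (defaults 1.23/1.87 for former/current smoking; 5.44/2.08/6.19 for
  ≤5h/6h/≥10h sleep) and whose intercepts are solved by fixed-point
  iteration so the marginal category distribution matches its target
  (59.3/26.8/13.9% smoking; 18.2/33.0/46.5/2.4% sleep — renormalised, as
  printed category distributions can sum to 100.1%). Outcomes are generated
  conditional on the *dichotomized* item because the benchmark association
  scale is the binary exposure. Sleep hours are whole numbers drawn within
  the category band (continuous in imputation, categorical in analysis).

What the generator does **not** emulate: enrollment design, attrition,
survey weighting, item-level nonresponse, measurement drift between waves,
or the full joint distribution of a real cohort. Passing tests therefore
show that the *procedure* behaves as claimed under a correct two-wave
graded-response world, not that a particular real cohort satisfies those
conditions.

```{r example, eval = FALSE}
co <- generate_cohort(generator_params(n_participants = 2000, seed = 1))
mean(dichotomize_ideation(co$phq9[co$wave == "W2"]))
```

## The FCS engine

`fit_fcs()` produces `m` completed datasets. Per imputation: missing cells
are initialised by draws from the observed margin; for `burn_in` cycles the
incomplete variables are visited in sequence, each one's univariate model is
refit and its missing cells redrawn; the last cycle is stored. In the
masking design only the target is incomplete and its predictors are fully
observed, so the chain is stationary after the first cycle; `burn_in`
defaults to 10 (a common FCS default) and tests use 2–3, which is exact in
this design. The engine nevertheless supports general multivariate
missingness, where the cycles matter.

*Discriminant imputer* (binary/ordinal/nominal variables): linear
discriminant class posteriors with proportional priors and pooled
covariance, fit on a bootstrap resample of the complete rows — the bootstrap
propagates parameter uncertainty, making the imputation approximately
proper. A resample that loses a class is retried (25 attempts, then the
original sample), since a fit without all observed classes cannot draw them.
Ordinal predictors enter as numeric scores; nominal predictors as dummy
indicators.

Numerical choices: the pooled covariance receives a ridge of `1e-6` on its
diagonal, and discriminant scores are computed on a whitened eigenbasis
dropping directions whose ridged eigenvalue falls below `1e-10` of the
largest (near-collinearity, e.g. the PTSD composite alongside its items, is
handled this way). The ridge is applied *before* the rank cut deliberately:
a direction with zero within-class variance but real class separation (a
predictor that copies the target) must dominate the posterior rather than
be discarded. With nothing dropped, the whitened computation equals the
direct `solve(S + ridge I)` Bayes rule to machine precision, which is how
the test oracle checks it.

*Linear imputer* (continuous variables): Bayesian linear regression — draw
the residual variance from its scaled inverse-chi-square posterior, the
coefficients from their conditional normal, then add predictive noise.

Seed management: one master seed spawns an independent sub-seed per
imputation, so `m` is parallelisable without changing results and reruns are
byte-identical.

## Evaluation conventions

Diagnostics (`confusion()`, `diag_stats()`, `pool_diagnostics()`) are
computed per imputed dataset and pooled as arithmetic means, in percent.
The parenthetical spread is the 2.5–97.5 percentile across imputations by
default, with min–max available (`interval = "range"`): published tables of
this kind rarely define their parentheses, so both are computed and neither
is asserted as *the* convention. Report rounding is half-up, integers for
sensitivity/specificity/PPV/NPV and two decimals for prevalence; full
precision is retained internally. Zero denominators yield `NA` with a
warning, never a silent zero. The random-assignment baseline is evaluated
with `m` independent assignments, mirroring pooling across imputations; its
expected sensitivity equals the assignment rate and its expected PPV the
truth prevalence, which the tests verify by simulation against the analytic
values.

Association recovery fits baseline-category multinomial logits (authored
in-package: full Newton–Raphson to a gradient max-norm below `1e-8`,
observed-information covariance, step-halving, divergence beyond |β| = 30
reported as complete separation, rank-deficient designs rejected) of
smoking and sleep category on the dichotomized exposure plus the fixed
covariate set, on wave-2 rows only — the target wave is the analysis wave,
stated explicitly rather than inferred. Age enters as categorical age-group
indicators (the generator emits groups). Pooling is on the log-odds scale
by Rubin's rules, then exponentiated; the degrees of freedom use the
classic `(m−1)(1 + W/((1+1/m)B))²` formula without the small-sample
adjustment, negligible at the study's `m = 100`. Ordinal-imputed targets
are dichotomized after imputation for *all* evaluation.

### A note on Rubin-interval calibration here

Under congenial imputation (the normal-mean experiment in the test suite)
the pooled intervals are calibrated, and the tests check their empirical
coverage against the nominal band. For the imputed-exposure association
models, however, the `ALL-*` imputation models condition on the analysis
outcome and many auxiliaries — strictly more than the analysis model uses.
This is the recommended practice for preserving associations (and the tests
confirm the pooled point estimate recovers the configured effect), but it
is also the textbook situation in which Rubin's total variance is
*conservative*: the tests measure coverage well above nominal, with the
Rubin variance a multiple of the empirical variance of the pooled estimate.
The association tests therefore assert confidence validity (coverage at
least nominal) and unbiasedness, not a two-sided calibration band.

## Problem sizes

The test suite scales the experiments to keep a full run around two
minutes: the preset-comparison experiment runs at n = 5,000 participants
with m = 20 imputations; coverage experiments use 200–500 replicates at
n = 80–1,500; full-cohort checks (threshold calibration to 4.05%,
random-assignment diagnostics, true-exposure association recovery) run at
the published n = 63,028, which the generator produces in seconds. The
acceptance script regenerates the full-size cohort and the 100
pseudo-imputation baseline from scratch at every invocation.

## Limitations

* Binary-target presets under-use the ordinal information and
  ordinal-target presets impute a higher dichotomized prevalence; with a
  rare item, false positives outnumber true positives for every informed
  model. Imputed values of a rare item are usable as covariates, not as
  prevalence estimates or individual-level screens.
* The discriminant imputer assumes class-conditional normality of the
  (numeric-scored) predictors; with ordinal predictors this is an
  approximation, and its miscalibration is precisely what the masking
  experiment quantifies.
* The engine is single-level: no multilevel/joint-model imputation, no
  predictive mean matching, and two waves only in the reshaping utilities
  (the wave label is kept open for extension).
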