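# wavegap

Recovering a survey item that is *completely missing at one wave* of a
longitudinal cohort, by multiple imputation — and measuring how well that
recovery works.

## The problem

Longitudinal surveys add and drop questions between waves. When an item (for
example the ninth, suicidal-ideation item of the PHQ-9 depression module) is
removed from one assessment, it is missing for *every* participant at that
wave, so no within-wave model can recover it. But the item was observed at
another wave, and if the data are stacked in **long format** (one row per
participant per wave), the item–item covariance observed at the complete wave
can inform the missing wave.

`wavegap` implements the full validation pipeline for this design, for
biostatisticians and cohort-study methodologists:

1. a **synthetic two-wave cohort generator** (graded-response ordinal items
   driven by a cross-wave-correlated latent severity, PTSD/physical
   functioning/alcohol modules, demographics, and smoking/sleep outcomes with
   configurable odds ratios to dichotomized ideation), so everything runs
   without access to any restricted cohort data;
2. **masking with held-out truth**: the target item is set to missing at
   wave 2, the true values are kept aside for scoring;
3. a from-scratch **fully conditional specification (FCS)** multiple-imputation
   engine producing *M* completed datasets, with **discriminant-function
   imputation** for categorical variables and Bayesian linear imputation for
   continuous ones, plus a **random-assignment (RAN) baseline**;
4. **diagnostic evaluation**: per-imputation confusion matrices against the
   held-out truth, pooled prevalence / sensitivity / specificity / PPV / NPV
   with across-imputation intervals;
5. **association recovery**: adjusted multinomial logistic models of smoking
   status and sleep-duration category on self-reported vs imputed ideation,
   pooled across imputations by Rubin's rules, with 95% CI-overlap flags.

## The statistics at the core

**FCS imputation.** Each incomplete variable is imputed from a univariate
model given all other modeled variables, cycling through a visit sequence.
For a categorical target with classes *g*, the discriminant imputer fits
class-conditional Gaussians with pooled covariance Σ (ridge-stabilised) on a
bootstrap resample of the complete rows and draws each missing value from

  P(g | x) ∝ π_g · exp( −½ (x−μ_g)ᵀ Σ⁻¹ (x−μ_g) ),  π_g the observed class fractions.

**Rubin's rules.** With per-imputation estimates Q₁…Q_M and variances
U₁…U_M: Q̄ = mean(Q), W = mean(U), B = var(Q), T = W + (1 + 1/M)·B, and a 95%
CI from the t distribution with ν = (M−1)(1 + W/((1+1/M)B))² degrees of
freedom.

**Model presets** mirror the validation study: `PHQ-BIN` / `PHQ-ORD` use the
8 remaining depression items as predictors with a binary / 4-level target;
`ALL-BIN` / `ALL-ORD` add demographics, 10 physical-functioning items, the
17 PCL-C items plus the PTSD screen, smoking, continuous sleep duration and
5 alcohol items (48 predictors); `RAN` assigns the target at random at the
observed prevalence. Ordinal-imputed targets are dichotomized *after*
imputation, mirroring how analyses use them.

## Worked example

```r
library(wavegap)
cfg <- experiment_config(
  params  = generator_params(n_participants = 3000, seed = 42),
  presets = c("RAN", "PHQ-BIN", "PHQ-ORD"),
  m = 10, burn_in = 5, seed = 2026)
bundle <- run_experiment(cfg)
print(bundle)
```

```
Validation experiment: n = 3000, truth prevalence 3.57%
Diagnostics (pooled):
      statistic Self-reported              RAN          PHQ-BIN          PHQ-ORD
  True negative          2893 2789 (2777-2800) 2793 (2783-2802) 2762 (2731-2782)
  True positive           107          5 (1-8)       43 (35-48)       53 (51-55)
 False negative             -     102 (99-106)       64 (59-72)       55 (52-56)
 False positive             -     104 (93-116)     100 (91-110)     131 (111-162)
     Prevalence          3.57 3.64 (3.17-4.07) 4.79 (4.38-5.10) 6.10 (5.45-7.21)
    Sensitivity             -          5 (1-7)       40 (33-45)       49 (48-51)
    Specificity             -       96 (96-97)       97 (96-97)       95 (94-96)
            PPV             -          4 (1-7)       30 (26-34)       29 (25-32)
            NPV             -       96 (96-97)       98 (97-98)       98 (98-98)

Smoking associations (AOR, 95% CI; * = no overlap with self-report):
         model            former           current
 Self-reported 1.59 (1.03, 2.46) 1.55 (0.90, 2.65)
       PHQ-BIN 1.27 (0.81, 1.97) 1.65 (0.94, 2.91)
       PHQ-ORD 1.21 (0.81, 1.83) 1.68 (1.05, 2.71)
```

Reading the output: the informed imputation models recover 40–49% of the
truly ideation-positive participants (versus 5% for random assignment at the
same prevalence), specificity and NPV stay high because the item is rare,
and the 4-level (`PHQ-ORD`) model imputes a *higher* prevalence than the
binary one — the over/under-estimation pattern this validation design is
built to expose. Association estimates from imputed exposure stay
directionally right and their CIs overlap the self-report benchmark for
smoking; the attenuated sleep `le5` interval is flagged (`*`). Counts and
parenthetical ranges are pooled means and 2.5–97.5 percentile intervals
across the `m` imputations.

The alternate-target run (`run_alternate_target(cfg, "phq4")`) re-runs the
identical pipeline on the commonly endorsed "feeling tired" item (~43%
endorsement), which is imputed with much higher sensitivity than the rare
ideation item — the rare-outcome penalty in one command.

## Documentation

The methods vignette (`vignettes/wave-missing-imputation.Rmd`) describes the
generative model, the imputation engine's numerical choices, the pooling and
rounding conventions, and the package's limitations.
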