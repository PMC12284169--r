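---
title: "Methods: longitudinal brain-age-gap rate analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal brain-age-gap rate analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bagrate)
library(dplyr)
```

## The problem

Brain age is the age a regression model predicts for a person from their
imaging-derived phenotypes (IDPs) — scalar MRI features such as regional
volumes, cortical thickness, or white-matter diffusion metrics. The
brain-age gap (BAG), written $\delta = Y_B - Y$ where $Y_B$ is predicted
and $Y$ chronological age, is a compact marker of brain health: positive
$\delta$ means an older-appearing brain. With two scans per person, the
rate of change

$$R_{BAG} = \frac{\delta_{t2} - \delta_{t1}}{\Delta T},$$

with $\Delta T$ the inter-scan interval in years, measures how fast a
brain is ageing relative to the calendar. `bagrate` implements the full
chain needed to compare $R_{BAG}$ between groups — for instance, people
whose second scan fell after a population-level disruption such as the
COVID-19 pandemic versus people scanned twice before it — together with a
synthetic cohort generator, so the whole pipeline can be exercised and
validated without access-controlled data.

## The brain-age model

`fit_brain_age_model()` trains, per stratum (sex and tissue type are the
conventional strata), the following chain. Every parameter is estimated on
training rows and frozen; `predict()` never refits anything on new data.

1. **Deconfounding.** Least-squares weights map the confound matrix (plus
   intercept) to every IDP; residualised training IDPs are exactly
   uncorrelated with each confound. At prediction time the *training*
   weights are applied to the new rows. Age-derived variables must not be
   included among the confounds, or the signal of interest is removed.
2. **Standardisation.** Per-feature z-scoring with training mean/SD. IDPs
   carry wildly different units; without this the SVD is dominated by
   scale. The source method is silent on this step; we consider it
   required for a mixed-unit feature table.
3. **SVD reduction.** The top $k$ right singular vectors (default
   $k = 50$) of the standardised table; the retained
   variance fractions are reported in the model object.
4. **Age regression.** Ordinary least squares of $Y$ on the $k$ component
   scores gives $Y_B$ and the raw gap $\delta_{raw} = Y_B - Y$.
5. **Bias correction.** Raw gaps are strongly age-dependent (regression
   toward the mean). A second least-squares fit of $\delta_{raw}$ on the
   age basis $[1, Y, Y^2]$ is subtracted, leaving a corrected gap
   orthogonal to age and age squared at machine precision
   (asserted at $10^{-10}$ on training rows). The quadratic basis allows
   the curvature the underlying method recommends; `bias_basis = "linear"`
   is available.

For unseen data the training-fitted correction is evaluated at each new
subject's age. Re-estimating the correction on the new cohort
(`refit_bias = TRUE`) is available but off by default: the train-once
contract is what makes t1/t2 predictions comparable. (Reports of
essentially zero gap–age correlation on unseen cohorts are tighter than
sampling noise allows unless the correction was re-estimated there; both
behaviours are provided, and the default keeps training weights only.)

### Measurement attenuation and the age-response gain

A genuine brain-age offset must be read through the same noisy
feature-to-age channel as chronological age itself, so measured gaps are
shrunk relative to true gaps by the model's *age-response gain* — the
slope of predicted on true age in training, numerically the in-sample
$R^2$ (about 0.8 when the model's accuracy is $r \approx 0.9$). This is
the classical errors-in-variables attenuation, and it propagates
multiplicatively into measured $R_{BAG}$ group differences. The fitted
model stores its gain, and `predict(..., deattenuate = TRUE)` divides
corrected gaps by it. The pipeline reports group contrasts on the
measured scale (what the field's figures display) and, separately, a
`recovery` summary on the deattenuated scale, which is the right scale
for comparing against a known injected effect. We verified empirically on
synthetic cohorts that measured differences run at roughly the gain times
the injected value and that the deattenuated estimator is unbiased within
sampling error (this is exercised by the test suite).

### Cross-validation protocol

`crossvalidate_brain_age()` implements 20-fold cross-validation repeated
100 times with random fold re-assignment (both configurable). Per fold the
*entire* chain — deconfounder, standardisation, SVD, regression, bias
correction — is refit on the remaining folds, so out-of-fold predictions
are leakage-free; a dedicated test checks that repeated CV on pure-noise
features yields a null-centred distribution of out-of-fold $r$. Pearson
$r$ and MAE are computed on the pooled out-of-fold predictions of each
repetition and then summarised across repetitions (pooling per repetition,
rather than averaging per-fold metrics, avoids small-fold instability).
Fold assignment is stratified by age decile by default so every fold spans
the age range; plain random assignment is a switch.

## Longitudinal quantities

`compute_rbag()` pairs each participant's sessions and computes $R_{BAG}$
and the average age $(Age_{t1} + Age_{t2})/2$ with exact arithmetic.
`age_effect_regression()` regresses $R_{BAG}$ on average age — the average
of the two scan ages balances the estimate against varying inter-scan
intervals — and reports the slope both in years/year per year of age and
multiplied by 365.25 into days/year. Unit conversions (12 months/year,
365.25 days/year) are lossless helpers; month-and-day renderings such as
"5 months and 25 days" are display-only, with the raw value always kept.

`reproducibility_stats()` quantifies scan-rescan stability three ways:
Pearson correlation of the two predicted ages; ICC(2,1) — two-way random
effects, absolute agreement, single measure — computed from the two-way
ANOVA mean squares with the standard F-based confidence interval; and the
partial correlation after residualising each session's prediction on its
own session's age. ICC(2,1) was chosen over the consistency form because
the scientific claim is stability of the *same* quantity over time, which
an additive session offset should penalise; the test suite pins the
implementation to an ANOVA-table oracle on a hand example.

## Group statistics

* **Effect sizes and tests.** `cohens_d()` uses the pooled-SD definition.
  `two_sample_tests()` wraps the pooled-variance Student t (Welch as a
  switch) and the Mann–Whitney test (exact for small tie-free samples,
  tie-corrected normal approximation otherwise), emitting tidy one-row
  results with a family label.
* **FDR.** `fdr_bh()`/`adjust_family()` apply Benjamini–Hochberg step-up
  within families. Which p-values share a family is a modelling choice;
  the convention here is one family per analysis panel, and the family id
  is mandatory in outputs so users can re-pool.
* **Permutation ANOVA.** `permutation_anova_2x2()` tests both main
  effects and the interaction of a 2x2 design with the Freedman–Lane
  scheme: for each effect, the other terms are nuisance; the response is
  residualised on the nuisance-only model, residuals are permuted, the
  nuisance fit is added back, and the effect's F statistic is recomputed.
  The default of 5000 permutations matches common practice; p-values use
  the add-one convention $p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$ so
  they are never exactly zero and are valid at finite $n_{perm}$. With an
  intercept-only nuisance the scheme reduces to plain label permutation,
  which the tests verify against exhaustive enumeration. An F statistic is
  reported; for two-level factors any t-contrast is a monotone transform
  of it, so permutation p-values are unaffected by that choice.
* **Calibration bands.** `wilson_ci()` provides the Wilson score interval
  used to judge empirical rejection rates; for a nominal 5% test checked
  with 5000 draws the band is (0.0443, 0.0564). The test suite runs 1000
  replicate null datasets and requires the interaction's empirical
  rejection rate to fall inside its own Wilson band.
* **Deprivation stratification.** `stratify_by_percentile()` labels
  scores strictly above the 70th percentile "high" and strictly below the
  30th "low" (linear-interpolation quantiles; the middle band is excluded,
  mirroring an above/below design; the reference population for the
  percentiles is configurable). `deprivation_clock()` reports the low-high
  difference in mean $R_{BAG}$ with its months-and-days rendering.

## Cognition

`cognitive_change()` computes the percentage change
$(Score_{t2} - Score_{t1}) \times 100 / Score_{t1}$ and the
interval-normalised rate $(Score_{t2} - Score_{t1})/\Delta T$. For timed
tests (Trail Making Test completion times), positive change means worse
performance. `sliding_window_curve()` smooths change against $R_{BAG}$
with a moving window (default width 3 in the units of the x variable,
grid step width/10, minimum 5 points per window — under-populated windows
are omitted rather than interpolated). `rbag_cognition_association()`
reports the full Pearson correlation and the partial correlation after
residualising both variables on average age. The window width is
configurable because the natural display unit of $R_{BAG}$ (months/year
vs years/year) changes the meaning of a fixed-width window.

## The synthetic cohort generator

The generator (`simulation_config()`, `generate_training_cohort()`,
`generate_longitudinal_cohort()`, `generate_cognitive_scores()`) emulates
the statistical structure the estimator assumes, with every injected
quantity recorded in a ground-truth table:

* **Ages** are truncated Gaussian: 62.6 ± 7.6 years on [45, 82] for the
  training cohort and 58.8 ± 6.2 for the longitudinal cohort, matching
  the study population this pipeline targets.
* **IDPs** are linear-Gaussian and low-rank:
  $X = Z L^\top + c\,C B + E$, where the first $q$ latent components load
  on standardised *effective age* (chronological age plus true BAG) with
  loading 0.55, a further block of components (default 40) is
  age-orthogonal, subject-stable "trait" structure, $C$ is a generic
  confound matrix (46 variables by default), and $E$ is iid noise set by
  the structured-to-noise variance ratio (default 4). Linear truth was
  chosen because the estimator is linear. The trait block matters: without
  it, SVD-50 retains pure-noise directions and scan-rescan reproducibility
  collapses, which real anatomy-rich IDP tables do not show.
* **Longitudinal structure.** Each participant has a true baseline BAG
  (SD 3.5 years) and a true BAG rate composed of a common drift, an
  age-dependent drift (0.00821 y/y per year — about 3 days/year), the
  Pandemic group offset (`true_rbag_effect`, default 0.458 y/y), an extra
  offset for deprived (employment score below the cohort's 30th
  percentile) Pandemic participants, and Gaussian noise (SD 0.3).
  Second-session features encode the resulting BAG increment through the
  same loadings. Non-age latent scores persist across sessions with
  correlation 0.985, and confound values with 0.9 (head size, site and
  similar are largely stable within a person): these two stability knobs
  set the scan-rescan reproducibility the generator emulates.
* **Intervals and dates.** Control intervals are Gaussian around 2.25
  years (narrow, truncated to [1.8, 2.8]); Pandemic intervals are uniform
  on [1.0, 4.5], reaching down to one year, so the standard 10%/2-year
  interval filter has real work to do. Scan dates are placed so Controls
  have both scans before the configurable onset date (default 2020-03-01)
  and Pandemic participants straddle it.
* **Cognition.** A positive baseline completion time and a follow-up
  equal to baseline times
  $(1 + (\text{drift} + \text{coupling} \times R_{BAG}^{true} \times \text{infected} + \text{noise})/100)$;
  the coupling (default 15% per y/y) applies only to the infected
  subgroup, so an infected-only association is a construction fact that
  recovery tests can verify against ground truth.
* **Seeds.** One master seed; each stage (structural loadings, training
  draw, longitudinal draw, cognition, CV, permutations) derives a fixed
  child seed, so stages regenerate independently and byte-identically.

**Scale.** Defaults are desk-scale: 2000 training participants, 200 IDPs,
400 per longitudinal group. These sizes keep a full pipeline run in
seconds and the repeated-CV suites in minutes on a single CPU while
leaving every estimator comfortably identified; they are deliberately far
below the population-imaging scale (tens of thousands of participants,
over a thousand IDPs per tissue) on which the reference results in this
literature are computed. Consequences are visible and expected: per-sex
models reach $r \approx 0.86$–0.89 and MAE near 3 years, scan-rescan
$r \approx 0.95$ and ICC around 0.8–0.9 rather than the ~0.98 reported at
full scale, because deconfounder estimation error and regression noise
shrink with $n$.

**What passing tests do and do not show.** The generator is linear and
Gaussian with independent confounds and a single injected group effect.
Passing recovery tests shows the pipeline is correct and calibrated under
its own assumptions; it says nothing about non-linear ageing trajectories,
realistic IDP covariance (e.g. FreeSurfer regional correlation structure),
scanner or site effects beyond generic confounds, informative missingness,
or selection effects in who returns for a second scan.

## Numerical choices and conventions

* Quantiles are linear-interpolation (type 7) everywhere; ties at filter
  thresholds are retained (strict inequalities).
* The 5-SD IDP outlier rule flags cells per column against the column
  mean/SD; zero-variance columns flag nothing (with a warning). The
  exclusion policy is any-flagged-cell by default, with a configurable
  flagged-fraction threshold. The rule is applied per session; whether
  pooling sessions first would be preferable is left as an explicit
  option for the analyst because the choice is not identified by the
  method itself.
* The interval filter removes rows below the 10th percentile *or* below
  2.0 years; because the percentile is recomputed on whatever table it is
  given, only the absolute rule is idempotent under re-application — the
  attached QC report records both criteria's counts, and the intended
  usage is a single pass.
* Orthogonality assertions use a $10^{-10}$ tolerance on standardised
  data; SVD rank is judged against `max(dim) * eps * d[1]`.
* Degenerate inputs have documented conventions rather than errors where
  a convention is defensible: constant response in the permutation ANOVA
  gives p = 1 for every effect; a constant covariate has SMD 0; an
  all-tied Mann–Whitney comparison has p = 1; zero-variance correlation
  inputs are reported as undefined (`NA`) with a message.
* Rank-deficient confound matrices fall back to the minimum-norm
  (pseudo-inverse) solution with a warning.

## Orchestration

`run_pipeline()` chains the stages (simulate, QC, fit per sex, predict
both sessions, BAG rates, group statistics, deprivation, cognition) and
returns tidy tibbles plus a manifest (package version, seed, settings,
config hash, row accounting). With `out_dir` set it writes each stage
table as CSV and the manifest as JSON — plain-text intermediates, chosen
for inspectability. Exclusion counts at every stage are carried in
`qc_report()` attributes and mirrored in the manifest, so participants
out of one stage always equal participants into the next plus logged
exclusions. The package's interface is R functions and this vignette;
`scripts/acceptance.R` is a thin reproduction script over the same
functions.

## Known limitations

* Two time points only: the rate $R_{BAG}$ is the estimand; no
  mixed-effects trajectory modelling.
* The balance machinery ships diagnostics (standardised mean differences
  and tests), not a matching algorithm: what downstream inference relies
  on is achieved balance, and an optional matcher would not change the
  contract.
* Attenuation correction divides by an estimated gain; at very low model
  accuracy the correction inflates variance roughly as 1/gain and should
  be read with its standard error.
* The 2x2 permutation machinery does not extend to covariate-adjusted
  (ANCOVA-style) designs or spatial inference; those are out of scope.
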