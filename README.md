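# bagrate

Longitudinal brain-age-gap (BAG) rate analysis for tabular
imaging-derived phenotypes (IDPs), with a seeded synthetic-cohort
generator for validation.

## What it is for

Brain-age models predict a person's age from MRI-derived features; the
brain-age gap $\delta = Y_B - Y$ (predicted minus chronological age) is a
brain-health marker. With two scans per participant, the rate of change

$$R_{BAG} = \frac{\delta_{t2} - \delta_{t1}}{\Delta T}$$

(years of BAG per year of follow-up, $\Delta T$ the inter-scan interval)
measures accelerated or decelerated brain ageing. `bagrate` is aimed at
researchers analysing longitudinal imaging cohorts — for example, asking
whether people whose second scan fell after the COVID-19 pandemic onset
aged faster than people scanned twice before it, and how that interacts
with sex and socio-demographic deprivation.

The package covers the full chain:

* **Unbiased brain-age model** — confound removal with training-set
  weights, per-feature standardisation, SVD reduction (top 50 components
  by default), linear age regression, and a quadratic age-bias correction
  that leaves the corrected gap orthogonal to age at machine precision;
  sex/tissue-stratified; 20-fold × 100-repeat cross-validation.
* **QC** — 5-SD technical-outlier flagging, the 10%/2-year inter-scan
  interval filter, pandemic/control group assignment from scan dates,
  covariate balance diagnostics (standardised mean differences).
* **Longitudinal statistics** — $R_{BAG}$, regression of $R_{BAG}$ on
  average age (reported in days/year), scan-rescan reproducibility
  (Pearson, ICC(2,1) with CI, age-controlled partial correlation).
* **Group inference** — Cohen's d, t and Mann–Whitney tests,
  Benjamini–Hochberg FDR by family, 2×2 permutation ANOVA
  (Freedman–Lane, 5000 permutations) with Wilson-interval calibration
  bands, 30th/70th-percentile deprivation stratification and
  months-and-days "clocks".
* **Cognition** — percentage and interval-normalised change in test
  scores, sliding-window curves against $R_{BAG}$, full and
  age-partialled correlations.
* **Synthetic cohorts** — a generator with Gaussian age marginals,
  age-driven low-rank IDP structure, confound contamination, paired scans
  with group-specific intervals, and injectable effects (group offset on
  the true BAG rate, deprivation interaction, infected-only cognitive
  coupling), all recorded in a ground-truth table for recovery tests.

Everything is data-frame in, tibble out, and composes with the pipe;
fitted objects have `tidy()`/`glance()` methods and `autoplot()`/`plot_*`
displays.

## Worked example

```r
library(bagrate)
library(dplyr)

cfg <- simulation_config(seed = 7)   # defaults: 2000 training, 400/group
run <- run_pipeline(cfg, k = 50, n_perm = 5000)

glance(run$models[["F"]])
#>   n_train n_idps     k variance_explained train_r train_mae sex   tissue
#> 1    1108    200    50              0.852   0.882      2.72 F     GM

run
#> bagrate pipeline run
#>   participants after QC: 629
#>   Pandemic vs Control R_BAG comparisons:
#>   label    estimate cohen_d        p    p_fdr
#> 1 G1 vs G2  0.461    0.721  3.48e-18 1.39e-17
#> 2 G3 vs G2  0.468    0.682  1.84e- 8 2.45e- 8
#> 3 G4 vs G2  0.458    0.710  2.52e-14 5.04e-14
#> 4 G3 vs G4  0.00932  0.0171 8.95e- 1 8.95e- 1
#>   pandemic x sex permutation ANOVA:
#>   effect      statistic        p
#> 1 factor_a       79.1   0.000200
#> 2 factor_b        1.64  0.209
#> 3 interaction     0.630 0.416
```

Reading this: the female-stratum model predicts age with in-sample
r = 0.88 and MAE = 2.7 years from 50 SVD components. After QC, 629
longitudinal participants remain. The Pandemic group's (G1) BAG grows
0.461 y/y faster than Controls' (G2) on the measured scale — about 5.5
months of extra brain age per year — with Cohen's d = 0.72, and both the
infected (G3) and uninfected (G4) pandemic subgroups show the effect
while differing negligibly from each other. The permutation ANOVA flags
the pandemic factor (p = 2e-4, the add-one minimum at 5000 permutations);
sex and the interaction are null here because the generator injected no
sex effect.

```r
run$recovery
#>   estimate     se conf_low conf_high scale
#> 1    0.612 0.0662    0.482     0.742 deattenuated
```

The recovery summary rescales the measured difference by the model's
age-response gain (measured gaps are attenuated by roughly the age
regression's R²; see the methods vignette). The deattenuated estimate
0.612 ± 0.066 matches the realised injected difference of 0.607 y/y
(0.458 group offset plus the deprivation-interaction share).

```r
run$deprivation |>
  filter(index == "dep_employment") |>
  select(group, difference, months_days)
#>   group    difference months_days
#> 1 Control       0.197 2 months and 11 days
#> 2 Pandemic      0.438 5 months and 8 days
```

Deprived (low employment score) participants age faster than well-off
ones by 5 months and 8 days of BAG per year within the Pandemic group,
versus 2 months and 11 days in Controls — the injected
pandemic × deprivation interaction.

## Vignette

`vignettes/bagrate-methods.Rmd` documents the model and its assumptions,
the attenuation correction, every tunable parameter with units and
defaults, the generator's design (what it emulates and what it does
not), numerical conventions, and known limitations.
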