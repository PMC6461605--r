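# longimorph

Statistical tools for longitudinal brain morphometry in small, rare-disease
cohorts — built around the design of a longitudinal imaging study of
Wolfram syndrome, in which 29 patients (1–7 annual MRI visits) and 52
pooled diabetic/non-diabetic controls (1–3 visits) were compared with two
complementary approaches: regional random-slope mixed models and
voxel-wise tensor-based morphometry (TBM) with sandwich-estimator
inference. The package is aimed at biostatisticians and imaging
methodologists who need these analyses as reusable, testable code, and —
because the original patient data cannot be shared — ships a
synthetic-cohort generator reproducing the study's published structure so
every method can be exercised, validated and power-analysed end to end.

## What it implements

**Synthetic cohorts** (`cohort_design()`, `generate_cohort()`,
`simulate_roi_volumes()`, `simulate_wurs()`, `simulate_tbm_stack()`):
unbalanced annual-visit cohorts; regional volume trajectories
`V_ij = a_i + b_i t_ij + e_ij` with group-specific slope distributions
taken from the study's published annual rates (thalamus −84.68 mm³/yr in
patients vs +11.26 in controls, etc.); eTIV head-size coupling; severity
scores rank-coupled to thalamic decline; and Jacobian-determinant map
stacks (midpoint and group-template variants) with injectable effect
clusters.

**ROI mixed models** (`fit_random_slope()`, `backward_select()`,
`annual_percent_change()`, `wurs_slope_correlation()`): REML random-slope
models `V_ij = x_ij'β + b_0i + b_1i t_ij + e_ij` with Satterthwaite
Type-III tests, tier-respecting backward selection from the full
group × time × age model, per-subject BLUP slopes scaled to annual percent
change with one-tailed slope-vs-zero tests, and Bonferroni-corrected
Spearman correlations (criterion 0.05/5 = 0.01).

**Voxel-wise marginal model** (`swe_design()`, `fit_marginal()`,
`form_clusters()`, `wild_bootstrap_fwe()`): per-voxel OLS with the
subject-level sandwich covariance
`(X'X)⁻¹ [Σ_i X_i' ẽ_i ẽ_i' X_i] (X'X)⁻¹` (HC2-type block adjustment,
group covariances never pooled), Wald/χ² statistic maps, connected-
component clusters at a p = 0.001 cluster-forming threshold, and
wild-bootstrap (Rademacher subject signs, null-imposed residuals)
cluster-extent FWE correction, `p_FWE = (1 + #{max_b ≥ s})/(B + 1)`.

**Trial power** (`trial_design()`, `empirical_power()`,
`analytic_power()`, `min_sample_size()`): Monte-Carlo power for a
two-arm, 3-year, six-monthly trial slowing the annual rate of regional
volume loss, cross-checked against the closed-form slope-variance oracle
`v = σ_e²/S_xx + σ_b²`, `power = Φ(|Δ|/√(2v/n) − z_{1−α/2})`.

All study presets (group sizes, visit-count distributions, annual rates
and SEMs, coupling strengths, trial grid) live in one editable parameter
file, `inst/extdata/longimorph_params.yaml`. The methods vignette
(`vignettes/longimorph-methods.Rmd`) documents every model, default and
numerical choice.

## Worked example

```r
library(longimorph)

cohort <- generate_cohort(cohort_design(seed = 1))
vols   <- correct_for_etiv(simulate_roi_volumes(cohort))
mf     <- roi_model_frame(vols, cohort, region = "thalamus")
fit    <- fit_random_slope(mf, mixed_model_spec(outcome = "thalamus",
            fixed_terms = c("group", "time", "group:time")))
fit
#> Random-slope mixed model (thalamus)
#>                term estimate     se     df       t         p
#> 1       (Intercept)  7569.50  94.42  79.28 80.1726 1.185e-77
#> 2      groupwolfram   -50.24 157.60  78.88 -0.3188 7.507e-01
#> 3              time     4.70  11.59 150.22  0.4055 6.857e-01
#> 4 groupwolfram:time  -102.80  14.97  64.86 -6.8660 3.018e-09
#>   var(intercept) 4.56e+05  var(slope) 1.13e+03  cov 967  var(resid) 8.85e+03
```

The `time` coefficient is the control-group annual change (+4.7 mm³/yr,
not significant: stable thalamus in controls) and the
`groupwolfram:time` interaction the patient excess decline
(−102.8 mm³/yr in this simulated cohort, generated around the preset
−84.68 − 11.26 ≈ −96 difference; p ≈ 3e-9).

```r
annual_percent_change(fit, mf)
#>     region   group  n mean_rate sem_rate mean_pct sem_pct      t df        p tail
#> 1 thalamus control 52       4.7     1.72   0.0614  0.0223   2.73 51 4.31e-03  one
#> 2 thalamus wolfram 29     -98.1     4.35  -1.3569  0.0717 -22.54 28 8.64e-20  one
```

Per-subject BLUP slopes scaled by each participant's own mean corrected
volume: patients lose ≈ 1.36 %/yr of thalamic volume in this draw,
controls are essentially flat; one-tailed t tests vs 0.

```r
d <- trial_design(n_per_arm = 34, reduction = 0.5, n_trials = 200, seed = 1)
empirical_power(d)
#>   n_per_arm reduction empirical_power  mc_se n_trials n_nonconverged
#> 1        34       0.5           0.985 0.0086      200              0
analytic_power(d)
#> [1] 0.964
```

Empirical and closed-form power agree within Monte-Carlo error. (With
the packaged default variances the thalamic slope is measured precisely,
so 34 per arm is comfortably overpowered for a 50 % slowing; the
parameter file controls both variance components.)

`run_pipeline(pipeline_config(seed = 1))` chains cohort generation, all
five regional analyses, the four voxel-wise contrasts with bootstrap FWE
correction, and the power simulation, writing CSV/NIfTI/JSON artefacts,
a selection trace, the resolved configuration and a log to one output
directory, deterministically per seed.

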