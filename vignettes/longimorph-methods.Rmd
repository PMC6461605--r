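---
title: "Methods: longitudinal morphometry models in longimorph"
author: "longimorph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal morphometry models in longimorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`longimorph` implements the statistical core of a longitudinal brain
morphometry study of a rare neurological disease (Wolfram syndrome):
unbalanced annual-visit cohorts, regional random-slope mixed models,
voxel-wise marginal-model inference on tensor-based morphometry (TBM)
maps with wild-bootstrap cluster-extent family-wise-error (FWE)
correction, and Monte-Carlo power estimation for a slope-slowing
clinical trial. Because the underlying patient data cannot be shared,
the package pairs each analysis with a synthetic-data generator that
reproduces the study's cohort structure and published group-level
parameters, so every method can be exercised and validated end to end.

## The synthetic cohort

`cohort_design()` / `generate_cohort()` emulate a two-group cohort: a
patient group followed annually for 1–7 visits and a pooled control
group (diabetic and non-diabetic) followed for 1–3 visits. The packaged
defaults (editable in `inst/extdata/longimorph_params.yaml`) are 29
patients and 52 controls, all patients diabetic, 24 of 52 controls
diabetic, sex counts 15/14 and 27/25 male/female, and baseline ages
drawn uniformly on 5.9–25.8 and 6.0–26.2 years.

Visit-count distributions are not published; only the single-timepoint
counts (4/29 and 12/52) and the mean follow-up (3.6 and 2.0 years) are.
We therefore calibrated the default distributions so that those
observables are matched in expectation: patient weights (4,3,4,5,5,4,4)
over 1–7 visits give an expected follow-up of exactly 3.6 years among
multi-visit participants at a unit mean inter-visit interval, and
control weights (12,2,38) over 1–3 visits give 1.95 years. Whether the
real visits were exactly annual is unknown; we model intervals as
Normal(1, 0.1²) years truncated below, a jitter a scheduling-driven
annual protocol would plausibly produce. Each participant draws from a
deterministic RNG substream (`derive_seed()`), so cohorts are bitwise
reproducible and stable under unrelated design edits.

Time enters the analyses in two forms mirroring longitudinal
registration pipelines: `time_from_baseline` (years since first scan)
and `time_to_midpoint` (signed years from the participant's mean scan
age, summing to zero within participant).

## Regional volume trajectories

`simulate_roi_volumes()` mirrors the model later fitted to the data:
per-participant intercepts and annual slopes drawn from group-specific
normal distributions, plus homoscedastic visit-level noise,

$$V_{ij} = \big(a_i + b_i\, t_{ij} + \varepsilon_{ij}\big)\,
  \big(1 + c\,(e_i/\bar e - 1)\big),$$

with $a_i \sim N(\mu_a, \sigma_a^2)$, $b_i \sim N(\beta_g, \sigma_b^2)$,
$\varepsilon_{ij} \sim N(0, \sigma_e^2)$, and a linear head-size
coupling of strength $c$ to the participant's estimated total
intracranial volume (eTIV, log-normal with mean 1.5·10⁶ mm³). At the
default $c = 1$ proportional eTIV correction
(`correct_for_etiv()`, scaling each volume by
$\bar e_{\mathrm{ref}}/e_i$, the atlas-scaling convention; a
residual-regression alternative is available) removes the coupling
exactly, so the correction step is genuinely exercised.

Group mean slopes $\beta_g$ default to the published annual rates for
five regions (brainstem, ventral pons, cerebellar white and gray
matter, thalamus; e.g. thalamus −84.68 mm³/yr in patients, +11.26 in
controls). Between-subject slope SDs are not published; we set
$\sigma_b = \mathrm{SEM}\times\sqrt{n}$ from the published SEMs, the SD
implied if the SEM describes a mean of per-subject slopes. Baseline
means/SDs and residual SDs are unpublished; the defaults are plausible
FreeSurfer-scale values (e.g. thalamus 7600 ± 700 mm³, residual 90 mm³)
kept in the parameter file so all analyses reference one editable
source.

## Severity scores and the rank-correlation coupling

`simulate_wurs()` produces nonnegative symptom-severity (WURS Physical)
scores for the patient group, rank-coupled to thalamic decline through
a latent bivariate-normal construction: a latent Gaussian correlated
with the standardized slopes at Pearson level $\rho$, pushed through a
monotone log-normal transform (median ≈ 15). Monotonicity makes the
score/slope Spearman correlation exactly that of the latent pair.

For a bivariate normal, the population Spearman is
$\rho_s = (6/\pi)\arcsin(\rho/2)$; `spearman_to_pearson()` inverts
this, and `wurs_latent_coupling(target, n = Inf)` uses it. The study's
reported correlation, however, is a *sample* Spearman at $n = 17$, and
the sample coefficient is biased toward zero:
$E[r_s] = \frac{6}{\pi(n+1)}\big[\arcsin\rho + (n-2)\arcsin(\rho/2)\big]$.
The packaged default coupling therefore inverts this finite-$n$
expectation at the study's $n = 17$ (latent $\rho \approx -0.718$), so
the expected sample correlation equals the reported −0.669 rather than
only its asymptotic limit. Both calibrations are exposed; the choice of
$n$ is a parameter-file entry.

## ROI random-slope mixed models

`fit_random_slope()` fits, by REML through `lme4`/`lmerTest`,

$$V_{ij} = \mathbf{x}_{ij}'\boldsymbol\beta + b_{0i} + b_{1i} t_{ij} +
 \varepsilon_{ij},$$

with an unstructured 2×2 covariance for $(b_{0i}, b_{1i})$. The study
describes fitting "a separate regression line for each participant";
a per-participant line needs both a random intercept and a random
slope, so that is the default; a slope-only structure (used by the
trial simulator, below) and intercept-only are selectable.
Fixed-effect t statistics and Type-III F tests use Satterthwaite
denominator degrees of freedom — the study names no df method, and
Satterthwaite is the common mixed-model convention. The full fixed
structure is the three-way interaction of group, time and age at first
session, all two-way interactions, and sex and diabetes main effects.
"Age" is age at the first session, a participant-level covariate, and
is entered uncentred. Participants with a single visit are retained
(they inform intercepts and variance components).

`backward_select()` removes, one per step, the most non-significant
term with $p > \alpha$, working down the order tiers (three-way, then
two-way, then main effects), never removing a term contained in a
retained higher-order interaction. Eligibility p values come from the
Type-III table.

Per-subject slopes combine the fixed-effect time derivative at the
participant's own covariates with the slope BLUP, so they are shrunken
toward the group trajectory. `annual_percent_change()` scales each
slope by the mean of that participant's own corrected volumes
(×100 %/yr), summarises per group with SEMs, and tests the slopes
against zero with a one-sample t test — one-tailed in the direction of
the observed group mean by default (the display convention used for
annual-percent-change figures), two-tailed on request; model term tests
remain two-tailed throughout. `wurs_slope_correlation()` computes the
Spearman correlation (average ranks under ties) with a Bonferroni
criterion $\alpha/n_{\mathrm{tests}}$ (0.05/5 = 0.01 for the packaged
five-region family).

## Voxel-wise marginal model with sandwich covariance

For TBM stacks (one Jacobian-determinant map per scan, expansion > 1,
contraction < 1), `fit_marginal()` fits per-voxel OLS over all maps and
estimates the covariance of a contrast non-iteratively from
subject-level residual outer products,

$$\widehat{\mathrm{cov}}(\hat\beta) = (X'X)^{-1}
 \Big[\sum_i X_i'\tilde e_i \tilde e_i' X_i\Big] (X'X)^{-1},$$

the "sandwich" marginal model for longitudinal imaging: no
within-subject convergence problems, and each subject's — hence each
group's — covariance enters only through its own term, never pooled
across groups. Residual blocks are adjusted as
$\tilde e_i = (I - H_{ii})^{-1/2} e_i$ (HC2-type) by default to reduce
small-sample bias; the unadjusted estimator is selectable, and with one
scan per subject the two reduce to the classical HC2/HC0 robust OLS
covariances (verified against the `sandwich` package in the tests).
Which exact covariance flavour the original SwE analysis used is not
published; we document ours rather than claim bit-equality. The Wald
statistic $(C\hat\beta)'[C\hat V C']^{-1}(C\hat\beta)$ is referred to a
χ² with rank(C) df and thresholded on the p scale, so single- and
multi-df contrasts are handled uniformly. Voxels whose residuals are
numerically zero (below 10⁻²⁰ of the data scale in sum of squares) are
reported at p = 1 and counted, rather than dividing rounding noise by
rounding noise. Raw Jacobians are analysed by default; a log option
exists since the generator is linear on the log scale.

Group-difference contrasts use the scan-to-group-template maps (all
participants, controlling eTIV, age, sex, diabetes); longitudinal
contrasts (group×time, group×time×age, time within group) use the
scan-to-midpoint maps, excluding single-visit participants, whose
midpoint maps are uninformative constants.

`form_clusters()` labels connected components of the suprathreshold set
(cluster-forming p = 0.001 by default) with 18-neighbour connectivity
(the SPM convention; 6 and 26 selectable), deterministically in
lexicographic order. `wild_bootstrap_fwe()` then fits the null-imposed
model (design projected onto the contrast's null space), multiplies
each subject's restricted residual block by an independent Rademacher
sign, refits, and records the maximum suprathreshold cluster size; an
observed cluster of size $s$ gets
$p_{\mathrm{FWE}} = (1 + \#\{\max_b \ge s\})/(B+1)$, with floor
$1/(B+1)$ (0.001 at the conventional B = 999).

A desk-scale caveat: at small cohort sizes cluster extents are small
integers, so the max-size null distribution is heavily tied and the
achieved FWE level sits below the nominal 0.05 (nearer 0.03 at B = 99
with ~20 subjects in our null calibration experiments, which use
10+10 subjects with 2–3 visits on a 16³ grid with a radius-5.5 voxel
spherical mask, noise SD 0.03, cluster-forming p = 0.01 and 200
simulated analyses). This is the usual discreteness of resampling
cluster inference, not anticonservatism; at the study's scale (81
participants, smooth maps, B = 999) the granularity is much finer. The
generator's voxel noise is spatially independent, which real
registration-derived Jacobian maps are not — passing calibration here
does not by itself demonstrate behaviour on smooth fields.

## Trial power simulation

`simulate_trial()` follows the study's trial model exactly: two arms of
equal size measured every six months for three years, per-subject
slopes Normal(arm mean, σ_b²), treatment mean slope
$(1-\text{reduction})\times$ placebo slope, homoscedastic error, no
random intercept (arms share the baseline mean). `trial_test()`
delegates to the same random-slope machinery (slope-only random
structure) and tests arm×time two-sided with a Satterthwaite Wald t at
α = 0.05. `empirical_power()` reports the rejection fraction over
`n_trials` simulated trials (1000 by convention) with its binomial
Monte-Carlo SE; non-convergent fits are excluded from the denominator
with a logged count.

`analytic_power()` is an independent closed-form oracle: the
per-subject OLS slope over the grid has variance
$v = \sigma_e^2/S_{xx} + \sigma_b^2$ (with $S_{xx} = 7.0$ for visits
0, 0.5, …, 3), and the two-sample z power is
$\Phi(|\Delta|/\sqrt{2v/n} - z_{1-\alpha/2})$ plus the opposite tail.
`min_sample_size()` brackets with the oracle and bisects on the integer
grid using seeded empirical power.

The study's variance estimates behind its published 34/48
patients-per-arm figures were never printed; with the parameter-file
defaults (σ_b from the SEM-derived value, σ_e = 90 mm³) the thalamic
slope is measured much more precisely and the minimal arm sizes are
correspondingly smaller. The published figures therefore serve as an
ordering anchor — a 60 % slowing never needs more patients than a 50 %
slowing — which the package reproduces, not as numeric targets.

## Numerical and design notes

* Degenerate (noise-free) mixed-model fits are permitted: `lme4`'s
  observation-count checks are relaxed and convergence/singularity are
  reported as flags, so exact-recovery tests can assert equality to
  1e-6. Term-test and BLUP computation can be switched off in
  simulation loops for speed.
* All generators consume named substreams of one master seed; equal
  seeds give bitwise-equal cohorts, volume tables, stacks and bootstrap
  null distributions.
* Cluster tables are 1-based voxel indices in R; the CSV writer emits
  0-based coordinates and says so in a header comment. CSVs are UTF-8,
  comma-separated, `.` decimal.
* Monte-Carlo problem sizes in the shipped tests (200 simulated
  cohorts for rate recovery; 200 null analyses × 99 bootstraps for FWE
  calibration; 1000 trials per power cell on a 3×3 grid of
  n ∈ {15, 25, 40} × reduction ∈ {0.4, 0.5, 0.6}) were chosen to keep
  Monte-Carlo SEs small relative to the quantities checked while
  remaining single-CPU friendly.
* Known limitations: no simulation of registration, segmentation or
  spatially smooth noise fields; no dropout or interim analyses in the
  trial simulator; χ² reference for the voxel-wise Wald statistic is
  asymptotic in the subject count (the wild bootstrap, not the χ² p,
  carries the cluster-level inference).

## A worked pass

```{r, eval = FALSE}
library(longimorph)

cohort <- generate_cohort(cohort_design(seed = 1))
vols <- correct_for_etiv(simulate_roi_volumes(cohort))
mf <- roi_model_frame(vols, cohort, region = "thalamus")
sel <- backward_select(mf, mixed_model_spec(outcome = "thalamus"))
annual_percent_change(sel$fit, mf)

stack <- simulate_tbm_stack(
  cohort, grid_dim = c(16, 16, 16),
  effect_spec = list(cluster = cube_cluster(c(16, 16, 16), half = 1),
                     slope = c(wolfram = -0.02, control = 0.005)))
sub <- stack_subset(stack, "to_midpoint")
des <- swe_design(sub$meta, c("group", "time", "age", "sex",
                              "diabetes", "group:time"))
wild_bootstrap_fwe(sub, des, swe_contrast(des, c("group:time" = 1)),
                   B = 199)

empirical_power(trial_design(n_per_arm = 34, reduction = 0.5,
                             n_trials = 200, seed = 1))
```

`run_pipeline(pipeline_config(seed = 1))` chains all stages and writes
the artefacts, the resolved configuration and a log to one directory.
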