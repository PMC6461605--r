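# Default study presets for the longimorph synthetic-cohort generator and
# downstream analyses. All volumes in mm^3, times in years.
#
# Quantities the source study reports (group sizes, age ranges, sex counts,
# annual-rate means and SEMs, the WURS/thalamus sample correlation) are
# entered as reported; quantities it does not report (visit-count
# distributions, baseline volume means/SDs, residual SDs, eTIV spread,
# interval jitter) are calibrated or plausible defaults, documented in the
# methods vignette. Edit here, not in code.

cohort:
  n_wolfram: 29
  n_control: 52
  diabetic_control_fraction: 0.46153846153846156   # 24 of 52
  sex_balance:
    wolfram: 0.5172413793103449                    # 15 M of 29
    control: 0.5192307692307693                    # 27 M of 52
  baseline_age_range:
    wolfram: [5.9, 25.8]
    control: [6.0, 26.2]
  # Probability of 1..K annual visits. Calibrated so that the expected
  # follow-up among multi-visit participants is 3.6 yr (Wolfram) and
  # ~2.0 yr (controls) at a unit mean interval, and the single-visit mass
  # is 4/29 and 12/52.
  visit_count_probs:
    wolfram:  [4, 3, 4, 5, 5, 4, 4]     # over 1..7 visits; normalised in code
    control:  [12, 2, 38]               # over 1..3 visits
  inter_visit_interval:
    mean: 1.0
    jitter_sd: 0.1

etiv:
  # log-normal, E[eTIV] = 1.5e6 mm^3
  meanlog: 14.21778
  sdlog: 0.08
  # reference for proportional head-size correction; NULL-like 0 means
  # "use the cohort mean" downstream
  reference: 1500000

# Per-region trajectory presets. mean_slope (mm^3/yr) and slope_sem are the
# reported group annual rates; slope_sd is derived in code as sem * sqrt(n).
# baseline_* and residual_sd are generator defaults (not reported upstream).
regions:
  brainstem:
    mean_slope:   {wolfram: -123.61, control: 182.39}
    slope_sem:    {wolfram: 26.08,   control: 17.71}
    baseline_mean: 21000
    baseline_sd:   2000
    residual_sd:   250
    etiv_coupling: 1.0
  ventral_pons:
    mean_slope:   {wolfram: -48.44, control: 93.23}
    slope_sem:    {wolfram: 18.33,  control: 12.34}
    baseline_mean: 5200
    baseline_sd:   600
    residual_sd:   120
    etiv_coupling: 1.0
  cerebellar_white:
    mean_slope:   {wolfram: 24.32,  control: 248.91}
    slope_sem:    {wolfram: 26.24,  control: 18.02}
    baseline_mean: 14500
    baseline_sd:   1800
    residual_sd:   280
    etiv_coupling: 1.0
  cerebellar_gray:
    mean_slope:   {wolfram: -420.95, control: -49.26}
    slope_sem:    {wolfram: 82.49,   control: 60.43}
    baseline_mean: 52000
    baseline_sd:   5000
    residual_sd:   600
    etiv_coupling: 1.0
  thalamus:
    mean_slope:   {wolfram: -84.68, control: 11.26}
    slope_sem:    {wolfram: 5.86,   control: 4.81}
    baseline_mean: 7600
    baseline_sd:   700
    residual_sd:   90
    etiv_coupling: 1.0

wurs:
  # Observed sample Spearman between thalamic annual percent change and the
  # WURS Physical score, and the n it was computed at. The generator's
  # latent Pearson coupling is calibrated so the EXPECTED sample Spearman
  # at reference_n reproduces this value (see vignette).
  target_sample_spearman: -0.669
  reference_n: 17
  # monotone log-normal score transform of the latent Gaussian
  score_meanlog: 2.708   # median score ~15
  score_sdlog: 0.6

tbm:
  noise_sd: 0.03         # SD of voxel log-Jacobian noise
  subject_offset_sd: 0.05
  grid_spacing: 1.5      # mm

trial:
  visit_times: [0.0, 0.5, 1.0, 1.5, 2.0, 2.5, 3.0]
  alpha: 0.05
  n_trials: 1000
  # defaults for the thalamus trial: placebo slope from the region preset,
  # slope_sd = sem * sqrt(29), residual_sd from the region preset
  region: thalamus
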