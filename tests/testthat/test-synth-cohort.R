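test_that("default cohort reproduces the study structure exactly", {
  ch <- generate_cohort(cohort_design(seed = 11))
  p <- ch$participants
  expect_equal(sum(p$group == "wolfram"), 29)
  expect_equal(sum(p$group == "control"), 52)
  expect_true(all(p$diabetes[p$group == "wolfram"] == 1L))
  expect_equal(sum(p$diabetes[p$group == "control"]), 24)
  expect_equal(sum(p$sex[p$group == "wolfram"] == "M"), 15)
  expect_equal(sum(p$sex[p$group == "control"] == "M"), 27)
  expect_true(all(p$etiv > 0))
  nv <- table(ch$visits$participant_id)
  expect_true(all(nv[p$id[p$group == "wolfram"]] %in% 1:7))
  expect_true(all(nv[p$id[p$group == "control"]] %in% 1:3))
  rng <- longimorph_params()$cohort$baseline_age_range
  expect_true(all(p$baseline_age[p$group == "wolfram"] >= rng$wolfram[1] &
                    p$baseline_age[p$group == "wolfram"] <= rng$wolfram[2]))
})

test_that("visit time covariates respect the mid-point definition", {
  ch <- generate_cohort(cohort_design(seed = 3))
  v <- ch$visits
  expect_true(all(tapply(v$session, v$participant_id,
                         function(s) all(diff(s) == 1))))
  expect_true(all(v$time_from_baseline[v$session == 1] == 0))
  sums <- tapply(v$time_to_midpoint, v$participant_id, sum)
  expect_true(max(abs(sums)) < 1e-9)
})

test_that("single-visit-only design gives one visit and zero midpoint time", {
  d <- cohort_design(n_wolfram = 5, n_control = 5,
                     visit_count_probs = list(wolfram = c(1),
                                              control = c(1)),
                     seed = 2)
  ch <- generate_cohort(d)
  expect_equal(nrow(ch$visits), 10)
  expect_true(all(ch$visits$time_to_midpoint == 0))
})

test_that("cohort generation is bitwise reproducible under a fixed seed", {
  a <- generate_cohort(cohort_design(seed = 19))
  b <- generate_cohort(cohort_design(seed = 19))
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_design(seed = 20))
  expect_false(identical(a$participants$baseline_age,
                         c2$participants$baseline_age))
})

test_that("follow-up calibration matches the direct expectation over the distribution", {
  pv <- longimorph_params()$cohort$visit_count_probs$wolfram
  target <- expected_followup(pv, interval_mean = 1)
  expect_equal(target, 3.6, tolerance = 1e-12)

  d <- cohort_design(seed = 101)
  fus <- replicate(300, NA_real_)
  for (r in seq_len(300)) {
    ch <- generate_cohort(d, seed = derive_seed(101, r))
    fu <- tapply(ch$visits$time_from_baseline, ch$visits$participant_id,
                 max)
    grp <- ch$participants$group[match(names(fu), ch$participants$id)]
    fus[r] <- mean(fu[grp == "wolfram" & fu > 0])
  }
  mc_se <- sd(fus) / sqrt(length(fus))
  expect_lt(abs(mean(fus) - target), 2 * mc_se + 1e-12)
})

test_that("invalid designs are rejected as configuration errors", {
  expect_error(cohort_design(n_wolfram = 0), class = "longimorph_config_error")
  expect_error(cohort_design(interval_mean = 0),
               class = "longimorph_config_error")
  expect_error(
    cohort_design(visit_count_probs = list(wolfram = c(-1, 2),
                                           control = c(1))),
    class = "longimorph_config_error")
  expect_error(
    cohort_design(visit_count_probs = list(wolfram = rep(1, 9),
                                           control = c(1))),
    class = "longimorph_config_error")
})

test_that("noise-free trajectories lie exactly on the group mean lines", {
  ch <- generate_cohort(small_design(seed = 5))
  p <- noise_free_params()
  vols <- simulate_roi_volumes(ch, p, regions = "thalamus")
  df <- vols$volumes
  ms <- unlist(p$regions$thalamus$mean_slope)[df$group]
  expected <- p$regions$thalamus$baseline_mean + ms * df$time_from_baseline
  expect_equal(df$volume, unname(expected), tolerance = 1e-12)
})

test_that("missing region parameters raise a configuration error", {
  ch <- generate_cohort(small_design())
  expect_error(simulate_roi_volumes(ch, regions = "hippocampus"),
               class = "longimorph_config_error")
})

test_that("per-participant OLS slopes are unbiased for the latent slopes", {
  diffs <- numeric(0)
  for (r in 1:40) {
    ch <- generate_cohort(small_design(seed = derive_seed(500, r),
                                       probs_w = c(0, 0, 1, 1),
                                       probs_c = c(0, 0, 1)))
    vols <- simulate_roi_volumes(ch, regions = "thalamus",
                                 seed = derive_seed(501, r))
    vols <- correct_for_etiv(vols, reference_etiv = vols$reference_etiv)
    df <- vols$volumes
    lat <- vols$latents
    for (id in unique(df$participant_id)) {
      d_i <- df[df$participant_id == id, ]
      b <- coef(lm(volume_corrected ~ time_from_baseline, data = d_i))[2]
      diffs <- c(diffs, b - lat$true_slope[lat$participant_id == id])
    }
  }
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("volume simulation is reproducible and coupling-correctable", {
  ch <- generate_cohort(small_design(seed = 8))
  a <- simulate_roi_volumes(ch, regions = "thalamus", seed = 42)
  b <- simulate_roi_volumes(ch, regions = "thalamus", seed = 42)
  expect_identical(a, b)
  ## proportional correction at coupling 1 recovers the latent trajectory
  corr <- correct_for_etiv(a, reference_etiv = a$reference_etiv)
  df <- corr$volumes
  lat <- corr$latents
  i <- match(df$participant_id, lat$participant_id)
  resid_lat <- df$volume_corrected -
    (lat$true_intercept[i] + lat$true_slope[i] * df$time_from_baseline)
  expect_lt(sd(resid_lat),
            longimorph_params()$regions$thalamus$residual_sd * 1.5)
  fit <- lm(volume_corrected ~ etiv, data = df)
  ## corrected volumes carry no residual head-size trend
  expect_lt(abs(coef(fit)[2]), 2 * summary(fit)$coefficients[2, 2] + 1e-3)
})
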