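test_that("eTIV correction scales proportionally and is idempotent", {
  df <- data.frame(participant_id = c("a", "b", "c"), region = "thalamus",
                   volume = c(1000, 1000, 1000),
                   etiv = c(1.5e6, 3.0e6, 1.5e6))
  out <- correct_for_etiv(df, reference_etiv = 1.5e6)
  expect_equal(out$volume_corrected, c(1000, 500, 1000))
  out2 <- correct_for_etiv(out, reference_etiv = 1.5e6)
  expect_equal(out2$volume_corrected, out$volume_corrected)
  expect_error(correct_for_etiv(transform(df, etiv = c(1, 0, 1))),
               class = "longimorph_data_error")
})

test_that("residual-method correction removes the pooled eTIV trend", {
  ch <- generate_cohort(cohort_design(seed = 31))
  vols <- simulate_roi_volumes(ch, regions = "brainstem", seed = 32)
  out <- correct_for_etiv(vols$volumes, method = "residual")
  fit <- lm(volume_corrected ~ etiv, data = out)
  expect_lt(abs(coef(fit)[["etiv"]]), 1e-8)
})

test_that("model specs enforce term hierarchy and valid alpha", {
  expect_error(mixed_model_spec(fixed_terms = c("group", "group:time")),
               class = "longimorph_config_error")
  expect_error(mixed_model_spec(fixed_terms = c("group", "time", "age",
                                                "group:time:age")),
               class = "longimorph_config_error")
  expect_error(mixed_model_spec(alpha = 0), class = "longimorph_config_error")
  expect_silent(mixed_model_spec(fixed_terms = c("group", "time",
                                                 "group:time")))
})

test_that("noise-free fits reproduce the generator coefficients", {
  ch <- generate_cohort(small_design(seed = 41, probs_w = c(0, 0, 1, 1),
                                     probs_c = c(0, 0, 1)))
  p <- noise_free_params()
  p$regions$thalamus$mean_slope <- list(wolfram = -80, control = 10)
  vols <- simulate_roi_volumes(ch, p, regions = "thalamus")
  mf <- roi_model_frame(vols, ch, region = "thalamus")
  fit <- fit_random_slope(mf, mixed_model_spec(
    fixed_terms = c("group", "time", "group:time")))
  fe <- setNames(fit$fixed_effects$estimate, fit$fixed_effects$term)
  expect_equal(fe[["(Intercept)"]], p$regions$thalamus$baseline_mean,
               tolerance = 1e-6)
  expect_equal(fe[["groupwolfram"]], 0, tolerance = 1e-6)
  expect_equal(fe[["time"]], 10, tolerance = 1e-6)
  expect_equal(fe[["groupwolfram:time"]], -90, tolerance = 1e-6)
  expect_lt(fit$varcomp$slope_var, 1e-6)
  ## per-subject slopes equal the group means exactly
  ps <- fit$per_subject_slopes
  expect_equal(ps$slope[ps$group == "wolfram"],
               rep(-80, sum(ps$group == "wolfram")), tolerance = 1e-6)
})

test_that("balanced two-visit random-intercept fit equals the paired-difference mean", {
  set.seed(77)
  n <- 14
  a <- rnorm(n, 5000, 300)
  dv <- rnorm(n, -40, 25)  # per-subject observed differences over 1 yr
  mf <- data.frame(
    y = c(rbind(a, a + dv)),
    id = factor(rep(seq_len(n), each = 2)),
    group = factor("control", levels = c("control", "wolfram")),
    time = rep(c(0, 1), n), age = 10, sex = factor("F"), diabetes = 0)
  fit <- fit_random_slope(mf, mixed_model_spec(
    fixed_terms = "time", random_terms = "intercept"))
  fe <- setNames(fit$fixed_effects$estimate, fit$fixed_effects$term)
  expect_equal(fe[["time"]], mean(dv), tolerance = 1e-8)
})

test_that("BLUP slopes are shrunk relative to per-subject OLS slopes", {
  ch <- generate_cohort(small_design(seed = 51, n_w = 10, n_c = 10,
                                     probs_w = c(0, 0, 1, 1, 1),
                                     probs_c = c(0, 0, 1)))
  vols <- correct_for_etiv(simulate_roi_volumes(ch, regions = "thalamus",
                                                seed = 52))
  mf <- roi_model_frame(vols, ch, region = "thalamus")
  fit <- fit_random_slope(mf, mixed_model_spec(
    fixed_terms = c("group", "time", "group:time")))
  ps <- fit$per_subject_slopes
  for (g in c("wolfram", "control")) {
    ids <- ps$participant_id[ps$group == g]
    ols <- vapply(ids, function(id) {
      d_i <- mf[mf$id == id, ]
      coef(lm(y ~ time, data = d_i))[2]
    }, numeric(1))
    expect_lte(var(ps$slope[ps$group == g]), var(ols))
  }
})

test_that("backward selection respects tiers, hierarchy and the alpha boundary", {
  ch <- generate_cohort(cohort_design(seed = 61))
  vols <- correct_for_etiv(simulate_roi_volumes(ch, regions = "thalamus",
                                                seed = 62))
  mf <- roi_model_frame(vols, ch, region = "thalamus")
  sel <- backward_select(mf, mixed_model_spec(outcome = "thalamus"))
  ## strong group-by-time effect in the generator: retained
  expect_true("group:time" %in% sel$spec$fixed_terms)
  ## no three-way effect in the generator: dropped, and dropped before
  ## any of its constituent two-way terms
  expect_false("group:time:age" %in% sel$spec$fixed_terms)
  if (nrow(sel$trace) > 1) {
    pos3 <- match("group:time:age", sel$trace$term)
    sub2 <- match(c("group:time", "group:age", "time:age"), sel$trace$term)
    expect_true(all(is.na(sub2) | sub2 > pos3))
  }
  ## final model never violates hierarchy
  expect_silent(longimorph:::check_hierarchy(sel$spec$fixed_terms))

  ## alpha = 1: nothing is ever removed
  sel1 <- backward_select(mf, mixed_model_spec(alpha = 1))
  expect_equal(nrow(sel1$trace), 0)
  expect_setequal(sel1$spec$fixed_terms, mixed_model_spec()$fixed_terms)
})

test_that("percent change arithmetic and slope-vs-zero tests are correct", {
  fit <- fake_fit("p1", "wolfram", -50)
  mf <- data.frame(y = c(5100, 4900), id = factor("p1"),
                   group = "wolfram")
  cs <- annual_percent_change(fit, mf)
  expect_equal(cs$mean_pct, -1.0)
  expect_equal(cs$t, 0)  # single subject, sd undefined -> 0 by convention

  ## all-zero slopes
  fit0 <- fake_fit(c("a", "b"), "control", c(0, 0))
  mf0 <- data.frame(y = rep(1000, 4), id = factor(rep(c("a", "b"), 2)),
                    group = "control")
  cs0 <- annual_percent_change(fit0, mf0)
  expect_equal(cs0$mean_pct, 0)
  expect_equal(cs0$t, 0)

  ## t-distribution oracle: consistently negative slopes
  set.seed(5)
  sl <- rnorm(12, -50, 5)
  ids <- sprintf("s%02d", 1:12)
  fitn <- fake_fit(ids, "wolfram", sl)
  mfn <- data.frame(y = rep(5000, 12), id = factor(ids),
                    group = "wolfram")
  csn <- annual_percent_change(fitn, mfn, one_tailed = TRUE)
  t_ref <- mean(sl) / (sd(sl) / sqrt(12))
  expect_equal(csn$t, t_ref)
  expect_equal(csn$p, pt(abs(t_ref), 11, lower.tail = FALSE))
  expect_lt(csn$p, 0.05)
  cs2 <- annual_percent_change(fitn, mfn, one_tailed = FALSE)
  expect_equal(cs2$p, 2 * csn$p)
})

test_that("severity correlation applies the Bonferroni criterion", {
  r <- wurs_slope_correlation(c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1))
  expect_equal(r$criterion, 0.01)
  expect_equal(r$rho, -1)
  expect_error(wurs_slope_correlation(1:3, 3:1),
               class = "longimorph_data_error")
  rc <- wurs_slope_correlation(rep(1, 6), c(1, 2, 3, 4, 5, 6))
  expect_true(rc$degenerate)
  expect_true(is.na(rc$rho))
})
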