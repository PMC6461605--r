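test_that("design construction builds, checks rank and forms products", {
  meta <- data.frame(participant_id = rep(c("a", "b"), each = 2),
                     group = rep(c("wolfram", "control"), each = 2),
                     time = c(-0.5, 0.5, -0.5, 0.5),
                     age = 10, sex = "M", diabetes = 0)
  des <- swe_design(meta, "group")
  expect_equal(dim(des$X), c(4, 2))
  expect_equal(qr(des$X)$rank, 2)

  des2 <- swe_design(meta, c("group", "time", "group:time"))
  expect_equal(des2$X[, "group:time"], des2$X[, "group"] * des2$X[, "time"])

  ## age is constant here: collinear with the intercept
  err <- tryCatch(swe_design(meta, c("group", "age")), error = identity)
  expect_s3_class(err, "longimorph_config_error")
  expect_match(conditionMessage(err), "age")
})

test_that("marginal fit matches an independent dense sandwich reference", {
  set.seed(42)
  n_subj <- 4
  meta <- data.frame(
    participant_id = rep(letters[1:n_subj], each = 2),
    group = rep(c("wolfram", "control"), each = 4),
    time = rep(c(-0.5, 0.5), n_subj),
    age = 10, sex = "F", diabetes = 0)
  Y <- matrix(rnorm(8 * 27, mean = 1, sd = 0.1), 8, 27)
  des <- swe_design(meta, c("group", "time"))
  for (adj in c("HC2", "none")) {
    ref <- dense_swe_reference(Y, des$X, meta$participant_id, adj)
    ct <- swe_contrast(des, c(time = 1))
    fit <- fit_marginal(Y, des, ct, adjust = adj, return_cov = TRUE)
    expect_equal(fit$beta, ref$beta, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(fit$cov_beta, ref$cov, tolerance = 1e-8)
    ## Wald from the reference pieces
    i_t <- which(des$columns == "time")
    w_ref <- (ref$beta[i_t, ])^2 / ref$cov[i_t, i_t, ]
    expect_equal(fit$wald, w_ref, tolerance = 1e-8)
    expect_equal(fit$p, pchisq(w_ref, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("with one map per subject the sandwich equals HC robust OLS", {
  skip_if_not_installed("sandwich")
  set.seed(7)
  meta <- data.frame(participant_id = letters[1:6],
                     group = rep(c("wolfram", "control"), 3),
                     time = rnorm(6), age = 1, sex = "F", diabetes = 0)
  Y <- matrix(rnorm(6 * 5), 6, 5)
  des <- swe_design(meta, c("group", "time"))
  for (v in 1:5) {
    dat <- data.frame(y = Y[, v], g = des$X[, "group"],
                      t = des$X[, "time"])
    ols <- lm(y ~ g + t, data = dat)
    for (pair in list(c("HC2", "HC2"), c("none", "HC0"))) {
      fit <- fit_marginal(Y[, v, drop = FALSE], des,
                          swe_contrast(des, c(group = 1)),
                          adjust = pair[1], return_cov = TRUE)
      vc <- sandwich::vcovHC(ols, type = pair[2])
      expect_equal(fit$cov_beta[, , 1], unname(as.matrix(vc)),
                   tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
})

test_that("sandwich covariance is symmetric positive semi-definite", {
  st <- tiny_stack(seed = 9, noise_sd = 0.08)
  sub <- stack_subset(st, "to_midpoint")
  des <- swe_design(sub$meta, c("group", "time", "group:time"))
  fit <- fit_marginal(sub, des, swe_contrast(des, c("group:time" = 1)),
                      return_cov = TRUE)
  for (v in seq(1, ncol(sub$maps), by = 37)) {
    Vb <- fit$cov_beta[, , v]
    expect_equal(Vb, t(Vb), tolerance = 1e-12)
    expect_gte(min(eigen(Vb, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-10)
  }
})

test_that("exactly null data produce no suprathreshold voxels", {
  ch <- generate_cohort(small_design(seed = 10))
  st <- simulate_tbm_stack(ch, c(8, 8, 8),
                           effect_spec = list(cluster = NULL,
                                              slope = c(wolfram = 0,
                                                        control = 0)),
                           noise_sd = 0, subject_offset_sd = 0, seed = 2)
  sub <- stack_subset(st, "to_midpoint")
  des <- swe_design(sub$meta, c("group", "time", "group:time"))
  fit <- fit_marginal(sub, des, swe_contrast(des, c("group:time" = 1)))
  expect_equal(fit$n_zero_variance, ncol(sub$maps))
  expect_true(all(fit$p == 1))
  expect_equal(nrow(form_clusters(fit, 0.001)), 0)
})

test_that("an injected group-by-time effect is detected at its cluster", {
  hits <- 0
  reps <- 10
  for (r in seq_len(reps)) {
    ch <- generate_cohort(small_design(seed = derive_seed(800, r),
                                       n_w = 10, n_c = 10,
                                       probs_w = c(0, 0, 1, 1),
                                       probs_c = c(0, 0, 1)))
    st <- simulate_tbm_stack(
      ch, c(12, 12, 12),
      effect_spec = list(cluster = cube_cluster(c(12, 12, 12), half = 1),
                         slope = c(wolfram = -0.08, control = 0.02)),
      noise_sd = 0.02, seed = derive_seed(801, r),
      variants = "to_midpoint")
    sub <- stack_subset(st, "to_midpoint")
    des <- swe_design(sub$meta, c("group", "time", "group:time"))
    fit <- fit_marginal(sub, des, swe_contrast(des, c("group:time" = 1)),
                        log_jacobian = TRUE)
    supra <- fit$voxel_index[fit$p < 0.001]
    cl_vox <- st$voxel_index[st$in_cluster]
    if (all(cl_vox %in% supra)) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("multi-df contrasts use chi-square df equal to the contrast rank", {
  st <- tiny_stack(seed = 12, noise_sd = 0.05)
  sub <- stack_subset(st, "to_midpoint")
  des <- swe_design(sub$meta, c("group", "time", "group:time"))
  C2 <- swe_contrast(des, list(c(time = 1), c("group:time" = 1)))
  fit <- fit_marginal(sub, des, C2)
  expect_equal(fit$df, 2)
  expect_equal(fit$p, pchisq(fit$wald, 2, lower.tail = FALSE),
               tolerance = 1e-12)
})
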