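#' Specify a two-arm slope-slowing trial design
#'
#' Design for a placebo-controlled trial whose outcome is the annual rate
#' of regional volume change, measured repeatedly on a fixed visit grid
#' (default every six months for three years). Each subject's slope is
#' normal around their arm mean; the treatment arm mean is
#' `(1 - reduction) * placebo_slope`; measurement error is homoscedastic
#' and there is no random intercept (arms share the baseline mean).
#'
#' @param n_per_arm Subjects per arm.
#' @param reduction Fractional slowing of the mean rate in `[0, 1]`.
#' @param placebo_slope Placebo-arm mean slope (mm^3/yr).
#' @param slope_sd Between-subject slope SD (mm^3/yr).
#' @param residual_sd Measurement error SD (mm^3).
#' @param baseline_mean Common baseline volume (mm^3).
#' @param visit_times Strictly increasing visit times (years), >= 2.
#' @param alpha Two-sided significance level.
#' @param n_trials Monte-Carlo trials for power estimation.
#' @param seed RNG seed.
#' @param params Packaged presets used for defaults (thalamus:
#'   `placebo_slope` = the patient-group annual rate, `slope_sd` =
#'   SEM * sqrt(n), `residual_sd` and `baseline_mean` from the region
#'   entry).
#' @return Object of class `trial_design`.
#' @export
trial_design <- function(n_per_arm = 34, reduction = 0.5,
                         placebo_slope = NULL, slope_sd = NULL,
                         residual_sd = NULL, baseline_mean = NULL,
                         visit_times = NULL, alpha = NULL,
                         n_trials = NULL, seed = 1L,
                         params = longimorph_params()) {
  tr <- params$trial
  rp <- params$regions[[tr$region]]
  d <- list(
    n_per_arm = n_per_arm, reduction = reduction,
    placebo_slope = placebo_slope %||% rp$mean_slope$wolfram,
    slope_sd = slope_sd %||% rp$slope_sd$wolfram,
    residual_sd = residual_sd %||% rp$residual_sd,
    baseline_mean = baseline_mean %||% rp$baseline_mean,
    visit_times = visit_times %||% tr$visit_times,
    alpha = alpha %||% tr$alpha,
    n_trials = n_trials %||% tr$n_trials,
    seed = seed)
  if (d$n_per_arm < 2) stop_config("n_per_arm must be >= 2")
  if (d$reduction < 0 || d$reduction > 1)
    stop_config("reduction must be in [0, 1]")
  if (length(d$visit_times) < 2 || any(diff(d$visit_times) <= 0))
    stop_config("visit_times must be strictly increasing with >= 2 points")
  if (d$slope_sd < 0 || d$residual_sd < 0)
    stop_config("slope_sd and residual_sd must be >= 0")
  structure(d, class = "trial_design")
}

#' Simulate one trial dataset
#'
#' @param design A [trial_design()].
#' @param seed RNG seed (default the design's).
#' @return Long data frame: `id` (factor), `arm` (0 placebo, 1 treated),
#'   `time`, `volume`, plus attribute `true_slopes`.
#' @export
simulate_trial <- function(design, seed = design$seed) {
  tv <- design$visit_times
  n <- design$n_per_arm
  arm_mean <- c(design$placebo_slope,
                (1 - design$reduction) * design$placebo_slope)
  with_seed(seed, {
    slopes <- stats::rnorm(2 * n, rep(arm_mean, each = n),
                           design$slope_sd)
    id <- rep(seq_len(2 * n), each = length(tv))
    tm <- rep(tv, 2 * n)
    vol <- design$baseline_mean + slopes[id] * tm +
      stats::rnorm(length(id), 0, design$residual_sd)
    out <- data.frame(id = factor(id),
                      arm = rep(rep(c(0, 1), each = n), each = length(tv)),
                      time = tm, volume = vol)
    attr(out, "true_slopes") <- slopes
    out
  })
}

#' Test the treatment-by-time effect in one trial
#'
#' Random-slope mixed model (no random intercept, homoscedastic error,
#' matching the generating model) with an arm-by-time fixed effect,
#' fitted through [fit_random_slope()]; the arm:time coefficient is
#' tested two-sided with a Satterthwaite Wald t.
#'
#' @param data A [simulate_trial()] dataset.
#' @param alpha Significance level.
#' @return List: `reject`, `p`, `estimate`, `converged`.
#' @export
trial_test <- function(data, alpha = 0.05) {
  mf <- data.frame(y = data$volume, id = data$id,
                   group = factor(ifelse(data$arm == 1, "wolfram",
                                         "control"),
                                  levels = c("control", "wolfram")),
                   time = data$time, age = 0, sex = factor("F"),
                   diabetes = 0)
  spec <- mixed_model_spec(fixed_terms = c("group", "time", "group:time"),
                           random_terms = "slope", alpha = alpha)
  fit <- fit_random_slope(mf, spec, term_tests = FALSE,
                          per_subject = FALSE)
  if (!isTRUE(fit$converged))
    return(list(reject = NA, p = NA_real_, estimate = NA_real_,
                converged = FALSE))
  fe <- fit$fixed_effects
  row <- fe[fe$term == "groupwolfram:time", ]
  list(reject = row$p < alpha, p = row$p, estimate = row$estimate,
       converged = TRUE)
}

#' Empirical power of a trial design
#'
#' Fraction of `n_trials` simulated trials in which the arm-by-time
#' effect is significant. Non-convergent fits are excluded from the
#' denominator (their count is reported).
#'
#' @param design A [trial_design()].
#' @return One-row data frame of class `power_row`: `n_per_arm`,
#'   `reduction`, `empirical_power`, `mc_se`
#'   (`sqrt(p (1 - p) / n_trials)`), `n_trials`, `n_nonconverged`.
#' @export
empirical_power <- function(design) {
  if (design$n_trials < 1) stop_config("n_trials must be >= 1")
  rejects <- logical(0); n_bad <- 0L
  for (tr in seq_len(design$n_trials)) {
    dat <- simulate_trial(design, seed = derive_seed(design$seed, tr))
    res <- trial_test(dat, design$alpha)
    if (!isTRUE(res$converged)) n_bad <- n_bad + 1L
    else rejects <- c(rejects, res$reject)
  }
  if (!length(rejects)) stop_data("all trials failed to converge")
  p_hat <- mean(rejects)
  out <- data.frame(n_per_arm = design$n_per_arm,
                    reduction = design$reduction,
                    empirical_power = p_hat,
                    mc_se = sqrt(p_hat * (1 - p_hat) / length(rejects)),
                    n_trials = length(rejects),
                    n_nonconverged = n_bad)
  class(out) <- c("power_row", class(out))
  out
}

#' Closed-form power oracle for the slope-slowing trial
#'
#' Independent analytic check on the Monte-Carlo power. The per-subject
#' OLS slope over the visit grid has variance
#' `v = residual_sd^2 / Sxx + slope_sd^2` with `Sxx = sum((t - tbar)^2)`
#' (7.0 for the default six-monthly three-year grid); the two-sample
#' z-test power at level alpha is
#' `Phi(|d| / sqrt(2 v / n) - z_{1 - alpha/2})` plus the opposite tail,
#' where `d = reduction * placebo_slope`.
#'
#' @param design A [trial_design()].
#' @return Power in `[0, 1]`.
#' @export
analytic_power <- function(design) {
  tv <- design$visit_times
  sxx <- sum((tv - mean(tv))^2)
  v <- design$residual_sd^2 / sxx + design$slope_sd^2
  delta <- abs(design$reduction * design$placebo_slope)
  se <- sqrt(2 * v / design$n_per_arm)
  z <- stats::qnorm(1 - design$alpha / 2)
  if (se == 0) return(if (delta > 0) 1 else design$alpha)
  stats::pnorm(delta / se - z) + stats::pnorm(-delta / se - z)
}

#' Smallest arm size reaching a target power
#'
#' Brackets the answer with the analytic oracle, then bisects on the
#' integer grid using seeded empirical power, assuming monotonicity in n.
#'
#' @param target_power Target in (0, 1).
#' @param reduction Fractional slowing.
#' @param design Template [trial_design()] (its `n_per_arm` is ignored).
#' @param n_cap Largest arm size considered.
#' @param n_min Smallest arm size considered.
#' @return List: `n_per_arm`, `analytic_n`, `evaluations` (power rows at
#'   the visited n).
#' @export
min_sample_size <- function(target_power, reduction, design = trial_design(),
                            n_cap = 500, n_min = 2) {
  if (target_power <= 0 || target_power >= 1)
    stop_config("target_power must be in (0, 1)")
  at_n <- function(n, what = c("analytic", "empirical")) {
    d <- design; d$n_per_arm <- n; d$reduction <- reduction
    if (match.arg(what) == "analytic") analytic_power(d)
    else empirical_power(d)
  }
  n_a <- n_min
  while (n_a <= n_cap && at_n(n_a) < target_power) n_a <- n_a + 1
  if (n_a > n_cap)
    stop_config("target power unreachable within n_cap = ", n_cap)
  evals <- list()
  emp <- function(n) {
    key <- as.character(n)
    if (is.null(evals[[key]])) evals[[key]] <<- at_n(n, "empirical")
    evals[[key]]$empirical_power
  }
  ## analytic value seeds the upper bracket; double until empirically
  ## sufficient, then integer bisection (lo always below target)
  hi <- n_a
  while (emp(hi) < target_power) {
    if (hi >= n_cap)
      stop_config("target power unreachable within n_cap = ", n_cap)
    hi <- min(n_cap, hi * 2)
  }
  lo <- n_min - 1  # sentinel below target by convention
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (mid < n_min) break
    if (emp(mid) >= target_power) hi <- mid else lo <- mid
  }
  list(n_per_arm = hi, analytic_n = n_a,
       evaluations = do.call(rbind, evals))
}

#' Empirical power curve over a grid
#'
#' @param design Template design.
#' @param n_grid,reduction_grid Grids of arm sizes and reductions.
#' @return Object of class `power_curve`: data frame of power rows with
#'   an `analytic_power` column.
#' @export
power_curve <- function(design = trial_design(), n_grid = c(15, 25, 40),
                        reduction_grid = c(0.4, 0.5, 0.6)) {
  rows <- list()
  for (n in n_grid) for (r in reduction_grid) {
    d <- design; d$n_per_arm <- n; d$reduction <- r
    d$seed <- derive_seed(design$seed, n, round(1000 * r))
    row <- empirical_power(d)
    row$analytic_power <- analytic_power(d)
    rows[[length(rows) + 1]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("power_curve", class(out))
  out
}
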