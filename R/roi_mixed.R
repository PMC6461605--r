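#' Correct regional volumes for head size (eTIV)
#'
#' Default is proportional atlas-style scaling: each raw volume is
#' multiplied by `reference_etiv / etiv_subject`, i.e. scaled to a common
#' head size. The alternative `"residual"` method removes the pooled
#' linear dependence of volume on eTIV within region
#' (`volume - b * (etiv - reference)`).
#'
#' @param volumes A `roi_volumes` object or long volume data frame with
#'   columns `participant_id`, `region`, `volume`, `etiv`.
#' @param reference_etiv Reference head size in mm^3 (default: mean of
#'   the per-participant eTIVs).
#' @param method `"proportional"` (default) or `"residual"`.
#' @return Input with a `volume_corrected` column (recomputed from the
#'   raw `volume` column, so the operation is idempotent).
#' @export
correct_for_etiv <- function(volumes, reference_etiv = NULL,
                             method = c("proportional", "residual")) {
  method <- match.arg(method)
  is_obj <- inherits(volumes, "roi_volumes")
  df <- if (is_obj) volumes$volumes else volumes
  check_columns(df, c("participant_id", "volume", "etiv"), "volume table")
  if (any(df$etiv <= 0)) stop_data("etiv must be > 0 for all rows")
  if (is.null(reference_etiv)) {
    per <- df$etiv[!duplicated(df$participant_id)]
    reference_etiv <- mean(per)
  }
  if (method == "proportional") {
    df$volume_corrected <- df$volume * reference_etiv / df$etiv
  } else {
    df$volume_corrected <- df$volume
    for (r in unique(df$region)) {
      i <- df$region == r
      b <- stats::coef(stats::lm(volume ~ etiv, data = df[i, ]))[["etiv"]]
      df$volume_corrected[i] <- df$volume[i] -
        b * (df$etiv[i] - reference_etiv)
    }
  }
  if (is_obj) {
    volumes$volumes <- df
    volumes$reference_etiv <- reference_etiv
    volumes
  } else df
}

roi_term_order <- function(term) lengths(strsplit(term, ":", fixed = TRUE))

roi_all_terms <- c("group", "time", "age", "sex", "diabetes",
                   "group:time", "group:age", "time:age", "group:time:age")

#' Specify a random-slope mixed model for a regional volume
#'
#' @param outcome Region name (used to filter long tables).
#' @param fixed_terms Character vector from `group`, `time`, `age`, `sex`,
#'   `diabetes` and their `:` interactions. `age` is age at the first
#'   session, fixed within participant. Term hierarchy is enforced: an
#'   interaction requires all its constituent main effects and
#'   sub-interactions among `group`, `time`, `age`.
#' @param random_terms Subset of `c("intercept", "slope")`; the default
#'   gives each participant their own regression line (random intercept
#'   and random time slope with unstructured covariance).
#' @param alpha Significance level in (0, 1), used by [backward_select()].
#' @return An object of class `mixed_model_spec`.
#' @export
mixed_model_spec <- function(outcome = NULL,
                             fixed_terms = roi_all_terms,
                             random_terms = c("intercept", "slope"),
                             alpha = 0.05) {
  if (alpha <= 0 || alpha > 1) stop_config("alpha must be in (0, 1]")
  bad <- setdiff(fixed_terms, roi_all_terms)
  if (length(bad))
    stop_config("unknown fixed term(s): ", paste(bad, collapse = ", "))
  if (!all(random_terms %in% c("intercept", "slope")) ||
      !length(random_terms))
    stop_config("random_terms must be a nonempty subset of intercept, slope")
  check_hierarchy(fixed_terms)
  structure(list(outcome = outcome, fixed_terms = fixed_terms,
                 random_terms = random_terms, alpha = alpha),
            class = "mixed_model_spec")
}

check_hierarchy <- function(terms) {
  for (tm in terms[roi_term_order(terms) > 1]) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    need <- unlist(lapply(seq_len(length(parts) - 1), function(k)
      apply(utils::combn(parts, k), 2, paste, collapse = ":")))
    missing <- setdiff(need, terms)
    if (length(missing))
      stop_config("term hierarchy violated: ", tm, " requires ",
                  paste(missing, collapse = ", "))
  }
  invisible(terms)
}

#' Build a model frame for the ROI mixed models
#'
#' Merges a long volume table with participant-level covariates and
#' renames to the modelling vocabulary: `y` (corrected volume if present,
#' else raw), `id`, `group` (factor, control reference), `time` (years
#' from baseline), `age` (age at first session), `sex`, `diabetes`.
#'
#' @param volumes `roi_volumes` object or volume data frame.
#' @param cohort Optional [generate_cohort()] result supplying `sex` and
#'   `diabetes` when the volume table lacks them.
#' @param region Optional region filter.
#' @return A data frame ready for [fit_random_slope()].
#' @export
roi_model_frame <- function(volumes, cohort = NULL, region = NULL) {
  df <- if (inherits(volumes, "roi_volumes")) volumes$volumes else volumes
  if (!is.null(region)) {
    df <- df[df$region == region, , drop = FALSE]
    if (!nrow(df)) stop_data("no rows for region ", region)
  }
  check_columns(df, c("participant_id", "group", "time_from_baseline"),
                "volume table")
  if (!is.null(cohort)) {
    p <- cohort$participants
    i <- match(df$participant_id, p$id)
    df$sex <- p$sex[i]; df$diabetes <- p$diabetes[i]
    df$baseline_age <- p$baseline_age[i]
  }
  if (is.null(df$baseline_age)) {
    check_columns(df, "age_at_scan", "volume table")
    df$baseline_age <- df$age_at_scan - df$time_from_baseline
  }
  y <- if (!is.null(df$volume_corrected)) df$volume_corrected else df$volume
  out <- data.frame(
    y = y,
    id = factor(df$participant_id),
    group = factor(df$group, levels = c("control", "wolfram")),
    time = df$time_from_baseline,
    age = df$baseline_age,
    stringsAsFactors = FALSE)
  out$sex <- if (!is.null(df$sex)) factor(df$sex) else factor("F")
  out$diabetes <- if (!is.null(df$diabetes)) df$diabetes else 0
  out
}

#' Fit a random-slope linear mixed model for regional volume change
#'
#' REML fit (via \pkg{lme4}/\pkg{lmerTest}) of
#' `y = X beta + b0_i + b1_i * time + e`, where each participant deviates
#' from the group-mean trajectory through a random intercept and/or random
#' time slope with unstructured covariance. Fixed-effect t statistics and
#' Type-III F tests use Satterthwaite denominator degrees of freedom.
#' Per-subject annual slopes combine the participant's fixed-effect time
#' derivative (at their own covariates) with the slope BLUP.
#'
#' @param data Model frame from [roi_model_frame()] (columns `y`, `id`,
#'   `group`, `time`, `age`, `sex`, `diabetes`).
#' @param spec A [mixed_model_spec()].
#' @param term_tests Compute the Type-III F table (set FALSE for speed in
#'   simulation loops).
#' @param per_subject Compute per-subject slopes.
#' @return An object of class `mixed_fit`: list with `fixed_effects`
#'   (estimate, se, df, t, p per coefficient), `varcomp` (intercept_var,
#'   slope_var, cov, residual_var), `term_tests` (F, df, p per term),
#'   `per_subject_slopes`, `loglik`, `converged`, `singular`, `messages`,
#'   and the underlying `fit`.
#' @export
fit_random_slope <- function(data, spec = mixed_model_spec(),
                             term_tests = TRUE, per_subject = TRUE) {
  check_columns(data, c("y", "id", "group", "time"), "model frame")
  re <- if (setequal(spec$random_terms, c("intercept", "slope")))
    "(1 + time | id)"
  else if (identical(spec$random_terms, "slope")) "(0 + time | id)"
  else "(1 | id)"
  fml <- stats::as.formula(paste(
    "y ~", paste(c(spec$fixed_terms, re), collapse = " + ")))
  ctl <- lme4::lmerControl(check.nobs.vs.nRE = "ignore",
                           check.nobs.vs.nlev = "ignore",
                           calc.derivs = FALSE)
  msgs <- character(0)
  fit <- withCallingHandlers(
    tryCatch(lmerTest::lmer(fml, data = data, REML = TRUE, control = ctl),
             error = function(e) e),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  if (inherits(fit, "error"))
    return(structure(list(converged = FALSE, singular = NA,
                          messages = conditionMessage(fit), spec = spec),
                     class = "mixed_fit"))
  converged <- !any(grepl("failed to converge", msgs))
  singular <- lme4::isSingular(fit)

  cs <- withCallingHandlers(
    suppressMessages(stats::coef(summary(fit))),
    warning = function(w) invokeRestart("muffleWarning"))
  fixed_effects <- data.frame(
    term = rownames(cs), estimate = cs[, "Estimate"],
    se = cs[, "Std. Error"], df = cs[, "df"], t = cs[, "t value"],
    p = cs[, "Pr(>|t|)"], row.names = NULL, stringsAsFactors = FALSE)

  vc <- lme4::VarCorr(fit)
  vm <- vc$id
  varcomp <- list(intercept_var = 0, slope_var = 0, cov = 0,
                  residual_var = attr(vc, "sc")^2)
  if (!is.null(vm)) {
    if ("(Intercept)" %in% rownames(vm))
      varcomp$intercept_var <- vm["(Intercept)", "(Intercept)"]
    if ("time" %in% rownames(vm))
      varcomp$slope_var <- vm["time", "time"]
    if (all(c("(Intercept)", "time") %in% rownames(vm)))
      varcomp$cov <- vm["(Intercept)", "time"]
  }

  tt <- NULL
  if (term_tests && length(spec$fixed_terms)) {
    at <- suppressMessages(stats::anova(fit, type = 3))
    tt <- data.frame(term = rownames(at), F = at[, "F value"],
                     df1 = at[, "NumDF"], df2 = at[, "DenDF"],
                     p = at[, "Pr(>F)"], row.names = NULL,
                     stringsAsFactors = FALSE)
  }

  pss <- NULL
  if (per_subject) {
    pd <- data[!duplicated(data$id), , drop = FALSE]
    nd0 <- pd; nd0$time <- 0
    nd1 <- pd; nd1$time <- 1
    fx <- stats::predict(fit, newdata = nd1, re.form = NA) -
      stats::predict(fit, newdata = nd0, re.form = NA)
    blup <- rep(0, nrow(pd))
    if ("slope" %in% spec$random_terms) {
      re_b <- lme4::ranef(fit)$id
      if ("time" %in% colnames(re_b))
        blup <- re_b[match(as.character(pd$id), rownames(re_b)), "time"]
    }
    pss <- data.frame(participant_id = as.character(pd$id),
                      group = as.character(pd$group),
                      fixed_slope = unname(fx), blup = blup,
                      slope = unname(fx) + blup,
                      stringsAsFactors = FALSE)
  }

  structure(list(fit = fit, fixed_effects = fixed_effects,
                 varcomp = varcomp, term_tests = tt,
                 per_subject_slopes = pss,
                 loglik = as.numeric(stats::logLik(fit)),
                 converged = converged, singular = singular,
                 messages = msgs, spec = spec),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("Random-slope mixed model",
      if (!is.null(x$spec$outcome)) paste0("(", x$spec$outcome, ")"), "\n")
  if (!isTRUE(x$converged)) cat("  ** did not converge **\n")
  print(x$fixed_effects, digits = 4)
  cat(sprintf("  var(intercept) %.3g  var(slope) %.3g  cov %.3g  var(resid) %.3g\n",
              x$varcomp$intercept_var, x$varcomp$slope_var,
              x$varcomp$cov, x$varcomp$residual_var))
  invisible(x)
}

#' Backward selection over mixed-model fixed effects
#'
#' Starting from the full model, repeatedly removes the most
#' non-significant eligible term with `p > alpha`, working down the order
#' tiers: first the three-way interaction, then two-way interactions,
#' then main effects. A term is ineligible while a retained higher-order
#' interaction contains it. Eligibility p values come from the Type-III
#' Satterthwaite F table.
#'
#' @param data Model frame (see [roi_model_frame()]).
#' @param full_spec The full [mixed_model_spec()].
#' @param term_tests_final Compute the term-test table for the final fit.
#' @return List with `spec` (selected model), `fit` (final `mixed_fit`),
#'   and `trace` (data frame of removals: step, term, p).
#' @export
backward_select <- function(data, full_spec = mixed_model_spec(),
                            term_tests_final = TRUE) {
  spec <- full_spec
  trace <- data.frame(step = integer(0), term = character(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  step <- 0L
  protected <- function(tm, terms) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    higher <- terms[roi_term_order(terms) > length(parts)]
    any(vapply(strsplit(higher, ":", fixed = TRUE),
               function(h) all(parts %in% h), logical(1)))
  }
  fit <- fit_random_slope(data, spec, term_tests = TRUE,
                          per_subject = FALSE)
  for (tier in sort(unique(roi_term_order(full_spec$fixed_terms)),
                    decreasing = TRUE)) {
    repeat {
      terms <- spec$fixed_terms
      elig <- terms[roi_term_order(terms) == tier &
                      !vapply(terms, protected, logical(1), terms = terms)]
      if (!length(elig) || !isTRUE(fit$converged)) break
      tt <- fit$term_tests
      pe <- tt$p[match(elig, tt$term)]
      if (all(is.na(pe))) break
      worst <- which.max(pe)
      if (is.na(pe[worst]) || pe[worst] <= spec$alpha) break
      step <- step + 1L
      trace <- rbind(trace, data.frame(step = step, term = elig[worst],
                                       p = pe[worst]))
      spec$fixed_terms <- setdiff(terms, elig[worst])
      fit <- fit_random_slope(data, spec, term_tests = TRUE,
                              per_subject = FALSE)
    }
  }
  final <- fit_random_slope(data, spec, term_tests = term_tests_final,
                            per_subject = TRUE)
  list(spec = spec, fit = final, trace = trace)
}

#' Annual percent change and slope-vs-zero tests
#'
#' Scales each participant's fitted annual slope by the mean of their own
#' (corrected) visit volumes to obtain annual percent change, then
#' summarises per group: mean rate and percent change with SEMs, and a
#' one-sample t test of the per-subject slopes against zero (one-tailed in
#' the direction of the observed group mean by default, two-tailed
#' optionally).
#'
#' @param fit A `mixed_fit` with per-subject slopes.
#' @param data The model frame the fit used (columns `y`, `id`, `group`).
#' @param region Label carried into the output.
#' @param one_tailed Tail convention for the slope-vs-zero test.
#' @return Object of class `change_summary`: data frame with one row per
#'   group (n, mean_rate, sem_rate, mean_pct, sem_pct, t, df, p, tail),
#'   plus attribute `per_subject` (participant-level percent changes).
#' @export
annual_percent_change <- function(fit, data, region = fit$spec$outcome,
                                  one_tailed = TRUE) {
  if (is.null(fit$per_subject_slopes))
    stop_data("fit has no per-subject slopes")
  ps <- fit$per_subject_slopes
  mv <- tapply(data$y, as.character(data$id), mean)
  mv_i <- mv[ps$participant_id]
  if (any(!is.finite(mv_i)) || any(mv_i == 0))
    stop_data("zero or missing mean volume for some participant")
  ps$mean_volume <- unname(mv_i)
  ps$pct_change <- 100 * ps$slope / ps$mean_volume
  rows <- lapply(split(ps, ps$group), function(g) {
    n <- nrow(g)
    t_stat <- if (n > 1 && stats::sd(g$slope) > 0)
      mean(g$slope) / (stats::sd(g$slope) / sqrt(n)) else 0
    p <- if (n < 2) NA_real_
    else if (one_tailed) stats::pt(abs(t_stat), n - 1, lower.tail = FALSE)
    else 2 * stats::pt(abs(t_stat), n - 1, lower.tail = FALSE)
    data.frame(region = region %||% NA_character_,
               group = g$group[1], n = n,
               mean_rate = mean(g$slope),
               sem_rate = stats::sd(g$slope) / sqrt(n),
               mean_pct = mean(g$pct_change),
               sem_pct = stats::sd(g$pct_change) / sqrt(n),
               t = t_stat, df = n - 1, p = p,
               tail = if (one_tailed) "one" else "two",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_subject") <- ps
  class(out) <- c("change_summary", class(out))
  out
}

#' Spearman correlation of decline with symptom severity, Bonferroni
#'
#' Spearman rank correlation (average ranks under ties) between
#' per-participant annual change values and severity scores, with a
#' Bonferroni-corrected significance criterion `alpha / n_tests`.
#'
#' @param slopes Numeric vector (e.g. percent annual change).
#' @param wurs Severity scores, same length/order.
#' @param n_tests Number of correlations in the family.
#' @param alpha Family significance level.
#' @return List: `rho`, `p`, `n`, `criterion`, `significant`, and
#'   `degenerate` (TRUE when an input is constant and rho undefined).
#' @export
wurs_slope_correlation <- function(slopes, wurs, n_tests = 5,
                                   alpha = 0.05) {
  ok <- stats::complete.cases(slopes, wurs)
  x <- slopes[ok]; y <- wurs[ok]
  n <- length(x)
  if (n < 4) stop_data("need at least 4 paired observations")
  criterion <- alpha / n_tests
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n,
                criterion = criterion, significant = NA,
                degenerate = TRUE))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n,
       criterion = criterion,
       significant = ct$p.value < criterion, degenerate = FALSE)
}
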