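#' Specify a synthetic cohort design
#'
#' Captures the structure of an unbalanced two-group longitudinal imaging
#' cohort: a patient ("wolfram") group followed for up to 7 annual visits
#' and a pooled control group (diabetic and non-diabetic) followed for up
#' to 3. Defaults reproduce the packaged study presets: 29 patients and 52
#' controls, all patients diabetic, baseline ages ~5-26, and visit-count
#' distributions calibrated so the expected follow-up among multi-visit
#' participants is 3.6 and ~2.0 years.
#'
#' @param n_wolfram,n_control Group sizes (>= 1).
#' @param diabetic_control_fraction Proportion of controls with type 1
#'   diabetes. All wolfram-group participants are diabetic.
#' @param baseline_age_range Named list with `wolfram` and `control`
#'   two-vectors `(low, high)` in years.
#' @param sex_balance Named list of proportions male per group.
#' @param visit_count_probs Named list of probability vectors over
#'   1..7 (wolfram) and 1..3 (control) visits; normalised internally.
#' @param interval_mean,interval_jitter_sd Inter-visit interval mean and
#'   jitter SD in years (`interval_mean > 0`).
#' @param seed Default RNG seed used by [generate_cohort()].
#' @param params Parameter list from [longimorph_params()] supplying
#'   defaults.
#' @return An object of class `cohort_design`.
#' @seealso [generate_cohort()]
#' @export
cohort_design <- function(n_wolfram = NULL, n_control = NULL,
                          diabetic_control_fraction = NULL,
                          baseline_age_range = NULL,
                          sex_balance = NULL,
                          visit_count_probs = NULL,
                          interval_mean = NULL,
                          interval_jitter_sd = NULL,
                          seed = 1L,
                          params = longimorph_params()) {
  cf <- params$cohort
  d <- list(
    n_wolfram = n_wolfram %||% cf$n_wolfram,
    n_control = n_control %||% cf$n_control,
    diabetic_control_fraction =
      diabetic_control_fraction %||% cf$diabetic_control_fraction,
    baseline_age_range = baseline_age_range %||% cf$baseline_age_range,
    sex_balance = sex_balance %||% cf$sex_balance,
    visit_count_probs = visit_count_probs %||% cf$visit_count_probs,
    interval_mean = interval_mean %||% cf$inter_visit_interval$mean,
    interval_jitter_sd =
      interval_jitter_sd %||% cf$inter_visit_interval$jitter_sd,
    seed = seed)
  validate_cohort_design(d)
  structure(d, class = "cohort_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_cohort_design <- function(d) {
  if (d$n_wolfram < 1 || d$n_control < 1)
    stop_config("group sizes must be >= 1")
  if (d$interval_mean <= 0)
    stop_config("inter-visit interval mean must be > 0")
  if (d$diabetic_control_fraction < 0 || d$diabetic_control_fraction > 1)
    stop_config("diabetic_control_fraction must be in [0, 1]")
  for (g in c("wolfram", "control")) {
    pv <- d$visit_count_probs[[g]]
    if (is.null(pv) || any(pv < 0) || sum(pv) <= 0)
      stop_config("visit_count_probs$", g,
                  " must be a nonnegative vector with positive sum")
    r <- d$baseline_age_range[[g]]
    if (length(r) != 2 || r[1] >= r[2])
      stop_config("baseline_age_range$", g, " must be (low, high)")
  }
  kmax <- c(wolfram = 7L, control = 3L)
  for (g in c("wolfram", "control"))
    if (length(d$visit_count_probs[[g]]) > kmax[[g]])
      stop_config("visit_count_probs$", g, " supports at most ",
                  kmax[[g]], " visits")
  invisible(d)
}

#' Expected follow-up implied by a visit-count distribution
#'
#' Direct expectation of `(visits - 1) * interval_mean` among participants
#' with at least two visits, i.e. the population value of the cohort-table
#' "mean follow-up" statistic (single-visit participants excluded, as in
#' the usual demographics-table convention).
#'
#' @param probs Nonnegative weight vector over 1..K visits.
#' @param interval_mean Mean inter-visit interval (years).
#' @return Expected follow-up in years.
#' @export
expected_followup <- function(probs, interval_mean = 1) {
  probs <- probs / sum(probs)
  k <- seq_along(probs)
  multi <- k >= 2
  if (!any(probs[multi] > 0)) return(0)
  sum(probs[multi] * (k[multi] - 1)) / sum(probs[multi]) * interval_mean
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws participants (group, diabetes, sex, baseline age, eTIV) and their
#' visit schedules. Sex and diabetes are assigned in exact design
#' proportions (randomly allocated); visit counts are drawn from the
#' design's per-group distributions; inter-visit intervals are
#' `Normal(interval_mean, jitter_sd)` truncated below at one tenth of the
#' mean. Each participant uses a deterministic RNG substream derived from
#' the seed, so the cohort is bitwise reproducible.
#'
#' Visit time covariates follow the longitudinal-registration convention:
#' `time_from_baseline` is years since the first scan and
#' `time_to_midpoint` is signed years from the participant's mid-point
#' (mean) scan age, so it sums to zero within participant.
#'
#' @param design A [cohort_design()].
#' @param seed RNG seed; defaults to the design's.
#' @param params Parameter presets (for the eTIV distribution).
#' @return An object of class `cohort`: a list with data frames
#'   `participants` (id, group, diabetes, sex, baseline_age, etiv) and
#'   `visits` (participant_id, session, age_at_scan, time_from_baseline,
#'   time_to_midpoint).
#' @export
#' @examples
#' ch <- generate_cohort(cohort_design(seed = 42))
#' table(ch$participants$group)
generate_cohort <- function(design, seed = design$seed,
                            params = longimorph_params()) {
  validate_cohort_design(design)
  nW <- design$n_wolfram; nC <- design$n_control
  ids <- c(sprintf("W%02d", seq_len(nW)), sprintf("C%02d", seq_len(nC)))
  group <- rep(c("wolfram", "control"), c(nW, nC))

  ## exact-count attribute allocation, shuffled under substreams
  alloc <- function(n, frac, sub) with_seed(sub, {
    k <- round(frac * n)
    sample(rep(c(1L, 0L), c(k, n - k)))
  })
  sexW <- alloc(nW, design$sex_balance$wolfram, derive_seed(seed, 1))
  sexC <- alloc(nC, design$sex_balance$control, derive_seed(seed, 2))
  diaC <- alloc(nC, design$diabetic_control_fraction, derive_seed(seed, 3))
  sex <- ifelse(c(sexW, sexC) == 1L, "M", "F")
  diabetes <- c(rep(1L, nW), diaC)

  et <- params$etiv
  n_all <- nW + nC
  baseline_age <- numeric(n_all)
  etiv <- numeric(n_all)
  visits <- vector("list", n_all)
  for (i in seq_len(n_all)) {
    g <- group[i]
    pv <- design$visit_count_probs[[g]]
    pv <- pv / sum(pv)
    rng <- design$baseline_age_range[[g]]
    vi <- with_seed(derive_seed(seed, 10, i), {
      ba <- stats::runif(1, rng[1], rng[2])
      ev <- stats::rlnorm(1, et$meanlog, et$sdlog)
      k <- sample.int(length(pv), 1, prob = pv)
      gaps <- if (k > 1)
        pmax(stats::rnorm(k - 1, design$interval_mean,
                          design$interval_jitter_sd),
             design$interval_mean / 10)
      else numeric(0)
      list(ba = ba, ev = ev, t = c(0, cumsum(gaps)))
    })
    baseline_age[i] <- vi$ba
    etiv[i] <- vi$ev
    tt <- vi$t
    visits[[i]] <- data.frame(
      participant_id = ids[i],
      session = seq_along(tt),
      age_at_scan = vi$ba + tt,
      time_from_baseline = tt,
      time_to_midpoint = tt - mean(tt),
      stringsAsFactors = FALSE)
  }

  participants <- data.frame(
    id = ids, group = group, diabetes = diabetes, sex = sex,
    baseline_age = baseline_age, etiv = etiv, stringsAsFactors = FALSE)
  structure(list(participants = participants,
                 visits = do.call(rbind, visits),
                 design = design, seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  p <- x$participants
  nv <- table(table(x$visits$participant_id))
  cat("Synthetic longitudinal cohort\n")
  cat(sprintf("  %d wolfram, %d control participants\n",
              sum(p$group == "wolfram"), sum(p$group == "control")))
  cat("  visits per participant:",
      paste(sprintf("%sx%s", names(nv), nv), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate regional volume trajectories for a cohort
#'
#' Draws per-participant latent intercepts and annual slopes from
#' group-specific normal distributions and builds visit-level volumes
#' `intercept_i + slope_i * time_from_baseline + Normal(0, residual_sd^2)`.
#' Head-size coupling multiplies the whole trajectory by
#' `1 + etiv_coupling * (etiv_i / reference - 1)`, so proportional eTIV
#' correction removes it exactly at coupling 1.
#'
#' @param cohort A [generate_cohort()] result.
#' @param params Parameter presets; `params$regions` must contain an entry
#'   for every requested region.
#' @param regions Regions to simulate (default all presets).
#' @param seed RNG seed (default: derived from the cohort's).
#' @return An object of class `roi_volumes`: list with `volumes` (long
#'   data frame: participant_id, group, session, age_at_scan,
#'   time_from_baseline, region, volume, etiv) and `latents`
#'   (participant_id, region, true_intercept, true_slope).
#' @export
simulate_roi_volumes <- function(cohort, params = longimorph_params(),
                                 regions = names(params$regions),
                                 seed = derive_seed(cohort$seed, 77)) {
  missing <- setdiff(regions, names(params$regions))
  if (length(missing))
    stop_config("no parameters for region(s): ",
                paste(missing, collapse = ", "))
  p <- cohort$participants
  v <- cohort$visits
  ref_etiv <- params$etiv$reference %||% mean(p$etiv)
  vol_list <- list(); lat_list <- list()
  for (r in seq_along(regions)) {
    region <- regions[r]
    rp <- params$regions[[region]]
    lat <- with_seed(derive_seed(seed, r), {
      mu_b <- rp$baseline_mean
      ms <- unlist(rp$mean_slope)[p$group]
      ss <- unlist(rp$slope_sd)[p$group]
      data.frame(
        participant_id = p$id, region = region,
        true_intercept = stats::rnorm(nrow(p), mu_b, rp$baseline_sd),
        true_slope = stats::rnorm(nrow(p), ms, ss),
        stringsAsFactors = FALSE)
    })
    idx <- match(v$participant_id, p$id)
    scale <- 1 + rp$etiv_coupling * (p$etiv[idx] / ref_etiv - 1)
    eps <- with_seed(derive_seed(seed, r, 999),
                     stats::rnorm(nrow(v), 0, rp$residual_sd))
    vol <- (lat$true_intercept[idx] +
              lat$true_slope[idx] * v$time_from_baseline + eps) * scale
    vol_list[[r]] <- data.frame(
      participant_id = v$participant_id,
      group = p$group[idx],
      session = v$session,
      age_at_scan = v$age_at_scan,
      time_from_baseline = v$time_from_baseline,
      region = region, volume = vol, etiv = p$etiv[idx],
      stringsAsFactors = FALSE)
    lat_list[[r]] <- lat
  }
  structure(list(volumes = do.call(rbind, vol_list),
                 latents = do.call(rbind, lat_list),
                 reference_etiv = ref_etiv, seed = seed),
            class = "roi_volumes")
}

#' Map a bivariate-normal population Spearman to its latent Pearson
#'
#' For jointly normal variables the population Spearman correlation is
#' `(6 / pi) * asin(rho / 2)` (Greiner's relation); this inverts it:
#' `rho = 2 * sin(pi * rho_s / 6)`.
#'
#' @param rho_s Target population Spearman in `[-1, 1]`.
#' @return The latent Pearson correlation.
#' @export
spearman_to_pearson <- function(rho_s) {
  if (any(abs(rho_s) > 1)) stop_config("rho_s must be in [-1, 1]")
  2 * sin(pi * rho_s / 6)
}

#' Latent Pearson coupling for a target Spearman correlation
#'
#' With `n = Inf` this is [spearman_to_pearson()]: the latent Pearson
#' whose population Spearman equals `target`. With finite `n` it instead
#' inverts the expectation of the *sample* Spearman coefficient of a
#' bivariate-normal sample of size n,
#' `E r_s = 6 / (pi (n + 1)) * (asin(rho) + (n - 2) asin(rho / 2))`,
#' so a study's observed rank correlation at its actual sample size is
#' reproduced in expectation rather than only asymptotically.
#'
#' @param target Target Spearman correlation in `[-1, 1]`.
#' @param n Sample size the target was observed at, or `Inf`.
#' @return Latent Pearson correlation.
#' @export
wurs_latent_coupling <- function(target, n = Inf) {
  if (abs(target) > 1) stop_config("target must be in [-1, 1]")
  if (!is.finite(n)) return(spearman_to_pearson(target))
  if (n < 4) stop_config("n must be >= 4")
  if (abs(target) == 1) return(sign(target))
  e_rs <- function(rho) 6 / (pi * (n + 1)) *
    (asin(rho) + (n - 2) * asin(rho / 2))
  stats::uniroot(function(r) e_rs(r) - target, c(-1, 1),
                 tol = 1e-12)$root
}

#' Simulate symptom-severity (WURS Physical) scores coupled to decline
#'
#' Builds a latent Gaussian correlated with the supplied per-participant
#' thalamic slopes at Pearson level `rho` and maps it through a monotone
#' log-normal transform to a nonnegative score, so the score/slope Spearman
#' correlation is exactly that of the latent pair. Negative coupling means
#' higher (worse) scores go with faster volume loss.
#'
#' The coupling is either `latent_pearson` directly, or derived from
#' `target_rank_corr` via [wurs_latent_coupling()] at `calibration_n`
#' (`Inf` gives the population-Spearman map). The default is the packaged
#' calibration reproducing the study's observed sample correlation.
#'
#' @param cohort A [generate_cohort()] result; only wolfram-group
#'   participants are scored.
#' @param thalamus_slopes Named numeric vector of per-participant annual
#'   change values (names = participant ids), e.g. latent slopes from
#'   [simulate_roi_volumes()] or fitted per-subject slopes.
#' @param target_rank_corr Target Spearman correlation in `[-1, 1]`.
#' @param calibration_n Sample size at which `target_rank_corr` should be
#'   reproduced in expectation (`Inf` = population value).
#' @param latent_pearson Optional explicit latent Pearson coupling,
#'   overriding `target_rank_corr`.
#' @param slope_mean,slope_sd Population mean and SD used to standardise
#'   the slopes (defaults: the packaged wolfram thalamus preset).
#' @param seed RNG seed.
#' @param params Parameter presets.
#' @return Data frame (participant_id, wurs_physical); zero rows if the
#'   cohort has no wolfram participants.
#' @export
simulate_wurs <- function(cohort, thalamus_slopes,
                          target_rank_corr = NULL,
                          calibration_n = NULL,
                          latent_pearson = NULL,
                          slope_mean = NULL, slope_sd = NULL,
                          seed = derive_seed(cohort$seed, 88),
                          params = longimorph_params()) {
  w <- params$wurs
  rp <- params$regions$thalamus
  if (is.null(latent_pearson)) {
    target <- target_rank_corr %||% w$target_sample_spearman
    if (abs(target) > 1) stop_config("target_rank_corr must be in [-1, 1]")
    ncal <- calibration_n %||%
      (if (is.null(target_rank_corr)) w$reference_n else Inf)
    latent_pearson <- wurs_latent_coupling(target, ncal)
  }
  slope_mean <- slope_mean %||% rp$mean_slope$wolfram
  slope_sd <- slope_sd %||% rp$slope_sd$wolfram
  wol <- cohort$participants$id[cohort$participants$group == "wolfram"]
  if (!length(wol))
    return(data.frame(participant_id = character(0),
                      wurs_physical = numeric(0)))
  s <- thalamus_slopes[wol]
  if (anyNA(s)) stop_data("thalamus_slopes missing for some participants")
  z_s <- (s - slope_mean) / slope_sd
  rho <- latent_pearson
  z <- with_seed(seed,
                 rho * z_s + sqrt(max(0, 1 - rho^2)) *
                   stats::rnorm(length(z_s)))
  data.frame(participant_id = wol,
             wurs_physical = exp(w$score_meanlog + w$score_sdlog * z),
             stringsAsFactors = FALSE)
}
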