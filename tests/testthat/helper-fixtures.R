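## Shared fixture builders. Everything is generated in code; nothing is
## read from disk.

## small two-group design for fast simulation loops
small_design <- function(seed = 1, n_w = 8, n_c = 8,
                         probs_w = c(0, 1, 1, 1), probs_c = c(0, 1, 1)) {
  cohort_design(n_wolfram = n_w, n_control = n_c,
                visit_count_probs = list(wolfram = probs_w,
                                         control = probs_c),
                seed = seed)
}

## parameter presets with all between/within-subject noise switched off
noise_free_params <- function() {
  p <- longimorph_params()
  for (r in names(p$regions)) {
    p$regions[[r]]$baseline_sd <- 0
    p$regions[[r]]$residual_sd <- 0
    p$regions[[r]]$slope_sd <- list(wolfram = 0, control = 0)
    p$regions[[r]]$etiv_coupling <- 0
  }
  p
}

## tiny null TBM stack for engine tests
tiny_stack <- function(seed = 1, grid = c(8L, 8L, 8L), noise_sd = 0.05,
                       design = small_design(seed), slope = c(wolfram = 0,
                                                              control = 0)) {
  ch <- generate_cohort(design)
  simulate_tbm_stack(ch, grid,
                     effect_spec = list(cluster = cube_cluster(grid, half = 1),
                                        slope = slope),
                     noise_sd = noise_sd, seed = derive_seed(seed, 3))
}

## independent dense sandwich reference: plain loops, no shared code with
## the package implementation
dense_swe_reference <- function(Y, X, subject, adjust = c("HC2", "none")) {
  adjust <- match.arg(adjust)
  n <- nrow(X); p <- ncol(X); V <- ncol(Y)
  XtXinv <- solve(t(X) %*% X)
  beta <- matrix(NA_real_, p, V)
  covb <- array(0, dim = c(p, p, V))
  for (v in seq_len(V)) beta[, v] <- XtXinv %*% t(X) %*% Y[, v]
  resid <- Y - X %*% beta
  for (s in unique(subject)) {
    rows <- which(subject == s)
    Xi <- X[rows, , drop = FALSE]
    Mi <- diag(length(rows))
    if (adjust == "HC2") {
      Hi <- Xi %*% XtXinv %*% t(Xi)
      es <- eigen(diag(length(rows)) - Hi, symmetric = TRUE)
      Mi <- es$vectors %*% diag(1 / sqrt(es$values),
                                length(rows)) %*% t(es$vectors)
    }
    for (v in seq_len(V)) {
      ei <- Mi %*% resid[rows, v]
      si <- XtXinv %*% t(Xi) %*% ei
      covb[, , v] <- covb[, , v] + si %*% t(si)
    }
  }
  list(beta = beta, cov = covb)
}

## manually built mixed_fit carrying known per-subject slopes, for testing
## the percent-change arithmetic in isolation
fake_fit <- function(ids, groups, slopes) {
  structure(list(per_subject_slopes = data.frame(
    participant_id = ids, group = groups, fixed_slope = slopes,
    blup = 0, slope = slopes, stringsAsFactors = FALSE),
    spec = list(outcome = "thalamus"), converged = TRUE),
    class = "mixed_fit")
}
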