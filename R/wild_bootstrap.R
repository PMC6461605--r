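## Orthonormal basis of the null space of a contrast matrix C (q x p):
## columns N with C N = 0, used to build the restricted (null) design.
contrast_null_basis <- function(C) {
  p <- ncol(C)
  sv <- svd(t(C), nu = p)
  r <- sum(sv$d > max(dim(C)) * max(sv$d, 0) * .Machine$double.eps)
  sv$u[, seq(r + 1, p), drop = FALSE]
}

#' Wild-bootstrap cluster-extent FWE correction
#'
#' Non-parametric family-wise-error-corrected cluster inference for the
#' voxel-wise marginal model. The observed statistic map is thresholded
#' at the cluster-forming p and its clusters measured. A null model with
#' the contrast constrained to zero is fitted once; each bootstrap
#' replicate multiplies every participant's restricted-model residual
#' block by an independent Rademacher sign, rebuilds the data, refits the
#' full model, and records the maximum suprathreshold cluster size. The
#' FWE-corrected p of an observed cluster of size s is
#' `(1 + #\{replicates with max size >= s\}) / (B + 1)`, so the smallest
#' attainable value is `1 / (B + 1)`.
#'
#' @param stack A `tbm_stack`.
#' @param design An [swe_design()] for the stack.
#' @param contrast Contrast vector/matrix over design columns.
#' @param B Number of bootstrap replicates (>= 1; 999 is conventional).
#' @param cluster_forming_p Uncorrected threshold defining clusters.
#' @param connectivity 6, 18 or 26.
#' @param adjust Sandwich small-sample adjustment, as in
#'   [fit_marginal()].
#' @param log_jacobian Analyse log maps.
#' @param seed RNG seed for the Rademacher signs.
#' @return List of class `swe_fwe`: `clusters` (cluster table with
#'   `fwe_p`), `stat_map`, `null_max_sizes` (length B), `B`,
#'   `cluster_forming_p`, `connectivity`, `seed`, `min_attainable_p`.
#' @export
wild_bootstrap_fwe <- function(stack, design, contrast, B = 999,
                               cluster_forming_p = 0.001,
                               connectivity = 18, adjust = "HC2",
                               log_jacobian = FALSE, seed = 1L) {
  if (B < 1) stop_config("B must be >= 1")
  Y <- if (log_jacobian) log(stack$maps) else stack$maps
  pre <- swe_precompute(design$X, design$subject, contrast, adjust)
  if (pre$q >= pre$p)
    stop_config("contrast leaves no null design")

  obs <- fit_marginal(stack, design, contrast, adjust = adjust,
                      log_jacobian = log_jacobian)
  obs_clusters <- form_clusters(obs, cluster_forming_p, connectivity)

  ## restricted (null-imposed) fit
  N <- contrast_null_basis(pre$C)
  X0 <- design$X %*% N
  B0 <- solve(crossprod(X0), crossprod(X0, Y))
  fitted0 <- X0 %*% B0
  E0 <- Y - fitted0

  subj_of_row <- as.integer(pre$subject)
  n_subj <- nlevels(pre$subject)
  geom <- list(dim = stack$dim, voxel_index = stack$voxel_index)
  null_max <- integer(B)
  for (b in seq_len(B)) {
    signs <- with_seed(derive_seed(seed, 104729, b),
                       sample(c(-1, 1), n_subj, replace = TRUE))
    Ystar <- fitted0 + E0 * signs[subj_of_row]
    rb <- swe_apply(pre, Ystar)
    supra <- which(rb$p < cluster_forming_p)
    null_max[b] <- if (!length(supra)) 0L else {
      labs <- label_components(geom$voxel_index[supra], geom$dim,
                               connectivity)
      max(tabulate(labs))
    }
  }

  cl <- obs_clusters
  if (nrow(cl)) {
    cl$fwe_p <- vapply(cl$size,
                       function(s) (1 + sum(null_max >= s)) / (B + 1),
                       numeric(1))
  } else cl$fwe_p <- numeric(0)
  structure(list(clusters = cl, stat_map = obs, null_max_sizes = null_max,
                 B = B, cluster_forming_p = cluster_forming_p,
                 connectivity = connectivity, adjust = adjust,
                 seed = seed, min_attainable_p = 1 / (B + 1)),
            class = "swe_fwe")
}

#' @export
print.swe_fwe <- function(x, ...) {
  cat(sprintf(
    "Wild-bootstrap cluster FWE: B = %d, cluster-forming p = %g, %d-connectivity\n",
    x$B, x$cluster_forming_p, x$connectivity))
  if (nrow(x$clusters)) print(as.data.frame(x$clusters), digits = 4)
  else cat("  no suprathreshold clusters\n")
  invisible(x)
}
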