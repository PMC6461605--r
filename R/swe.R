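#' Build a voxel-wise marginal-model design
#'
#' One row per map. Columns: intercept plus the requested covariates,
#' where `group` codes the patient group as 0/1, `time` is the map's time
#' covariate (signed years to the participant mid-point, or cohort-centred
#' age for group-template maps), `sex` codes male as 1, and `etiv` is
#' standardised for conditioning. Interactions are written with `:` and
#' are elementwise products of the constituent columns.
#'
#' @param meta Map metadata (e.g. `stack$meta`): must contain the columns
#'   needed by `covariates`, plus `participant_id`.
#' @param covariates Character vector of column labels, e.g.
#'   `c("group", "time", "age", "sex", "diabetes", "group:time")`.
#' @return List of class `swe_design`: `X` (design matrix with intercept),
#'   `subject` (factor over rows), `columns`.
#' @export
swe_design <- function(meta, covariates = c("group", "time",
                                            "group:time")) {
  check_columns(meta, "participant_id", "stack meta")
  base_col <- function(nm) {
    switch(nm,
      group = as.numeric(meta$group == "wolfram"),
      time = meta$time,
      age = meta$age,
      sex = as.numeric(meta$sex == "M"),
      diabetes = as.numeric(meta$diabetes),
      etiv = as.numeric(scale(meta$etiv)),
      stop_config("unknown covariate: ", nm))
  }
  cols <- list(intercept = rep(1, nrow(meta)))
  for (cv in covariates) {
    parts <- strsplit(cv, ":", fixed = TRUE)[[1]]
    cols[[cv]] <- Reduce(`*`, lapply(parts, base_col))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop <- colnames(X)[setdiff(seq_len(ncol(X)),
                                qr_x$pivot[seq_len(qr_x$rank)])]
    stop_config("design matrix is rank deficient; collinear column(s): ",
                paste(drop, collapse = ", "))
  }
  structure(list(X = X, subject = factor(meta$participant_id),
                 columns = colnames(X)),
            class = "swe_design")
}

#' Contrast vector/matrix over design columns
#'
#' @param design An [swe_design()].
#' @param weights Named numeric vector (single-df contrast) or a list of
#'   such vectors (multi-df), names matching design columns.
#' @return Numeric matrix with one row per contrast df.
#' @export
swe_contrast <- function(design, weights) {
  if (!is.list(weights)) weights <- list(weights)
  C <- matrix(0, nrow = length(weights), ncol = length(design$columns),
              dimnames = list(NULL, design$columns))
  for (r in seq_along(weights)) {
    w <- weights[[r]]
    bad <- setdiff(names(w), design$columns)
    if (length(bad))
      stop_config("contrast names not in design: ",
                  paste(bad, collapse = ", "))
    C[r, names(w)] <- w
  }
  C
}

## Precompute everything that does not depend on the data values:
## OLS projector, per-subject blocks and HC2 adjustment, contrast rows.
swe_precompute <- function(X, subject, contrast, adjust = c("HC2", "none")) {
  adjust <- match.arg(adjust)
  n <- nrow(X); p <- ncol(X)
  C <- if (is.matrix(contrast)) contrast else matrix(contrast, nrow = 1)
  if (ncol(C) != p) stop_config("contrast length must equal design columns")
  XtXinv <- solve(crossprod(X))
  P1 <- XtXinv %*% t(X)            # p x n, beta = P1 Y
  subject <- factor(subject)
  blocks <- split(seq_len(n), subject)
  subj_w <- vector("list", length(blocks))  # q x ni row weights
  CA <- C %*% XtXinv               # q x p
  for (i in seq_along(blocks)) {
    rows <- blocks[[i]]
    Xi <- X[rows, , drop = FALSE]
    M <- diag(length(rows))
    if (adjust == "HC2") {
      H <- Xi %*% XtXinv %*% t(Xi)
      eh <- eigen((diag(length(rows)) - H), symmetric = TRUE)
      ev <- pmax(eh$values, 1e-12)
      M <- eh$vectors %*% diag(1 / sqrt(ev), length(ev)) %*% t(eh$vectors)
    }
    subj_w[[i]] <- (CA %*% t(Xi)) %*% M   # q x ni
  }
  list(X = X, n = n, p = p, q = nrow(C), C = C, XtXinv = XtXinv,
       P1 = P1, CA = CA, blocks = blocks, subj_w = subj_w,
       adjust = adjust, subject = subject)
}

## Apply the precomputed engine to a data matrix (maps x voxels):
## per voxel OLS beta, subject-level sandwich covariance of the contrast,
## Wald statistic and chi-square p value.
swe_apply <- function(pre, Y, return_beta = FALSE) {
  B <- pre$P1 %*% Y                     # p x V
  E <- Y - pre$X %*% B
  V <- ncol(Y)
  q <- pre$q
  cb <- pre$C %*% B                     # q x V
  ## voxels whose residuals are pure rounding noise have no usable
  ## variance estimate; flag them rather than divide noise by noise
  degenerate <- colSums(E^2) <= 1e-20 * colSums(Y^2)
  if (q == 1L) {
    var_c <- numeric(V)
    for (i in seq_along(pre$blocks)) {
      g <- pre$subj_w[[i]] %*% E[pre$blocks[[i]], , drop = FALSE]
      var_c <- var_c + as.numeric(g)^2
    }
    bad <- !(var_c > 0) | !is.finite(var_c) | degenerate
    wald <- numeric(V)
    wald[!bad] <- as.numeric(cb)[!bad]^2 / var_c[!bad]
  } else {
    gs <- vector("list", length(pre$blocks))
    for (i in seq_along(pre$blocks))
      gs[[i]] <- pre$subj_w[[i]] %*% E[pre$blocks[[i]], , drop = FALSE]
    wald <- numeric(V); bad <- degenerate
    Vc <- matrix(0, q, q)
    for (v in seq_len(V)) {
      if (bad[v]) next
      Vc[] <- 0
      for (i in seq_along(gs)) {
        gv <- gs[[i]][, v]
        Vc <- Vc + tcrossprod(gv)
      }
      w <- tryCatch(drop(crossprod(cb[, v], solve(Vc, cb[, v]))),
                    error = function(e) NA_real_)
      if (!is.finite(w)) { bad[v] <- TRUE; w <- 0 }
      wald[v] <- w
    }
  }
  p_val <- stats::pchisq(wald, df = q, lower.tail = FALSE)
  p_val[bad] <- 1
  out <- list(wald = wald, p = p_val, df = q, cb = cb,
              n_zero_variance = sum(bad))
  if (return_beta) { out$beta <- B; out$resid <- E }
  out
}

#' Voxel-wise marginal model with subject-level sandwich covariance
#'
#' Fits per-voxel ordinary least squares over all maps and estimates the
#' covariance of the contrast robustly from subject-level residual outer
#' products (the "sandwich"): each participant's residual block
#' contributes only to its own term, so groups with different covariance
#' structures are handled without pooling across groups and without
#' iterative random-effects fitting. Residual blocks are scaled by
#' `(I - H_ii)^{-1/2}` by default (HC2-type small-sample adjustment).
#' The Wald statistic `(C b)' [C V C']^{-1} (C b)` is referred to a
#' chi-square with `rank(C)` degrees of freedom.
#'
#' @param stack A `tbm_stack` (or a numeric matrix maps x voxels).
#' @param design An [swe_design()] built from the stack's metadata.
#' @param contrast Contrast from [swe_contrast()] (or numeric vector).
#' @param adjust `"HC2"` (default) or `"none"`.
#' @param log_jacobian Analyse `log(maps)` instead of raw values.
#' @param return_cov Also return the full p x p sandwich covariance of
#'   beta at every voxel (array `p x p x V`; small problems only).
#' @return Object of class `stat_map`: `beta` (p x V), `wald`, `p`, `df`,
#'   `contrast`, `n_zero_variance`, and stack geometry (`dim`,
#'   `voxel_index`, `mask`) when available.
#' @export
fit_marginal <- function(stack, design, contrast, adjust = "HC2",
                         log_jacobian = FALSE, return_cov = FALSE) {
  Y <- if (inherits(stack, "tbm_stack")) stack$maps else stack
  if (log_jacobian) Y <- log(Y)
  pre <- swe_precompute(design$X, design$subject, contrast, adjust)
  res <- swe_apply(pre, Y, return_beta = TRUE)
  out <- list(beta = res$beta, wald = res$wald, p = res$p, df = res$df,
              contrast = pre$C, n_zero_variance = res$n_zero_variance,
              columns = design$columns)
  if (return_cov) {
    V <- ncol(Y); p <- pre$p
    covb <- array(0, dim = c(p, p, V))
    for (i in seq_along(pre$blocks)) {
      rows <- pre$blocks[[i]]
      Xi <- pre$X[rows, , drop = FALSE]
      M <- diag(length(rows))
      if (adjust == "HC2") {
        H <- Xi %*% pre$XtXinv %*% t(Xi)
        eh <- eigen(diag(length(rows)) - H, symmetric = TRUE)
        M <- eh$vectors %*% diag(1 / sqrt(pmax(eh$values, 1e-12)),
                                 length(rows)) %*% t(eh$vectors)
      }
      Si <- pre$XtXinv %*% t(Xi) %*% M %*%
        res$resid[rows, , drop = FALSE]          # p x V
      for (v in seq_len(V))
        covb[, , v] <- covb[, , v] + tcrossprod(Si[, v])
    }
    out$cov_beta <- covb
  }
  if (inherits(stack, "tbm_stack")) {
    out$dim <- stack$dim; out$voxel_index <- stack$voxel_index
    out$mask <- stack$mask
  }
  structure(out, class = "stat_map")
}
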