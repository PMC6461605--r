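#' Spherical analysis mask
#'
#' @param dim Integer 3-vector of grid dimensions.
#' @param radius Radius in voxels (default: fits inside the grid with a
#'   one-voxel margin).
#' @param center Sphere centre (default: grid centre).
#' @return Logical 3-D array.
#' @export
sphere_mask <- function(dim, radius = min(dim) / 2 - 1,
                        center = (dim + 1) / 2) {
  idx <- as.matrix(expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                               z = seq_len(dim[3])))
  d2 <- (idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2 +
    (idx[, 3] - center[3])^2
  array(d2 <= radius^2, dim = dim)
}

#' Cubic effect cluster
#'
#' @param dim Grid dimensions.
#' @param center Cluster centre voxel.
#' @param half Half-width in voxels (cube side `2 * half + 1`).
#' @return Logical 3-D array marking cluster voxels.
#' @export
cube_cluster <- function(dim, center = round(dim / 2), half = 1) {
  a <- array(FALSE, dim = dim)
  lo <- pmax(center - half, 1); hi <- pmin(center + half, dim)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  a
}

#' Simulate a tensor-based morphometry (Jacobian determinant) map stack
#'
#' Generates per-visit 3-D Jacobian-determinant maps for every participant
#' in two registration variants. In the `to_midpoint` variant the
#' log-Jacobian at voxel v is `slope_g(v) * time_to_midpoint + noise`:
#' annualised expansion/contraction relative to the participant's own
#' mid-point template. In the `to_group_template` variant it is
#' `offset_i + group_offset_g(v) + slope_g(v) * time_ref + noise`, where
#' `offset_i` is a participant-level scale offset and `time_ref` is age at
#' scan centred on the cohort mean scan age. Slopes and group offsets are
#' nonzero only inside the effect cluster; all map values are positive.
#'
#' @param cohort A [generate_cohort()] result.
#' @param grid_dim Integer 3-vector, e.g. `c(16, 16, 16)`.
#' @param effect_spec List with elements `cluster` (logical array of
#'   `grid_dim`, or NULL for no effect), `slope` (named list/vector of
#'   log-Jacobian change per year for `wolfram` and `control`), and
#'   optionally `group_offset` (named, log scale, default 0).
#' @param noise_sd SD of independent voxel-level log-Jacobian noise
#'   (>= 0).
#' @param subject_offset_sd SD of the participant scale offset used in the
#'   `to_group_template` variant.
#' @param mask Logical 3-D analysis mask (default [sphere_mask()]).
#' @param variants Which variants to generate.
#' @param grid_spacing Voxel size in mm (metadata only).
#' @param seed RNG seed.
#' @return An object of class `tbm_stack`: list with `maps` (matrix,
#'   one row per map over in-mask voxels), `mask`, `dim`, `meta` (data
#'   frame: map, participant_id, group, session, variant, time, plus the
#'   participant covariates), `voxel_index` (in-mask linear indices), and
#'   `grid_spacing`.
#' @export
simulate_tbm_stack <- function(cohort, grid_dim = c(16L, 16L, 16L),
                               effect_spec = list(cluster = NULL,
                                                  slope = c(wolfram = 0,
                                                            control = 0)),
                               noise_sd = 0.03,
                               subject_offset_sd = 0.05,
                               mask = sphere_mask(grid_dim),
                               variants = c("to_midpoint",
                                            "to_group_template"),
                               grid_spacing = 1.5,
                               seed = derive_seed(cohort$seed, 99)) {
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (!identical(dim(mask), as.integer(grid_dim)))
    mask <- array(as.logical(mask), dim = grid_dim)
  vox <- which(mask)
  if (!length(vox)) stop_config("mask is empty")

  cl <- effect_spec$cluster
  in_cluster <- rep(FALSE, length(vox))
  if (!is.null(cl)) {
    if (is.matrix(cl)) {  # n x 3 voxel coordinates
      if (any(cl < 1) || any(t(cl) > grid_dim))
        stop_config("grid too small for requested cluster")
      cl_lin <- cl[, 1] + (cl[, 2] - 1) * grid_dim[1] +
        (cl[, 3] - 1) * prod(grid_dim[1:2])
    } else {
      cl_lin <- which(array(as.logical(cl), dim = grid_dim))
    }
    if (!all(cl_lin %in% vox))
      stop_config("effect cluster must lie inside the mask")
    in_cluster <- vox %in% cl_lin
  }
  slope <- effect_spec$slope %||% c(wolfram = 0, control = 0)
  goff <- effect_spec$group_offset %||% c(wolfram = 0, control = 0)

  p <- cohort$participants
  v <- cohort$visits
  idx <- match(v$participant_id, p$id)
  t_ref <- v$age_at_scan - mean(v$age_at_scan)
  u <- with_seed(derive_seed(seed, 1),
                 stats::rnorm(nrow(p), 0, subject_offset_sd))

  V <- length(vox)
  rows <- list(); meta <- list(); m <- 0L
  for (variant in variants) {
    for (j in seq_len(nrow(v))) {
      i <- idx[j]; g <- p$group[i]
      lin <- numeric(V)
      if (variant == "to_midpoint") {
        tcov <- v$time_to_midpoint[j]
        lin[in_cluster] <- unname(slope[[g]]) * tcov
      } else {
        tcov <- t_ref[j]
        lin[in_cluster] <- unname(goff[[g]]) + unname(slope[[g]]) * tcov
        lin <- lin + u[i]
      }
      eps <- with_seed(derive_seed(seed, 2, match(variant, variants), j),
                       stats::rnorm(V, 0, noise_sd))
      m <- m + 1L
      rows[[m]] <- exp(lin + eps)
      meta[[m]] <- data.frame(
        map = m, participant_id = v$participant_id[j], group = g,
        session = v$session[j], variant = variant, time = tcov,
        age = p$baseline_age[i], sex = p$sex[i],
        diabetes = p$diabetes[i], etiv = p$etiv[i],
        stringsAsFactors = FALSE)
    }
  }
  structure(list(maps = do.call(rbind, rows), mask = mask,
                 dim = as.integer(grid_dim),
                 meta = do.call(rbind, meta), voxel_index = vox,
                 in_cluster = in_cluster, grid_spacing = grid_spacing,
                 seed = seed),
            class = "tbm_stack")
}

#' Extract one map of a stack as a 3-D array
#'
#' @param stack A `tbm_stack`.
#' @param i Map index (row of `stack$meta`).
#' @return 3-D array with `NA` outside the mask.
#' @export
tbm_map <- function(stack, i) {
  a <- array(NA_real_, dim = stack$dim)
  a[stack$voxel_index] <- stack$maps[i, ]
  a
}

#' Subset a TBM stack by variant and visit structure
#'
#' For mid-point (longitudinal) analyses, single-visit participants carry
#' no within-subject change information and are dropped by default; for
#' group-template analyses they are retained.
#'
#' @param stack A `tbm_stack`.
#' @param variant `"to_midpoint"` or `"to_group_template"`.
#' @param drop_single_visit Drop participants with one visit (default:
#'   TRUE for `to_midpoint`).
#' @return A `tbm_stack` restricted to the selected maps.
#' @export
stack_subset <- function(stack, variant,
                         drop_single_visit = variant == "to_midpoint") {
  keep <- stack$meta$variant == variant
  if (drop_single_visit) {
    nv <- table(stack$meta$participant_id[keep])
    keep <- keep & stack$meta$participant_id %in% names(nv)[nv > 1]
  }
  out <- stack
  out$maps <- stack$maps[keep, , drop = FALSE]
  out$meta <- stack$meta[keep, , drop = FALSE]
  out$meta$map <- seq_len(nrow(out$meta))
  rownames(out$meta) <- NULL
  out
}
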