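## CSV dialect used throughout: UTF-8, comma separator, header row,
## "." decimal point.

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_csv_checked <- function(path, required, what) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, required, what)
  df
}

#' Write / read a cohort as CSV
#'
#' Two files: `participants.csv` (id, group, diabetes, sex, baseline_age,
#' etiv) and `visits.csv` (participant_id, session, age_at_scan,
#' time_from_baseline, time_to_midpoint). Round-trip preserves values.
#'
#' @param cohort A `cohort` object.
#' @param dir Output directory (created if needed).
#' @return `write_cohort`: the directory, invisibly. `read_cohort`: a
#'   `cohort` object.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_plain(cohort$participants, file.path(dir, "participants.csv"))
  write_csv_plain(cohort$visits, file.path(dir, "visits.csv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  p <- read_csv_checked(file.path(dir, "participants.csv"),
                        c("id", "group", "diabetes", "sex",
                          "baseline_age", "etiv"), "participants.csv")
  v <- read_csv_checked(file.path(dir, "visits.csv"),
                        c("participant_id", "session", "age_at_scan",
                          "time_from_baseline", "time_to_midpoint"),
                        "visits.csv")
  structure(list(participants = p, visits = v, design = NULL,
                 seed = NA_integer_), class = "cohort")
}

#' Write / read a long regional volume table as CSV
#'
#' @param volumes `roi_volumes` object or its `volumes` data frame.
#' @param path CSV path.
#' @return `read_roi_volumes` returns the data frame (schema-checked:
#'   `participant_id`, `group`, `session`, `time_from_baseline`,
#'   `region`, `volume`, `etiv`).
#' @export
write_roi_volumes <- function(volumes, path) {
  df <- if (inherits(volumes, "roi_volumes")) volumes$volumes else volumes
  write_csv_plain(df, path)
}

#' @rdname write_roi_volumes
#' @export
read_roi_volumes <- function(path) {
  read_csv_checked(path, c("participant_id", "group", "session",
                           "time_from_baseline", "region", "volume",
                           "etiv"), "volume table")
}

#' Write / read a 3-D volume as NIfTI-1
#'
#' Values are stored as float64 so round-trips are bitwise exact.
#'
#' @param vol 3-D numeric array.
#' @param path NIfTI path (`.nii` or `.nii.gz`).
#' @param spacing Voxel size in mm (isotropic).
#' @return `read_volume` returns the array with the NIfTI attributes of
#'   \pkg{RNifti}.
#' @export
write_volume <- function(vol, path, spacing = 1.5) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(spacing, 3)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) RNifti::readNifti(path)

#' Read a binary analysis mask from NIfTI
#'
#' @param path NIfTI path; voxel values must be exactly 0 or 1.
#' @return Logical 3-D array.
#' @export
read_mask <- function(path) {
  v <- as.array(RNifti::readNifti(path))
  if (!all(v %in% c(0, 1)))
    stop_data("mask must be binary (values 0/1 only): ", path)
  array(v == 1, dim = dim(v))
}

#' Write / read a TBM stack as per-map NIfTI files plus a manifest
#'
#' The manifest CSV has one row per map (participant_id, session,
#' variant, time, filename); the mask is written as `mask.nii.gz`.
#'
#' @param stack A `tbm_stack`.
#' @param dir Output directory.
#' @return `read_tbm_stack` rebuilds a `tbm_stack` (without effect-truth
#'   metadata); map shapes are checked against the mask.
#' @export
write_tbm_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(array(as.numeric(stack$mask), dim = stack$dim),
               file.path(dir, "mask.nii.gz"), stack$grid_spacing)
  fn <- sprintf("map_%04d.nii.gz", seq_len(nrow(stack$meta)))
  for (i in seq_len(nrow(stack$meta))) {
    a <- array(1, dim = stack$dim)  # unit Jacobian outside the mask
    a[stack$voxel_index] <- stack$maps[i, ]
    write_volume(a, file.path(dir, fn[i]), stack$grid_spacing)
  }
  manifest <- cbind(stack$meta, filename = fn)
  write_csv_plain(manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' @rdname write_tbm_stack
#' @export
read_tbm_stack <- function(dir) {
  manifest <- read_csv_checked(file.path(dir, "manifest.csv"),
                               c("participant_id", "session", "variant",
                                 "time", "filename"), "manifest.csv")
  mask <- read_mask(file.path(dir, "mask.nii.gz"))
  vox <- which(mask)
  maps <- matrix(NA_real_, nrow(manifest), length(vox))
  for (i in seq_len(nrow(manifest))) {
    a <- as.array(read_volume(file.path(dir, manifest$filename[i])))
    if (!identical(dim(a), dim(mask)))
      stop_data("map shape mismatch with mask: ", manifest$filename[i])
    maps[i, ] <- a[vox]
  }
  structure(list(maps = maps, mask = mask, dim = dim(mask),
                 meta = manifest[setdiff(names(manifest), "filename")],
                 voxel_index = vox,
                 grid_spacing = RNifti::pixdim(
                   read_volume(file.path(dir, "mask.nii.gz")))[1]),
            class = "tbm_stack")
}

#' Write a cluster table as CSV (0-based voxel coordinates)
#'
#' @param clusters A `cluster_table` (optionally with `fwe_p`).
#' @param path CSV path. The first line is a comment stating the
#'   coordinate convention.
#' @export
write_cluster_table <- function(clusters, path) {
  df <- as.data.frame(clusters)
  for (cc in c("peak_x", "peak_y", "peak_z"))
    if (cc %in% names(df)) df[[cc]] <- df[[cc]] - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# peak voxel coordinates are 0-based", con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
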