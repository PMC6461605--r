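#' Load the packaged study parameter presets
#'
#' Reads the editable YAML parameter file shipped with the package (or a
#' user-supplied one with the same structure). The file holds the cohort
#' design presets (group sizes, age ranges, visit-count distributions),
#' per-region trajectory presets (annual-rate means and SEMs, baseline and
#' residual scales, eTIV coupling), the WURS coupling calibration, and the
#' trial-simulation defaults.
#'
#' @param path Path to a YAML parameter file; default is the packaged file.
#' @return A nested list mirroring the YAML structure, with derived
#'   quantities added: each region gains `slope_sd` (per group,
#'   `sem * sqrt(n)`), and `$wurs$latent_pearson` holds the calibrated
#'   latent coupling (see [wurs_latent_coupling()]).
#' @export
#' @examples
#' p <- longimorph_params()
#' p$regions$thalamus$mean_slope$wolfram
longimorph_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "longimorph_params.yaml",
                        package = "longimorph", mustWork = TRUE)
  p <- yaml::read_yaml(path)
  n <- c(wolfram = p$cohort$n_wolfram, control = p$cohort$n_control)
  p$regions <- lapply(p$regions, function(r) {
    r$slope_sd <- list(
      wolfram = r$slope_sem$wolfram * sqrt(n[["wolfram"]]),
      control = r$slope_sem$control * sqrt(n[["control"]]))
    r
  })
  p$wurs$latent_pearson <- wurs_latent_coupling(
    p$wurs$target_sample_spearman, n = p$wurs$reference_n)
  p
}

#' Region names covered by the packaged presets
#' @return Character vector of the five regions.
#' @export
roi_regions <- function() {
  c("brainstem", "ventral_pons", "cerebellar_white", "cerebellar_gray",
    "thalamus")
}
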