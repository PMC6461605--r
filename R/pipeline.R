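#' Default end-to-end pipeline configuration
#'
#' @param seed Master seed for all stages.
#' @param out_dir Output directory.
#' @param ... Overrides for any default element (unknown names are
#'   rejected).
#' @return Named list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("longimorph_"),
                            ...) {
  cfg <- list(
    seed = seed,
    out_dir = out_dir,
    regions = roi_regions(),
    grid_dim = c(16L, 16L, 16L),
    cluster_half_width = 1L,
    tbm_slope = c(wolfram = -0.02, control = 0.005),
    tbm_group_offset = c(wolfram = -0.05, control = 0),
    tbm_noise_sd = 0.03,
    n_bootstrap = 199L,
    cluster_forming_p = 0.001,
    connectivity = 18,
    power_n_per_arm = 34L,
    power_reductions = c(0.5, 0.6),
    power_n_trials = 200L,
    voxelwise = TRUE,
    tbm_manifest = NULL,   # real-data entry: directory with manifest/mask
    mask = NULL,
    one_tailed_change = TRUE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_config("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

stage <- function(name, log_con, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  writeLines(sprintf("stage %-10s ok  (%.1f s)", name,
                     as.numeric(difftime(Sys.time(), t0, units = "secs"))),
             log_con)
  res
}

#' Run the full synthetic-study pipeline
#'
#' Generates a cohort, simulates and analyses the five regional volume
#' trajectories (backward-selected random-slope models, annual percent
#' change, severity correlation), runs the four voxel-wise contrasts with
#' wild-bootstrap cluster FWE correction on a simulated TBM stack, and
#' estimates trial power. All artefacts, the fully resolved
#' configuration (JSON) and a run log are written to `out_dir`; the run
#' is deterministic given the seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the main in-memory results and the
#'   output directory.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  writeLines(c(sprintf("longimorph %s | R %s",
                       as.character(utils::packageVersion("longimorph")),
                       paste(R.version$major, R.version$minor, sep = ".")),
               sprintf("seed %d", cfg$seed)), log_con)
  params <- longimorph_params()
  jsonlite::write_json(cfg[setdiff(names(cfg), "mask")],
                       file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  cohort <- stage("generate", log_con, {
    ch <- generate_cohort(cohort_design(seed = cfg$seed), params = params)
    write_cohort(ch, file.path(cfg$out_dir, "cohort"))
    ch
  })

  roi <- stage("roi", log_con, {
    vols <- simulate_roi_volumes(cohort, params, regions = cfg$regions)
    vols <- correct_for_etiv(vols)
    write_roi_volumes(vols, file.path(cfg$out_dir, "roi_volumes.csv"))
    fits <- list(); change <- list(); trace_lines <- character(0)
    for (rg in cfg$regions) {
      mf <- roi_model_frame(vols, cohort, region = rg)
      sel <- backward_select(mf, mixed_model_spec(outcome = rg))
      fits[[rg]] <- sel
      change[[rg]] <- annual_percent_change(sel$fit, mf, region = rg,
                                            one_tailed = cfg$one_tailed_change)
      trace_lines <- c(trace_lines, paste0("== ", rg, " =="),
                       if (nrow(sel$trace))
                         sprintf("removed %-18s p = %.4f",
                                 sel$trace$term, sel$trace$p)
                       else "nothing removed")
    }
    writeLines(trace_lines, file.path(cfg$out_dir, "selection_trace.txt"))
    change_df <- do.call(rbind, change)
    write_csv_plain(change_df, file.path(cfg$out_dir, "change_summary.csv"))

    lat <- vols$latents[vols$latents$region == "thalamus", ]
    slopes <- stats::setNames(lat$true_slope, lat$participant_id)
    wurs <- simulate_wurs(cohort, slopes, params = params)
    thal_ps <- attr(change[["thalamus"]], "per_subject")
    thal_ps <- thal_ps[thal_ps$group == "wolfram", ]
    wc <- wurs_slope_correlation(
      thal_ps$pct_change[match(wurs$participant_id,
                               thal_ps$participant_id)],
      wurs$wurs_physical)
    jsonlite::write_json(wc, file.path(cfg$out_dir, "wurs_correlation.json"),
                         auto_unbox = TRUE, digits = NA)
    list(volumes = vols, fits = fits, change = change_df, wurs = wc)
  })

  vox <- NULL
  if (isTRUE(cfg$voxelwise)) {
    vox <- stage("voxelwise", log_con, {
      if (!is.null(cfg$tbm_manifest)) {
        if (is.null(cfg$mask))
          stop_config("voxelwise enabled with a map manifest but no mask")
        stack <- read_tbm_stack(cfg$tbm_manifest)
      } else {
        stack <- simulate_tbm_stack(
          cohort, grid_dim = cfg$grid_dim,
          effect_spec = list(
            cluster = cube_cluster(cfg$grid_dim,
                                   half = cfg$cluster_half_width),
            slope = cfg$tbm_slope, group_offset = cfg$tbm_group_offset),
          noise_sd = cfg$tbm_noise_sd,
          seed = derive_seed(cfg$seed, 5))
      }
      analyses <- list(
        group = list(variant = "to_group_template",
                     covariates = c("group", "time", "age", "sex",
                                    "diabetes", "etiv"),
                     weights = c(group = 1)),
        group_by_time = list(variant = "to_midpoint",
                             covariates = c("group", "time", "age", "sex",
                                            "diabetes", "group:time"),
                             weights = c("group:time" = 1)),
        group_by_time_by_age = list(
          variant = "to_midpoint",
          covariates = c("group", "time", "age", "sex", "diabetes",
                         "group:time", "group:age", "time:age",
                         "group:time:age"),
          weights = c("group:time:age" = 1)),
        time_wolfram = list(variant = "to_midpoint",
                            covariates = c("group", "time", "age", "sex",
                                           "diabetes", "group:time"),
                            weights = c(time = 1, "group:time" = 1)),
        time_control = list(variant = "to_midpoint",
                            covariates = c("group", "time", "age", "sex",
                                           "diabetes", "group:time"),
                            weights = c(time = 1)))
      out <- list()
      for (nm in names(analyses)) {
        an <- analyses[[nm]]
        sub <- stack_subset(stack, an$variant)
        des <- swe_design(sub$meta, an$covariates)
        fwe <- wild_bootstrap_fwe(
          sub, des, swe_contrast(des, an$weights), B = cfg$n_bootstrap,
          cluster_forming_p = cfg$cluster_forming_p,
          connectivity = cfg$connectivity,
          seed = derive_seed(cfg$seed, 6, match(nm, names(analyses))))
        write_cluster_table(fwe$clusters,
                            file.path(cfg$out_dir,
                                      paste0("clusters_", nm, ".csv")))
        out[[nm]] <- fwe
      }
      jsonlite::write_json(
        list(seed = cfg$seed, B = cfg$n_bootstrap,
             cluster_forming_p = cfg$cluster_forming_p,
             connectivity = cfg$connectivity,
             analyses = names(analyses)),
        file.path(cfg$out_dir, "voxelwise_meta.json"),
        auto_unbox = TRUE, digits = NA)
      out
    })
  }

  pow <- stage("power", log_con, {
    rows <- list()
    for (r in cfg$power_reductions) {
      d <- trial_design(n_per_arm = cfg$power_n_per_arm, reduction = r,
                        n_trials = cfg$power_n_trials,
                        seed = derive_seed(cfg$seed, 7, round(100 * r)),
                        params = params)
      row <- empirical_power(d)
      row$analytic_power <- analytic_power(d)
      rows[[length(rows) + 1]] <- row
    }
    pc <- do.call(rbind, rows)
    write_csv_plain(pc, file.path(cfg$out_dir, "power.csv"))
    pc
  })

  invisible(list(out_dir = cfg$out_dir, cohort = cohort, roi = roi,
                 voxelwise = vox, power = pow))
}
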