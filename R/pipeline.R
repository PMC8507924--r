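#' Measure habitat volumes over a simulated group
#'
#' Generates `n` phantoms from one survival-group model, segments each with
#' the k-means habitat pipeline and measures the habitat volumes, returning
#' one row per subject. This is the volume parameter-recovery analog of the
#' group-wise volume tables: the cohort means of the measured
#' low-diffusivity/low-perfusion (`LMD_LrCBV`) and
#' high-diffusivity/low-perfusion-in-necrosis (`HMD_LrCBV_nec`) volumes
#' estimate the group-model means.
#'
#' @param group `"short"` or `"long"`.
#' @param n number of phantoms.
#' @param seed integer seed.
#' @param model optional [group_model()] override.
#' @param grid_shape,voxel_size forwarded to [phantom_spec()].
#' @return Data frame: measured `LMD_LrCBV`, `HMD_LrCBV_nec`, `En`, `Nec`,
#'   `En_HrCBV`, `tumor` (cm^3) plus the matching ground-truth values.
#' @export
volume_recovery_study <- function(group, n = 200, seed = 1, model = NULL,
                                  grid_shape = c(64L, 64L, 64L),
                                  voxel_size = c(1, 1, 1)) {
  model <- model %||% group_model(group)
  spec <- phantom_spec(grid_shape = grid_shape, voxel_size = voxel_size,
                       n_short = 1, n_long = 1, seed = seed)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- generate_subject(spec, model, derive_seed(seed, i))
    cat_i <- suppressWarnings(
      segment_subject(sub$volumes, seed = derive_seed(seed, 100000 + i)))
    vr <- roi_volumes(cat_i, sub$volumes$tumor_mask,
                      sub$volumes$voxel_size)
    g <- function(r) vr$absolute_cm3[vr$roi == r]
    tv <- sub$truth$true_volumes
    rows[[i]] <- data.frame(
      LMD_LrCBV = g("LMD_LrCBV"), HMD_LrCBV_nec = g("HMD_LrCBV_nec"),
      En = g("CE"), Nec = g("necrotic"), En_HrCBV = g("En_HrCBV"),
      tumor = g("tumor"),
      true_LMD_LrCBV = tv[["LMD_LrCBV"]],
      true_HMD_LrCBV = tv[["HMD_LrCBV"]])
  }
  do.call(rbind, rows)
}

default_run_config <- function() {
  list(
    phantom = list(grid_shape = c(64L, 64L, 64L), voxel_size = c(1, 1, 1),
                   n_short = 16L, n_long = 13L, noise_sd = NULL),
    segmentation = list(slicewise = FALSE),
    radiomics = list(n_levels = 32L),
    selection = list(enabled = TRUE, n_select = 60L, step_fraction = 0.1,
                     rfe_trees = 200L),
    gboost = list(n_estimators = 200L, learning_rate = 0.05, max_depth = 1L,
                  subsample = 0.8, min_leaf = 5L),
    evaluation = list(n_trials = 10L, tune = FALSE, paper_faithful = FALSE),
    seed = 1L,
    out_dir = "habitboost-run"
  )
}

#' Validate a pipeline run configuration
#'
#' Reads a YAML file (or takes a list), injects defaults for omitted
#' fields, and reports every violation with a path into the configuration
#' (e.g. `phantom.noise_sd`). An empty file yields the defaults-only
#' configuration.
#'
#' @param config path to a YAML file, or a named list.
#' @return Validated configuration list of class `run_config`; errors list
#'   all violations.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  if (!is.list(config)) stopf("config must be a YAML mapping or a list")
  cfg <- modifyList(default_run_config(), config)
  errs <- character(0)
  chk <- function(ok, path, msg)
    if (!ok) errs <<- c(errs, sprintf("%s: %s", path, msg))
  ph <- cfg$phantom
  chk(length(ph$grid_shape) == 3 && all(ph$grid_shape >= 8),
      "phantom.grid_shape", "must be three axis lengths >= 8")
  chk(all(ph$voxel_size > 0), "phantom.voxel_size",
      "must be strictly positive")
  chk(ph$n_short >= 0 && ph$n_long >= 0 && ph$n_short + ph$n_long >= 2,
      "phantom.n_short", "cohort needs at least two subjects")
  if (!is.null(ph$noise_sd))
    chk(all(unlist(ph$noise_sd) >= 0), "phantom.noise_sd", "must be >= 0")
  chk(cfg$radiomics$n_levels >= 2, "radiomics.n_levels", "must be >= 2")
  n_features <- 480L
  chk(cfg$selection$n_select >= 1 &&
        cfg$selection$n_select <= n_features, "selection.n_select",
      sprintf("must be in [1, %d]", n_features))
  chk(cfg$selection$step_fraction > 0 && cfg$selection$step_fraction <= 1,
      "selection.step_fraction", "must be in (0, 1]")
  chk(cfg$gboost$learning_rate > 0 && cfg$gboost$learning_rate <= 1,
      "gboost.learning_rate", "must be in (0, 1]")
  chk(cfg$gboost$subsample > 0 && cfg$gboost$subsample <= 1,
      "gboost.subsample", "must be in (0, 1]")
  chk(cfg$evaluation$n_trials >= 1, "evaluation.n_trials", "must be >= 1")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed",
      "must be a single integer")
  if (length(errs))
    stopf("invalid configuration:\n  %s", paste(errs, collapse = "\n  "))
  class(cfg) <- "run_config"
  cfg
}

#' Run the full phantom-to-evaluation pipeline
#'
#' Executes the stages in order — phantom generation, habitat segmentation,
#' radiomic feature extraction, RF-RFE selection, repeated-LOOCV evaluation
#' — writing per-stage artifacts (gzipped NIfTI volumes, CSV tables, JSON
#' reports), a run manifest with checksums of the text artifacts, and a
#' human-readable summary (metric panel, group volume means, feature-count
#' check). Reruns with the same configuration produce identical summary and
#' manifest checksums. A stage error aborts the run with the stage name;
#' partial outputs are retained next to a `FAILED` marker.
#'
#' @param config a [validate_config()] result, a list, or a YAML path.
#' @param out_dir overrides `config$out_dir`.
#' @return The run directory, invisibly; the summary is written to
#'   `summary.json`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  run_dir <- out_dir %||% config$out_dir
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
               file.path(run_dir, "FAILED"))
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  }
  tryCatch({
    stage <- "phantom"
    gm <- list(
      short = do.call(group_model, c(list(group = "short"),
                                     if (!is.null(config$phantom$noise_sd))
                                       list(noise_sd = unlist(config$phantom$noise_sd)))),
      long = do.call(group_model, c(list(group = "long"),
                                    if (!is.null(config$phantom$noise_sd))
                                      list(noise_sd = unlist(config$phantom$noise_sd)))))
    spec <- phantom_spec(grid_shape = config$phantom$grid_shape,
                         voxel_size = config$phantom$voxel_size,
                         n_short = config$phantom$n_short,
                         n_long = config$phantom$n_long,
                         seed = derive_seed(config$seed, 1),
                         group_models = gm)
    cohort <- generate_cohort(spec, out_dir = file.path(run_dir, "phantom"))

    stage <- "habitats"
    hab_dir <- file.path(run_dir, "habitats")
    dir.create(hab_dir, recursive = TRUE, showWarnings = FALSE)
    catalogs <- vector("list", length(cohort$subjects))
    hab_summary <- list()
    for (i in seq_along(cohort$subjects)) {
      sid <- cohort$manifest$subject_id[i]
      sub <- cohort$subjects[[i]]
      catalogs[[i]] <- suppressWarnings(
        segment_subject(sub$volumes, seed = derive_seed(config$seed, 100 + i),
                        slicewise = config$segmentation$slicewise))
      sdir <- file.path(hab_dir, sid)
      dir.create(sdir, showWarnings = FALSE)
      for (nm in names(catalogs[[i]]$masks)) {
        img <- RNifti::asNifti(catalogs[[i]]$masks[[nm]] * 1,
                               pixdim = sub$volumes$voxel_size)
        RNifti::writeNifti(img, file.path(sdir, paste0(nm, ".nii.gz")))
      }
      truth_masks <- sub$truth$subhabitat_masks
      hab_summary[[sid]] <- list(
        voxel_counts = lapply(catalogs[[i]]$masks, sum),
        dice_vs_truth = lapply(names(truth_masks), function(nm)
          dice(catalogs[[i]]$masks[[nm]], truth_masks[[nm]])) |>
          setNames(names(truth_masks)))
    }
    jsonlite::write_json(hab_summary, file.path(hab_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)

    stage <- "radiomics"
    rad_dir <- file.path(run_dir, "radiomics")
    dir.create(rad_dir, showWarnings = FALSE)
    vecs <- list(); labs <- character(0); vol_rows <- list()
    for (i in seq_along(cohort$subjects)) {
      sid <- cohort$manifest$subject_id[i]
      sub <- cohort$subjects[[i]]
      vecs[[sid]] <- extract_subject_features(
        sub$volumes, catalogs[[i]],
        config = list(n_levels = config$radiomics$n_levels))
      labs <- c(labs, sub$truth$survival_class)
      vr <- roi_volumes(catalogs[[i]], sub$volumes$tumor_mask,
                        sub$volumes$voxel_size)
      vol_rows[[sid]] <- data.frame(subject_id = sid,
                                    group = sub$truth$survival_class, vr)
    }
    table <- assemble_feature_table(vecs, labs)
    feat_df <- data.frame(subject_id = table$subject_ids, table$x_raw,
                          label = as.character(table$labels),
                          check.names = FALSE)
    write.csv(feat_df, file.path(rad_dir, "features.csv"),
              row.names = FALSE)
    volumes <- do.call(rbind, vol_rows)
    write.csv(volumes, file.path(rad_dir, "volumes.csv"),
              row.names = FALSE)

    stage <- "selection"
    sel_dir <- file.path(run_dir, "selection")
    dir.create(sel_dir, showWarnings = FALSE)
    sel <- NULL
    if (isTRUE(config$selection$enabled)) {
      sel <- rf_rfe(table$x, table$labels,
                    n_select = config$selection$n_select,
                    step_fraction = config$selection$step_fraction,
                    n_trees = config$selection$rfe_trees,
                    seed = derive_seed(config$seed, 2))
      jsonlite::write_json(
        list(selected = sel$selected,
             elimination_trace = sel$elimination_trace, seed = sel$seed),
        file.path(sel_dir, "selection.json"), auto_unbox = TRUE,
        digits = NA)
    }

    stage <- "evaluation"
    eval_dir <- file.path(run_dir, "evaluation")
    dir.create(eval_dir, showWarnings = FALSE)
    ec <- eval_config(rfe = isTRUE(config$selection$enabled),
                      n_select = config$selection$n_select,
                      step_fraction = config$selection$step_fraction,
                      rfe_trees = config$selection$rfe_trees,
                      gboost = config$gboost,
                      tune = isTRUE(config$evaluation$tune),
                      paper_faithful = isTRUE(config$evaluation$paper_faithful))
    report <- suppressWarnings(
      repeated_trials(table, ec, n_trials = config$evaluation$n_trials,
                      base_seed = derive_seed(config$seed, 3)))
    write.csv(data.frame(trial = seq_len(report$n_trials),
                         accuracy = report$per_trial$accuracy),
              file.path(eval_dir, "trial_accuracies.csv"),
              row.names = FALSE)
    write.csv(report$roc, file.path(eval_dir, "roc.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(mean = as.list(report$mean), sd = as.list(report$sd),
           n_trials = report$n_trials, seeds = report$seeds),
      file.path(eval_dir, "cv_report.json"), auto_unbox = TRUE,
      digits = NA)

    stage <- "summary"
    vol_means <- aggregate(cbind(absolute_cm3) ~ group + roi, volumes, mean)
    summary <- list(
      n_subjects = nrow(table$x),
      n_features = ncol(table$x),
      n_selected = if (is.null(sel)) NULL else length(sel$selected),
      metrics_mean = as.list(round(report$mean, 6)),
      metrics_sd = as.list(round(report$sd, 6)),
      group_volume_means_cm3 = split(
        setNames(vol_means$absolute_cm3, vol_means$roi), vol_means$group),
      seed = config$seed)
    jsonlite::write_json(summary, file.path(run_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)

    files <- list.files(run_dir, recursive = TRUE, full.names = TRUE)
    text_files <- files[grepl("\\.(csv|json)$", files)]
    manifest <- data.frame(
      file = substring(text_files, nchar(run_dir) + 2),
      md5 = unname(tools::md5sum(text_files)))
    write.csv(manifest, file.path(run_dir, "run_manifest.csv"),
              row.names = FALSE)
    invisible(run_dir)
  }, error = on_fail)
}
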