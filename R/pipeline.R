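run_stage <- function(name, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
  elapsed <- proc.time()[["elapsed"]] - t0
  log$stages[[name]] <- list(seconds = round(elapsed, 3))
  message(sprintf("[%s] done in %.2f s", name, elapsed))
  res
}

#' Run the full body-composition pipeline
#'
#' Orchestrates phantom generation (or file input), compartmentalization,
#' tissue classification, quantification, and — when a cohort block is
#' configured — the survival-model stage, writing every intermediate labelmap
#' and table plus a manifest with seeds and per-stage wall time. Reruns with
#' the same config and seed are bit-identical for labelmaps and tables.
#'
#' @param config A named list or a path to a YAML file with fields `mode`
#'   (`"phantom"` or `"files"`), `output_dir`, `seed`, and optional blocks
#'   `phantom` (overrides for [phantom_spec()]), `files` (`volume` path and
#'   named `masks` paths), `subject` (`sex`, `height_cm`, `weight_kg`),
#'   `options` (`body_threshold`, `hull_organs`, `eat_density_gated`,
#'   `noise_sd`), and `cohort` (overrides for [cohort_spec()] plus `models`,
#'   a list of covariate vectors).
#' @return Invisibly, a list with `metrics`, `manifest`, and the segmentation
#'   objects.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  mode <- config$mode %||% "phantom"
  out_dir <- config$output_dir %||% "thoraxcomp-run"
  seed <- as.integer(config$seed %||% 1L)
  opts <- config$options %||% list()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- new.env()
  log$stages <- list()

  truth <- NULL
  if (mode == "phantom") {
    spec <- do.call(phantom_spec, config$phantom %||% list())
    ph <- run_stage("phantom", log, generate_phantom(spec, seed = seed))
    volume <- ph$volume
    masks <- ph$masks
    truth <- ph$truth
    noise_sd <- opts$noise_sd %||% 0
    if (noise_sd > 0) {
      volume <- run_stage("degrade", log, degrade_phantom(volume, noise_sd, seed = seed))
    }
    run_stage("write-inputs", log, {
      write_ct_volume(volume, file.path(out_dir, "volume.nii.gz"))
      write_mask_set(masks, file.path(out_dir, "masks"))
      jsonlite::write_json(
        c(as.list(truth), attributes(truth)[c("body_voxels", "cavity_voxels",
                                              "lung_voxels", "slab")]),
        file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA
      )
    })
  } else if (mode == "files") {
    volume <- run_stage("read-volume", log, read_ct_volume(config$files$volume))
    masks <- run_stage("read-masks", log,
                       read_mask_set(config$files$masks, reference = volume))
  } else {
    abort(sprintf("Unknown mode '%s'.", mode))
  }

  ranges <- if (is.null(config$hu_ranges)) hu_ranges() else do.call(hu_ranges, config$hu_ranges)
  seg <- run_stage("segment", log, segment_volume(
    volume, masks, ranges = ranges,
    body_threshold = opts$body_threshold %||% -500,
    hull_organs = opts$hull_organs %||% c("lungs", "heart", "eat"),
    eat_density_gated = opts$eat_density_gated %||% TRUE
  ))

  subj <- NULL
  if (!is.null(config$subject)) {
    subj <- subject(id = config$subject$id %||% "subject",
                    sex = config$subject$sex %||% "female",
                    height_cm = config$subject$height_cm,
                    weight_kg = config$subject$weight_kg)
  }
  metrics <- run_stage("quantify", log, summarize_composition(
    seg$labels, volume, seg$compartments, subj = subj,
    lungs = masks$masks[["lungs"]]
  ))

  run_stage("write-outputs", log, {
    write_ct_volume(seg$compartments$labels, file.path(out_dir, "compartments.nii.gz"),
                    spacing = volume$spacing, datatype = "uint8")
    write_ct_volume(seg$labels$labels, file.path(out_dir, "tissue_labels.nii.gz"),
                    spacing = volume$spacing, datatype = "uint8")
    utils::write.csv(metrics, file.path(out_dir, "composition.csv"), row.names = FALSE)
    utils::write.csv(composition_row(metrics), file.path(out_dir, "composition_row.csv"),
                     row.names = FALSE)
  })

  models <- NULL
  if (!is.null(config$cohort)) {
    models <- run_stage("cohort-models", log, {
      cargs <- config$cohort
      model_spec <- cargs$models
      cargs$models <- NULL
      cspec <- do.call(cohort_spec, cargs)
      cohort <- impute_missing_bmi(simulate_cohort(cspec, seed = seed))
      utils::write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
      fits <- lapply(model_spec %||% list(base = c("age", "vat_density_hu")),
                     function(cv) fit_cox(cohort, unlist(cv)))
      res <- dplyr::bind_rows(lapply(names(fits), function(nm) {
        td <- tidy(fits[[nm]], exponentiate = TRUE)
        td$model <- nm
        td
      }))
      utils::write.csv(res, file.path(out_dir, "cox_results.csv"), row.names = FALSE)
      list(fits = fits, results = res)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("thoraxcomp")),
    r_version = R.version.string,
    mode = mode, seed = seed,
    stages = log$stages,
    voxel_counts = list(
      body = sum(seg$compartments$labels > 0L),
      intrathoracic = sum(seg$compartments$labels == 1L),
      extrathoracic = sum(seg$compartments$labels == 2L)
    ),
    tissue_volumes_cm3 = setNames(as.list(metrics$volume_cm3), metrics$tissue)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(metrics = metrics, manifest = manifest, segmentation = seg,
                 truth = truth, models = models))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
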