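#' Pipeline configuration
#'
#' Bundles the segmentation and DWMA-detection parameters with optional
#' I/O paths. Can be read from / written to YAML.
#'
#' @param seg a [seg_config()].
#' @param dwma a [dwma_config()].
#' @param bias_order polynomial order of the bias-field model (default 3;
#'   0 disables bias correction).
#' @param normalization `"median_iqr"` or `"zscore"`.
#' @param mask_threshold atlas tissue-prior threshold for the working brain
#'   mask (default 0.9): only voxels this confidently cerebral enter the
#'   bias fit and segmentation, keeping skull-boundary voxels, which belong
#'   to no modelled tissue class, out of the mixture.
#' @param paths named list of file paths (`input`, `atlas`, `out_dir`), all
#'   optional when running in memory.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seg = seg_config(), dwma = dwma_config(),
                            bias_order = 3, normalization = "median_iqr",
                            mask_threshold = 0.9, paths = list()) {
  if (bias_order < 0) stop("bias_order must be >= 0")
  if (mask_threshold <= 0 || mask_threshold >= 1)
    stop("mask_threshold must be in (0, 1)")
  structure(list(seg = seg, dwma = dwma, bias_order = bias_order,
                 normalization = normalization,
                 mask_threshold = mask_threshold, paths = paths),
            class = "pipeline_config")
}

config_as_list <- function(config) {
  list(seg = unclass(config$seg),
       dwma = unclass(config$dwma),
       bias_order = config$bias_order,
       normalization = config$normalization,
       mask_threshold = config$mask_threshold)
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @param config a [pipeline_config()].
#' @return a `pipeline_config` (read) or `path` (write).
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(seg = do.call(seg_config, y$seg %||% list()),
                  dwma = do.call(dwma_config, y$dwma %||% list()),
                  bias_order = y$bias_order %||% 3,
                  normalization = y$normalization %||% "median_iqr",
                  mask_threshold = y$mask_threshold %||% 0.9,
                  paths = y$paths %||% list())
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(c(config_as_list(config), list(paths = config$paths)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full DWMA quantification pipeline
#'
#' Executes, in order: brain masking from the atlas, bias-field correction,
#' intensity normalization, atlas-guided EM tissue segmentation, ventricle
#' identification, centrum semiovale definition, and SD-threshold DWMA
#' detection with small-component clean-up. After phantom generation the
#' pipeline is fully deterministic: reruns on the same inputs give
#' byte-identical results.
#'
#' @param volume input T2w [brain_volume()] or a NIfTI path.
#' @param atlas co-registered `tissue_atlas` or an atlas NIfTI path.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, the bias field, hard
#'   segmentation, centrum semiovale mask, DWMA mask (all NIfTI) and a
#'   result JSON embedding the configuration are written there.
#' @param verbose log stage progress to stderr.
#' @return list with `result` (a `dwma_result`), `segmentation`,
#'   `cs_mask`, `ventricles`, `bias`, `normalized` volume, and (when
#'   `out_dir` is given) `artifacts`, the named vector of files written.
#' @export
run_pipeline <- function(volume, atlas, config = pipeline_config(),
                         out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message("[neodwma] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (is.character(volume)) volume <- stage("read", read_volume(volume))
  if (is.character(atlas)) atlas <- stage("read", read_atlas(atlas))

  say("brain mask from atlas (threshold %.2f)", config$mask_threshold)
  mask <- stage("brain_mask", brain_mask_from_atlas(atlas, config$mask_threshold))

  corrected <- volume
  bias <- NULL
  if (config$bias_order > 0) {
    say("bias field correction (order %d)", config$bias_order)
    bias <- stage("bias_field",
                  estimate_bias_field(volume, mask, config$bias_order, atlas))
    corrected <- stage("bias_field", correct_bias(volume, bias))
  }

  say("intensity normalization (%s)", config$normalization)
  norm <- stage("normalize",
                normalize_intensity(corrected, mask, config$normalization))

  say("tissue segmentation (EM, prior weight %.2f)", config$seg$prior_weight)
  seg <- stage("tissue_seg",
               fit_tissue_model(norm$volume, atlas, mask, config$seg))
  say("EM finished after %d iterations", seg$n_iterations)

  say("ventricle identification")
  vent <- stage("ventricles", ventricle_mask(seg, atlas))
  say("centrum semiovale definition")
  cs <- stage("centrum_semiovale",
              centrum_semiovale_mask(seg, vent, config$dwma))
  say("DWMA detection (alpha %.2f, tau %.2f)",
      config$dwma$alpha, config$dwma$membership_threshold)
  res <- stage("dwma_quant", detect_dwma(norm$volume, seg, cs, config$dwma))
  say("DWMA: %d voxels, normalized volume %.5f", res$n_voxels,
      res$normalized_volume)

  out <- list(result = res, segmentation = seg, cs_mask = cs,
              ventricles = vent, bias = bias, normalized = norm$volume)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    vd <- volume$voxel_dims
    art <- c(field = file.path(out_dir, "bias_field.nii.gz"),
             seg = file.path(out_dir, "segmentation.nii.gz"),
             cs_mask = file.path(out_dir, "cs_mask.nii.gz"),
             dwma_mask = file.path(out_dir, "dwma_mask.nii.gz"),
             result = file.path(out_dir, "result.json"))
    bf <- if (is.null(bias)) array(1, dim(volume$data)) else bias$field
    write_volume(bf, art[["field"]], vd, datatype = "float64")
    write_volume(hard_labels(seg), art[["seg"]], vd, datatype = "uint8")
    write_volume(cs * 1L, art[["cs_mask"]], vd, datatype = "uint8")
    write_volume(res$mask * 1L, art[["dwma_mask"]], vd, datatype = "uint8")
    writeLines(dwma_result_json(res, config), art[["result"]])
    out$artifacts <- art
  }
  out
}

# Serialise the scalar part of a dwma_result together with the full
# configuration (provenance) as pretty JSON.
dwma_result_json <- function(res, config) {
  jsonlite::toJSON(list(
    n_voxels = res$n_voxels,
    volume_mm3 = res$volume_mm3,
    wm_volume_mm3 = res$wm_volume_mm3,
    normalized_volume = res$normalized_volume,
    cerebral_mean = res$cerebral_mean,
    cerebral_sd = res$cerebral_sd,
    threshold_used = res$threshold_used,
    voxel_dims = res$voxel_dims,
    config = config_as_list(config)
  ), auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Cohort prognostic report
#'
#' The statistical evaluation applied to a cohort table: univariate and
#' multivariable linear models of the Bayley Motor composite on normalized
#' DWMA volume (scaled per 10-percentage-point increase) with gestational
#' age and global abnormality score as co-predictors; logistic regression
#' of cerebral palsy on DWMA; severe-DWMA dichotomization at the 90th
#' percentile; and 2x2 prognostic properties of severe DWMA, of
#' moderate-or-worse global abnormality, and of visually classified severe
#' DWMA (grade 3) against cerebral palsy.
#'
#' @param cohort data.frame as from [make_cohort()].
#' @param percentile severe-DWMA percentile cut-off (default 90).
#' @return object of class `dwma_report`: lists `ols_univariate`,
#'   `ols_multivariable`, `logistic_cp`, `properties` (one
#'   `prognostic_properties` per predictor), `severe_cut`.
#' @export
cohort_report <- function(cohort, percentile = 90) {
  need <- c("ndwma", "bayley_motor", "cp", "gestational_age", "global_score",
            "visual_dwma_grade")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  x10 <- cohort$ndwma * 10
  uni <- ols_fit(cbind(dwma_per10pct = x10), cohort$bayley_motor)
  multi <- ols_fit(cbind(dwma_per10pct = x10,
                         gestational_age = cohort$gestational_age,
                         global_score = cohort$global_score),
                   cohort$bayley_motor)
  logit <- logistic_fit(cbind(dwma_per10pct = x10), cohort$cp)

  severe <- dichotomize_severe(cohort$ndwma, percentile)
  cat_global <- classify_global_abnormality(cohort$global_score)
  props <- list(
    severe_dwma = prognostic_properties(
      contingency_table(predictor = severe, outcome = cohort$cp == 1)),
    global_abnormality = prognostic_properties(
      contingency_table(predictor = cat_global %in% c("moderate", "severe"),
                        outcome = cohort$cp == 1)),
    visual_severe_dwma = prognostic_properties(
      contingency_table(predictor = cohort$visual_dwma_grade == 3,
                        outcome = cohort$cp == 1)))

  structure(list(ols_univariate = uni,
                 ols_multivariable = multi,
                 logistic_cp = logit,
                 properties = props,
                 severe_cut = stats::quantile(cohort$ndwma, percentile / 100,
                                              names = FALSE),
                 n = nrow(cohort)),
            class = "dwma_report")
}

#' @export
print.dwma_report <- function(x, ...) {
  cat(sprintf("DWMA prognostic report, n = %d\n\n", x$n))
  cat("Multivariable Bayley Motor model:\n")
  print(x$ols_multivariable)
  co <- x$logistic_cp$coefficients
  i <- co$term != "(Intercept)"
  cat(sprintf("\nCP odds ratio per 10%% DWMA increase: %.2f (%.2f, %.2f)\n",
              co$or[i][1], co$or_lower[i][1], co$or_upper[i][1]))
  for (nm in names(x$properties)) {
    cat("\n--", nm, "--\n")
    print(x$properties[[nm]])
  }
  invisible(x)
}
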