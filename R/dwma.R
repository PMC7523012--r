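#' Configuration of DWMA detection
#'
#' @param alpha cut-off threshold in SD multiples: a voxel is a DWMA
#'   candidate when its intensity exceeds mean + alpha x SD of cerebral
#'   (GM + WM) tissue. Default 1.8; 2.0 defines only very small regions
#'   and is offered for comparison.
#' @param membership_threshold partial-volume control tau: only voxels with
#'   tissue membership probability >= tau count (default 0.95).
#' @param min_component_voxels 26-connected components smaller than this
#'   are removed as isolated false positives (default 3), automating what
#'   is otherwise a manual clean-up of 2-8 voxel mislabels.
#' @param connectivity component connectivity, 26 (default) or 6.
#' @param midline_exclusion_voxels half-width (voxels) of a band around the
#'   mid-sagittal plane excluded from the centrum semiovale, where
#'   interhemispheric-fissure voxels are the commonest false positives
#'   (default 2).
#' @param cs_slices_above number of axial slices above the lateral
#'   ventricles that define the centrum semiovale (default 2).
#' @return object of class `dwma_config`.
#' @export
dwma_config <- function(alpha = 1.8, membership_threshold = 0.95,
                        min_component_voxels = 3, connectivity = 26,
                        midline_exclusion_voxels = 2, cs_slices_above = 2) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (membership_threshold <= 0 || membership_threshold >= 1)
    stop("membership_threshold must be in (0, 1)")
  if (min_component_voxels < 1) stop("min_component_voxels must be >= 1")
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  if (midline_exclusion_voxels < 0) stop("midline_exclusion_voxels must be >= 0")
  if (cs_slices_above < 1) stop("cs_slices_above must be >= 1")
  structure(list(alpha = alpha,
                 membership_threshold = membership_threshold,
                 min_component_voxels = as.integer(min_component_voxels),
                 connectivity = connectivity,
                 midline_exclusion_voxels = as.integer(midline_exclusion_voxels),
                 cs_slices_above = as.integer(cs_slices_above)),
            class = "dwma_config")
}

#' Mean and SD of cerebral-tissue intensity
#'
#' Computes the mean and population SD of intensities over voxels that are
#' confidently cerebral tissue: P(GM) >= tau or P(WM) >= tau. These set the
#' DWMA threshold mean + alpha x SD. The SD uses the population convention
#' (divisor n) for bit-reproducibility; the eligible set is large enough
#' that the choice is immaterial.
#'
#' @param volume preprocessed [brain_volume()].
#' @param seg a `tissue_segmentation`.
#' @param tau membership probability threshold (default 0.95).
#' @return named numeric vector `c(mean =, sd =, n =)`.
#' @export
cerebral_stats <- function(volume, seg, tau = 0.95) {
  eligible <- seg$posteriors[, , , "gm"] >= tau | seg$posteriors[, , , "wm"] >= tau
  n <- sum(eligible)
  if (n < 2) stop("fewer than 2 voxels with GM or WM membership >= ", tau)
  x <- volume$data[eligible]
  mu <- mean(x)
  sigma <- sqrt(sum((x - mu)^2) / n)
  c(mean = mu, sd = sigma, n = n)
}

#' Centrum semiovale mask
#'
#' Operationalizes the centrum semiovale as the central white matter of the
#' two axial slices immediately above the lateral ventricles: with k the
#' topmost slice containing a ventricle voxel, the mask is the WM-labelled
#' voxels on slices k+1 .. k+`cs_slices_above`, eroded in-plane by one
#' voxel (the "central" restriction), minus a band of
#' +/- `midline_exclusion_voxels` around the mid-sagittal plane.
#'
#' @param seg a `tissue_segmentation`.
#' @param ventricles logical array from [ventricle_mask()].
#' @param config a [dwma_config()].
#' @return logical 3D array.
#' @export
centrum_semiovale_mask <- function(seg, ventricles, config = dwma_config()) {
  if (!any(ventricles)) stop("ventricle mask is empty")
  d <- dim(ventricles)
  k <- max(which(apply(ventricles, 3, any)))
  top <- k + config$cs_slices_above
  if (top > d[3])
    stop("slices above the ventricles (", k + 1L, "..", top,
         ") exceed the grid (", d[3], " slices)")
  wm <- hard_labels(seg) == 3L
  wm <- erode_inplane(wm, 1)
  mask <- array(FALSE, d)
  mask[, , (k + 1L):top] <- wm[, , (k + 1L):top]
  if (config$midline_exclusion_voxels > 0) {
    mid <- (d[1] + 1) / 2
    band <- abs(seq_len(d[1]) - mid) <= config$midline_exclusion_voxels
    mask[band, , ] <- FALSE
  }
  if (!any(mask)) stop("centrum semiovale mask is empty")
  mask
}

#' Detect and quantify DWMA in the centrum semiovale
#'
#' Candidate voxels lie in the centrum semiovale, exceed the cut-off
#' threshold mean + alpha x SD of cerebral tissue (strict inequality), and
#' have white-matter membership probability >= tau (the centrum semiovale
#' is white matter by definition, while the threshold statistics pool GM
#' and WM). Components smaller than `min_component_voxels` under the
#' configured connectivity are then removed. An empty result is not an
#' error: a normalized DWMA volume of 0 is meaningful.
#'
#' @param volume preprocessed [brain_volume()].
#' @param seg a `tissue_segmentation`.
#' @param cs_mask logical array from [centrum_semiovale_mask()].
#' @param config a [dwma_config()].
#' @return object of class `dwma_result`: logical `mask`, `n_voxels`,
#'   `volume_mm3` (= n_voxels x voxel volume, exact), `wm_volume_mm3`
#'   (soft cerebral WM volume), `normalized_volume` (their ratio),
#'   `cerebral_mean`, `cerebral_sd`, `threshold_used`, `config`,
#'   `voxel_dims`.
#' @export
detect_dwma <- function(volume, seg, cs_mask, config = dwma_config()) {
  if (!any(cs_mask)) stop("centrum semiovale mask is empty")
  st <- cerebral_stats(volume, seg, config$membership_threshold)
  thr <- st[["mean"]] + config$alpha * st[["sd"]]
  cand <- cs_mask &
    volume$data > thr &
    seg$posteriors[, , , "wm"] >= config$membership_threshold
  mask <- filter_small_components(cand, config$min_component_voxels,
                                  config$connectivity)
  n <- sum(mask)
  vv <- prod(volume$voxel_dims)
  wm_vol <- tissue_volumes(seg, volume$voxel_dims)[["wm"]]
  structure(list(mask = mask,
                 n_voxels = n,
                 volume_mm3 = n * vv,
                 wm_volume_mm3 = wm_vol,
                 normalized_volume = if (n == 0) 0 else n * vv / wm_vol,
                 cerebral_mean = st[["mean"]],
                 cerebral_sd = st[["sd"]],
                 threshold_used = thr,
                 config = config,
                 voxel_dims = volume$voxel_dims),
            class = "dwma_result")
}

#' Normalized DWMA volume
#'
#' DWMA volume divided by total cerebral white matter volume: a unitless
#' fraction comparable across head sizes.
#'
#' @param result a `dwma_result`.
#' @return numeric scalar.
#' @export
normalized_dwma <- function(result) {
  if (!inherits(result, "dwma_result")) stop("`result` must be a dwma_result")
  if (result$wm_volume_mm3 <= 0) stop("white matter volume is zero")
  if (result$n_voxels == 0) return(0)
  result$volume_mm3 / result$wm_volume_mm3
}

#' @export
print.dwma_result <- function(x, ...) {
  cat("<dwma_result>\n")
  cat(sprintf("  DWMA voxels:        %d (%.2f mm^3)\n", x$n_voxels, x$volume_mm3))
  cat(sprintf("  cerebral WM volume: %.1f mm^3\n", x$wm_volume_mm3))
  cat(sprintf("  normalized DWMA:    %.5f\n", x$normalized_volume))
  cat(sprintf("  threshold:          %.3f (mean %.3f + %.2g x SD %.3f)\n",
              x$threshold_used, x$cerebral_mean, x$config$alpha, x$cerebral_sd))
  invisible(x)
}

#' @export
summary.dwma_result <- function(object, ...) {
  print(object)
  if (object$n_voxels > 0) {
    lab <- label_components(object$mask, object$config$connectivity)
    sizes <- tabulate(lab[lab > 0])
    cat(sprintf("  components:         %d (sizes %s)\n", length(sizes),
                paste(sort(sizes, decreasing = TRUE), collapse = ", ")))
  }
  invisible(object)
}
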