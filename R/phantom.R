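#' Specification of a synthetic T2-weighted phantom
#'
#' Defines the imaging conditions for a synthetic neonatal T2w volume:
#' grid geometry, per-tissue intensity statistics, injected DWMA lesions of
#' known location and size, a smooth multiplicative bias field, and additive
#' scanner noise. Defaults emulate term-equivalent-age T2w contrast, where
#' CSF is brightest, unmyelinated white matter is hyperintense to grey
#' matter, and the in-plane resolution is 0.93 x 0.93 mm with 1 mm slices.
#'
#' DWMA lesions are ellipsoids specified in mm (a sphere when one radius is
#' given); a voxel belongs to a lesion when its centre lies inside the
#' ellipsoid, so ground-truth voxel counts are integers. Lesion intensity is
#' offset from the WM mean in units of the WM standard deviation.
#'
#' @param grid_shape voxels per axis (default 96^3).
#' @param voxel_dims voxel dimensions in mm.
#' @param class_means named intensity means for background/csf/gm/wm
#'   (arbitrary units; default ordering CSF > WM > GM).
#' @param class_sds named per-tissue intensity SDs; these carry the full
#'   within-tissue voxel variability (biological texture plus thermal
#'   noise).
#' @param dwma_blobs list of lesions, each a list with `center` (voxel
#'   coordinates, 1-based), `radius_mm` (scalar or length-3 semi-axes) and
#'   `offset_sd` (> 0, WM-SD units).
#' @param bias_amplitude peak fractional deviation of the multiplicative
#'   bias field from 1 (default 0.2).
#' @param noise_sigma SD of a small additive noise floor applied after the
#'   bias field (background/quantization residue); the within-tissue noise
#'   itself lives in `class_sds`, so this stays well below them.
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param seed integer controlling all randomness in [make_phantom()].
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96),
                         voxel_dims = c(0.93, 0.93, 1.0),
                         class_means = c(background = 15, csf = 160, gm = 90, wm = 108),
                         class_sds = c(background = 2, csf = 6, gm = 5, wm = 5),
                         dwma_blobs = list(),
                         bias_amplitude = 0.2,
                         noise_sigma = 0.5,
                         noise_model = c("gaussian", "rician"),
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape <= 0)) stop("grid_shape must be positive")
  if (any(voxel_dims <= 0)) stop("voxel_dims must be positive")
  if (!all(TISSUE_NAMES %in% names(class_means)))
    stop("class_means must name all of: ", paste(TISSUE_NAMES, collapse = ", "))
  if (!all(TISSUE_NAMES %in% names(class_sds)))
    stop("class_sds must name all of: ", paste(TISSUE_NAMES, collapse = ", "))
  if (anyDuplicated(class_means[TISSUE_NAMES]))
    stop("class_means must be distinct")
  if (any(class_sds < 0)) stop("class_sds must be >= 0")
  if (bias_amplitude < 0) stop("bias_amplitude must be >= 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  for (b in dwma_blobs) {
    if (is.null(b$center) || is.null(b$radius_mm) || is.null(b$offset_sd))
      stop("each DWMA blob needs `center`, `radius_mm`, `offset_sd`")
    if (b$offset_sd <= 0) stop("DWMA blob intensity offset must be > 0")
  }
  structure(list(grid_shape = grid_shape,
                 voxel_dims = as.numeric(voxel_dims),
                 class_means = class_means[TISSUE_NAMES],
                 class_sds = class_sds[TISSUE_NAMES],
                 dwma_blobs = dwma_blobs,
                 bias_amplitude = bias_amplitude,
                 noise_sigma = noise_sigma,
                 noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Smooth multiplicative bias: a random full-quadratic polynomial in
# normalised coordinates, centred to mean 0 and scaled to peak amplitude
# `amplitude` over the brain, then shifted to 1.
make_true_bias <- function(grid_shape, brain, amplitude) {
  if (amplitude == 0) return(array(1, grid_shape))
  co <- lapply(1:3, function(ax) seq(-1, 1, length.out = grid_shape[ax]))
  u1 <- array(co[[1]], grid_shape)
  u2 <- array(rep(co[[2]], each = grid_shape[1]), grid_shape)
  u3 <- array(rep(co[[3]], each = grid_shape[1] * grid_shape[2]), grid_shape)
  cf <- stats::runif(9, -1, 1)
  g <- cf[1] * u1 + cf[2] * u2 + cf[3] * u3 +
    cf[4] * u1 * u2 + cf[5] * u1 * u3 + cf[6] * u2 * u3 +
    cf[7] * u1^2 + cf[8] * u2^2 + cf[9] * u3^2
  g <- g - mean(g[brain])
  peak <- max(abs(g[brain]))
  if (peak < .Machine$double.eps) return(array(1, grid_shape))
  1 + amplitude * g / peak
}

#' Generate a synthetic T2w phantom with known DWMA ground truth
#'
#' Tissue labels are the atlas argmax (deterministic given the atlas).
#' Voxel intensities are drawn per tissue as mean + N(0, sd); DWMA lesion
#' voxels use WM mean + `offset_sd` x WM sd as their mean. The volume is
#' then multiplied by a smooth bias field and corrupted by additive
#' (optionally Rician) noise. Everything injected is recorded in the
#' returned ground truth.
#'
#' @param spec a [phantom_spec()].
#' @param atlas a [make_atlas()] result on the same grid.
#' @return list with `volume` (a [brain_volume()]) and `truth` (class
#'   `phantom_truth`: `label_volume` with codes 0 background / 1 CSF /
#'   2 GM / 3 WM, logical `dwma_mask`, `bias_field`, and
#'   `dwma_true_volume_mm3` = voxel volume x number of lesion voxels).
#' @export
make_phantom <- function(spec, atlas) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  if (!inherits(atlas, "tissue_atlas")) stop("`atlas` must be a tissue_atlas")
  if (!identical(dim(atlas$prob)[1:3], spec$grid_shape))
    stop("atlas grid does not match spec grid")

  d <- spec$grid_shape
  lab <- atlas_hard_labels(atlas)

  dwma <- array(FALSE, d)
  offset_map <- array(0, d)
  for (i in seq_along(spec$dwma_blobs)) {
    b <- spec$dwma_blobs[[i]]
    ctr <- as.numeric(b$center)
    cl <- lab[ctr[1], ctr[2], ctr[3]]
    if (cl != tissue_code("wm"))
      stop(sprintf("DWMA blob %d: center (%g, %g, %g) is not in white matter (label %d)",
                   i, ctr[1], ctr[2], ctr[3], cl))
    semi <- rep(as.numeric(b$radius_mm), length.out = 3)
    co <- lapply(1:3, function(ax)
      ((seq_len(d[ax]) - ctr[ax]) * spec$voxel_dims[ax]) / semi[ax])
    q <- array(co[[1]], d)^2 +
      array(rep(co[[2]], each = d[1]), d)^2 +
      array(rep(co[[3]], each = d[1] * d[2]), d)^2
    inside <- q <= 1 & lab == tissue_code("wm")
    dwma <- dwma | inside
    offset_map[inside] <- b$offset_sd
  }

  vol <- with_seed(spec$seed, {
    n <- prod(d)
    mu <- spec$class_means[lab + 1L]
    sd <- spec$class_sds[lab + 1L]
    mu <- mu + offset_map * spec$class_sds[["wm"]]
    x <- array(stats::rnorm(n, mu, sd), d)
    brain <- lab != tissue_code("background")
    bias <- make_true_bias(d, brain, spec$bias_amplitude)
    x <- x * bias
    if (spec$noise_sigma > 0) {
      if (spec$noise_model == "rician") {
        x <- sqrt((x + stats::rnorm(n, 0, spec$noise_sigma))^2 +
                    stats::rnorm(n, 0, spec$noise_sigma)^2)
      } else {
        x <- x + stats::rnorm(n, 0, spec$noise_sigma)
      }
    }
    list(x = x, bias = bias)
  })

  truth <- structure(list(label_volume = lab,
                          dwma_mask = dwma,
                          bias_field = vol$bias,
                          dwma_true_volume_mm3 = sum(dwma) * prod(spec$voxel_dims)),
                     class = "phantom_truth")
  list(volume = brain_volume(vol$x, spec$voxel_dims), truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d DWMA voxels (%.2f mm^3), %d WM voxels\n",
              sum(x$dwma_mask), x$dwma_true_volume_mm3,
              sum(x$label_volume == tissue_code("wm"))))
  invisible(x)
}

#' Place a DWMA lesion inside the true centrum semiovale of an atlas
#'
#' Finds the topmost axial slice containing ventricle prior mass and returns
#' a blob specification centred between the two slices immediately above it.
#' The lesion is displaced laterally and anteriorly from the ventricle
#' column so it sits in central white matter where the atlas CSF prior is
#' negligible, and its vertical semi-axis defaults to 1.1 mm so it is
#' confined to those two slices (DWMA in the centrum semiovale is a thin
#' in-plane patch, which a sphere of equal volume cannot represent).
#'
#' @param atlas a `tissue_atlas`.
#' @param radius_mm in-plane semi-axis of the lesion (mm).
#' @param offset_sd lesion intensity offset in WM-SD units.
#' @param lateral_mm lateral displacement from the midline (mm).
#' @param anterior_mm anterior displacement from the grid centre (mm).
#' @param z_semi_mm vertical semi-axis (mm).
#' @return a blob list suitable for `dwma_blobs` in [phantom_spec()].
#' @export
cs_blob <- function(atlas, radius_mm = 4.2, offset_sd = 3,
                    lateral_mm = 9, anterior_mm = 15, z_semi_mm = 1.1) {
  d <- dim(atlas$prob)[1:3]
  # the topmost slice a segmentation faithful to the atlas labels will call
  # ventricle: argmax-CSF voxels carrying ventricle prior
  vent <- atlas_hard_labels(atlas) == tissue_code("csf") &
    atlas$ventricle_prior > 0.25
  if (!any(vent)) stop("atlas has no ventricle prior mass")
  k <- max(which(apply(vent, 3, any)))
  if (k + 2L > d[3]) stop("ventricle top too close to grid top")
  zc <- k + 1.5                       # midway between slices k+1 and k+2
  xc <- round(d[1] / 2 + lateral_mm / atlas$voxel_dims[1])
  yc <- round(d[2] / 2 + anterior_mm / atlas$voxel_dims[2])
  list(center = c(xc, yc, zc),
       radius_mm = c(radius_mm, radius_mm, z_semi_mm),
       offset_sd = offset_sd)
}
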