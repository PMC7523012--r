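#' @keywords internal
TISSUE_NAMES <- c("background", "csf", "gm", "wm")

# Integer label codes used everywhere: 0 background, 1 CSF, 2 GM, 3 WM.
tissue_code <- function(name) match(name, TISSUE_NAMES) - 1L

#' Synthetic neonatal probabilistic tissue atlas
#'
#' Builds a probabilistic atlas over \{background, CSF, GM, WM\} from a
#' nested-ellipsoid brain model: a thin outer CSF rim, a cortical GM ribbon,
#' a central WM core, and two ellipsoidal lateral ventricles (CSF) interior
#' to the WM. This is the simplest geometry that preserves the topological
#' facts the quantification pipeline relies on: ventricles are surrounded by
#' white matter, cortex is exterior to it, and there are axial white-matter
#' slices immediately above the ventricles (the centrum semiovale).
#'
#' Hard indicator maps of the geometry are blurred with an isotropic
#' Gaussian of FWHM-equivalent `smoothing_mm` (interpreted as the standard
#' deviation in mm) and renormalised, yielding soft priors near tissue
#' boundaries. A separate ventricle prior channel (the blurred ventricle
#' indicator) supports ventricle identification downstream.
#'
#' @param grid_shape integer length-3, voxels per axis (each >= 32).
#' @param voxel_dims voxel dimensions in mm; default 0.93 x 0.93 x 1.0.
#' @param smoothing_mm Gaussian sigma (mm) applied to the indicator maps;
#'   0 gives hard 0/1 priors.
#' @param seed optional integer; when given, ellipsoid semi-axes are jittered
#'   by up to +/-4% so repeated calls emulate anatomical variability across
#'   subjects.
#' @return object of class `tissue_atlas`: list with `prob` (4D array,
#'   fourth axis ordered background/CSF/GM/WM, summing to 1 at every voxel),
#'   `ventricle_prior` (3D array in \[0,1\]), `voxel_dims`, `smoothing_mm`.
#' @export
make_atlas <- function(grid_shape = c(96, 96, 96),
                       voxel_dims = c(0.93, 0.93, 1.0),
                       smoothing_mm = 2,
                       seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 32L))
    stop("grid too small: need at least 32 voxels per axis to contain the brain model")
  if (any(voxel_dims <= 0)) stop("voxel_dims must be positive")
  if (smoothing_mm < 0) stop("smoothing_mm must be >= 0")

  jitter <- c(1, 1, 1)
  vjitter <- c(1, 1, 1)
  if (!is.null(seed)) {
    jitter <- with_seed(seed, 1 + 0.04 * stats::runif(3, -1, 1))
    vjitter <- with_seed(seed + 1L, 1 + 0.06 * stats::runif(3, -1, 1))
  }

  extent <- grid_shape * voxel_dims
  centre <- extent / 2
  semi <- 0.42 * extent * jitter            # outer brain semi-axes (mm)

  # voxel-centre coordinates in mm, normalised to the brain ellipsoid
  co <- lapply(1:3, function(ax) ((seq_len(grid_shape[ax]) - 0.5) * voxel_dims[ax] -
                                    centre[ax]) / semi[ax])
  u1 <- array(co[[1]], grid_shape)
  u2 <- array(rep(co[[2]], each = grid_shape[1]), grid_shape)
  u3 <- array(rep(co[[3]], each = grid_shape[1] * grid_shape[2]), grid_shape)
  rho2 <- u1^2 + u2^2 + u3^2

  # radial shells: CSF rim, cortical ribbon, WM core. The ribbon/core split
  # (0.73) gives a cerebral GM:WM volume ratio near 1:1, in line with
  # term-equivalent-age morphometry.
  lab <- array(0L, grid_shape)
  lab[rho2 <= 1] <- tissue_code("csf")      # outer CSF rim
  lab[rho2 <= 0.92^2] <- tissue_code("gm")  # cortical ribbon
  lab[rho2 <= 0.73^2] <- tissue_code("wm")  # central white matter

  # two lateral ventricles, fully interior to the WM core and centred on the
  # equatorial plane, so the two slices immediately above them cut the WM
  # core where it is wide (the centrum semiovale). The fourth power in z
  # gives the ventricle body a blunt superior surface, as in the real
  # anatomy, which makes the "topmost ventricle slice" well defined.
  vsemi <- c(0.10, 0.18, 0.30) * vjitter
  vcent <- list(c(-0.22, 0.02, 0), c(0.22, 0.02, 0))
  vent <- array(FALSE, grid_shape)
  for (vc in vcent) {
    q <- ((u1 - vc[1]) / vsemi[1])^2 + ((u2 - vc[2]) / vsemi[2])^2 +
      ((u3 - vc[3]) / vsemi[3])^4
    vent <- vent | (q <= 1)
  }
  lab[vent] <- tissue_code("csf")

  prob <- array(0, c(grid_shape, 4L))
  for (k in 0:3) prob[, , , k + 1L][lab == k] <- 1
  vprior <- vent * 1.0

  if (smoothing_mm > 0) {
    sig <- smoothing_mm / voxel_dims
    for (k in 1:4) prob[, , , k] <- smooth_gaussian(prob[, , , k], sig)
    tot <- prob[, , , 1] + prob[, , , 2] + prob[, , , 3] + prob[, , , 4]
    for (k in 1:4) prob[, , , k] <- prob[, , , k] / tot
    vprior <- smooth_gaussian(vprior, sig)
  }
  dimnames(prob) <- list(NULL, NULL, NULL, TISSUE_NAMES)

  structure(list(prob = prob,
                 ventricle_prior = vprior,
                 voxel_dims = as.numeric(voxel_dims),
                 smoothing_mm = smoothing_mm),
            class = "tissue_atlas")
}

#' @export
print.tissue_atlas <- function(x, ...) {
  d <- dim(x$prob)
  cat(sprintf("<tissue_atlas> %d x %d x %d voxels, classes: %s\n",
              d[1], d[2], d[3], paste(TISSUE_NAMES, collapse = ", ")))
  cat(sprintf("  voxel dims %.3g x %.3g x %.3g mm, smoothing %.3g mm\n",
              x$voxel_dims[1], x$voxel_dims[2], x$voxel_dims[3], x$smoothing_mm))
  invisible(x)
}

# Hard (argmax) atlas labels with ties resolved in class-code order.
atlas_hard_labels <- function(atlas) {
  p <- atlas$prob
  d <- dim(p)[1:3]
  lab <- array(0L, d)
  best <- p[, , , 1]
  for (k in 2:4) {
    better <- p[, , , k] > best
    lab[better] <- k - 1L
    best[better] <- p[, , , k][better]
  }
  lab
}

#' Write / read a tissue atlas as 4D NIfTI
#'
#' The atlas is stored as a single 4D NIfTI file with five channels:
#' background, CSF, GM, WM probabilities followed by the ventricle prior.
#'
#' @param atlas a `tissue_atlas`.
#' @param path output `.nii.gz` path.
#' @return `path` (write) or a `tissue_atlas` (read).
#' @export
write_atlas <- function(atlas, path) {
  d <- dim(atlas$prob)
  arr <- array(0, c(d[1:3], 5L))
  arr[, , , 1:4] <- atlas$prob
  arr[, , , 5] <- atlas$ventricle_prior
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(atlas$voxel_dims, 1)
  RNifti::writeNifti(img, path, datatype = "float64")
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 5L)
    stop("expected a 4D atlas file with 5 channels: ", path)
  arr <- array(as.numeric(img), d)
  prob <- arr[, , , 1:4, drop = FALSE]
  dimnames(prob) <- list(NULL, NULL, NULL, TISSUE_NAMES)
  structure(list(prob = prob,
                 ventricle_prior = arr[, , , 5],
                 voxel_dims = RNifti::pixdim(img)[1:3],
                 smoothing_mm = NA_real_),
            class = "tissue_atlas")
}

# Evaluate an expression with a temporary RNG state seeded at `seed`.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
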