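#' Brain mask from a probabilistic atlas
#'
#' A voxel enters the mask when its combined brain-tissue prior
#' P(CSF) + P(GM) + P(WM) reaches `threshold`; the mask is then reduced to
#' its largest 26-connected component.
#'
#' @param atlas a `tissue_atlas`.
#' @param threshold probability in (0, 1); default 0.5.
#' @return logical 3D array.
#' @export
brain_mask_from_atlas <- function(atlas, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  p <- atlas$prob
  brain <- p[, , , "csf"] + p[, , , "gm"] + p[, , , "wm"] >= threshold
  if (!any(brain)) stop("brain mask is empty at threshold ", threshold)
  largest_component(brain, 26)
}

# Polynomial design matrix in coordinates normalised to [-1, 1] per axis,
# all monomials of total degree <= order (including the constant).
poly_design <- function(idx, grid_shape, order) {
  u <- lapply(1:3, function(ax) {
    n <- grid_shape[ax]
    if (n > 1) 2 * (idx[, ax] - 1) / (n - 1) - 1 else rep(0, nrow(idx))
  })
  cols <- list(rep(1, nrow(idx)))
  nm <- "1"
  for (i in 0:order) for (j in 0:(order - i)) for (k in 0:(order - i - j)) {
    if (i + j + k == 0) next
    cols[[length(cols) + 1L]] <- u[[1]]^i * u[[2]]^j * u[[3]]^k
    nm <- c(nm, sprintf("x%dy%dz%d", i, j, k))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- nm
  X
}

#' Estimate a multiplicative bias field
#'
#' Fits a low-order 3D polynomial to log-intensities inside the mask by
#' least squares and exponentiates the fitted smooth part, giving a
#' positive multiplicative field gauge-fixed to mean 1 over the mask.
#' Smoothness is the only property assumed of the true inhomogeneity.
#'
#' When an `atlas` is supplied, tissue contrast is modelled jointly with
#' the field: per-tissue intercepts (most probable atlas tissue per voxel)
#' enter the least-squares design alongside the polynomial, so the
#' polynomial captures the smooth inhomogeneity and the intercepts the
#' anatomy. Without an atlas the polynomial is fitted to the raw
#' log-intensities, which is adequate only when tissue contrast is small
#' relative to the bias.
#'
#' Non-positive intensities inside the mask (possible after noise) are
#' clamped to the smallest positive masked intensity so the log transform
#' is defined everywhere.
#'
#' @param volume a [brain_volume()].
#' @param mask logical array: voxels used for the fit (and corrected by
#'   [correct_bias()]).
#' @param order total polynomial degree (default 3).
#' @param atlas optional `tissue_atlas` for anatomy adjustment.
#' @return object of class `bias_field`: list with `field` (3D array,
#'   1 outside the mask), `order`, `mask_used`.
#' @export
estimate_bias_field <- function(volume, mask, order = 3, atlas = NULL) {
  if (!inherits(volume, "brain_volume")) stop("`volume` must be a brain_volume")
  d <- dim(volume$data)
  if (!identical(dim(mask), d)) stop("mask shape does not match volume")
  if (!any(mask)) stop("mask is empty")
  x <- volume$data[mask]
  if (any(x <= 0)) {
    pos <- x[x > 0]
    if (length(pos) == 0) stop("no positive intensities inside mask; log fit undefined")
    x[x <= 0] <- min(pos)
  }
  lx <- log(x)

  idx <- which(mask, arr.ind = TRUE)
  X <- poly_design(idx, d, order)

  if (!is.null(atlas)) {
    # joint anatomy + inhomogeneity model: tissue-group intercepts (most
    # probable atlas tissue per voxel) alongside the polynomial, so the
    # polynomial captures the smooth field and the dummies the contrast
    g <- factor(atlas_hard_labels(atlas)[mask])
    if (nlevels(g) > 1) {
      G <- stats::model.matrix(~ g)[, -1, drop = FALSE]
      fit <- stats::lm.fit(cbind(X, G), lx)
      lfield <- as.vector(X %*% fit$coefficients[seq_len(ncol(X))])
    } else {
      fit <- stats::lm.fit(X, lx)
      lfield <- as.vector(X %*% fit$coefficients)
    }
  } else {
    fit <- stats::lm.fit(X, lx)
    lfield <- as.vector(X %*% fit$coefficients)
  }

  field <- array(1, d)
  field[mask] <- exp(lfield)
  field[mask] <- field[mask] / mean(field[mask])
  structure(list(field = field, order = order, mask_used = mask),
            class = "bias_field")
}

#' @export
print.bias_field <- function(x, ...) {
  f <- x$field[x$mask_used]
  cat(sprintf("<bias_field> order %d, range [%.4f, %.4f] over %d masked voxels\n",
              x$order, min(f), max(f), sum(x$mask_used)))
  invisible(x)
}

#' Divide out an estimated bias field
#'
#' Output equals input / field inside the estimation mask and is left
#' unchanged outside; voxel dimensions are preserved. Because the field has
#' mean 1 over the mask, global brightness is approximately conserved.
#'
#' @param volume a [brain_volume()].
#' @param field a [estimate_bias_field()] result.
#' @return corrected [brain_volume()].
#' @export
correct_bias <- function(volume, field) {
  if (!inherits(field, "bias_field")) stop("`field` must be a bias_field")
  if (!identical(dim(volume$data), dim(field$field)))
    stop("volume and field shapes differ")
  out <- volume$data
  m <- field$mask_used
  out[m] <- out[m] / field$field[m]
  brain_volume(out, volume$voxel_dims)
}

#' Robust intensity normalization
#'
#' `median_iqr` (default) maps the masked median to 1000 and the masked
#' inter-quartile range to 100: out = (in - median) / IQR * 100 + 1000.
#' `zscore` uses mean/SD with the same anchors. Both are invertible through
#' the returned parameters and equivariant under positive affine intensity
#' maps, which is what makes the downstream SD-threshold DWMA rule
#' invariant to scanner scaling.
#'
#' @param volume a [brain_volume()].
#' @param mask logical array defining the reference region.
#' @param method `"median_iqr"` or `"zscore"`.
#' @return list with `volume` (normalized) and `params` (class
#'   `normalization_params`: `center`, `scale`, `method`).
#' @export
normalize_intensity <- function(volume, mask, method = c("median_iqr", "zscore")) {
  method <- match.arg(method)
  if (!any(mask)) stop("mask is empty")
  x <- volume$data[mask]
  if (method == "median_iqr") {
    center <- stats::median(x)
    scale <- stats::IQR(x, type = 7)
    if (scale == 0) stop("IQR of masked intensities is 0; cannot normalize")
  } else {
    center <- mean(x)
    scale <- stats::sd(x)
    if (scale == 0) stop("SD of masked intensities is 0; cannot normalize")
  }
  out <- (volume$data - center) / scale * 100 + 1000
  params <- structure(list(center = center, scale = scale, method = method),
                      class = "normalization_params")
  list(volume = brain_volume(out, volume$voxel_dims), params = params)
}

#' Invert an intensity normalization
#' @param volume normalized [brain_volume()].
#' @param params `normalization_params` from [normalize_intensity()].
#' @return [brain_volume()] on the original intensity scale.
#' @export
denormalize_intensity <- function(volume, params) {
  out <- (volume$data - 1000) / 100 * params$scale + params$center
  brain_volume(out, volume$voxel_dims)
}
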