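#' Configuration for atlas-guided tissue segmentation
#'
#' @param max_iter maximum EM iterations (default 100).
#' @param tol relative change in observed-data log-likelihood below which
#'   EM is declared converged (default 1e-5).
#' @param prior_weight weight in \[0,1\] blending the atlas prior with a
#'   uniform prior over the three tissue classes:
#'   pi' = w * pi_atlas + (1 - w)/3. The default 1 is pure atlas guidance.
#' @param membership_threshold partial-volume control: the probability a
#'   voxel must reach to count as a single tissue (default 0.95).
#' @return object of class `seg_config`.
#' @export
seg_config <- function(max_iter = 100, tol = 1e-5, prior_weight = 1,
                       membership_threshold = 0.95) {
  if (tol <= 0) stop("tol must be > 0")
  if (prior_weight < 0 || prior_weight > 1) stop("prior_weight must be in [0, 1]")
  if (membership_threshold <= 0 || membership_threshold >= 1)
    stop("membership_threshold must be in (0, 1)")
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 prior_weight = prior_weight,
                 membership_threshold = membership_threshold),
            class = "seg_config")
}

#' Atlas-guided EM segmentation into CSF / GM / WM
#'
#' Fits a three-class Gaussian mixture to the masked intensities with
#' voxelwise atlas priors: the E-step posterior is proportional to
#' prior x Gaussian likelihood, and the M-step re-estimates each class
#' mean and SD from posterior-weighted intensities. Initialization uses
#' atlas-prior-weighted moments, so the fit is deterministic, and because
#' means and SDs are re-estimated each step the segmentation is invariant
#' to positive affine intensity transforms of the input. The observed-data
#' log-likelihood is non-decreasing across iterations (EM ascent).
#'
#' Voxels whose atlas prior for a class is exactly zero keep zero posterior
#' for that class regardless of intensity.
#'
#' @param volume preprocessed [brain_volume()].
#' @param atlas co-registered `tissue_atlas`.
#' @param mask logical array of brain voxels to segment.
#' @param config a [seg_config()].
#' @return object of class `tissue_segmentation`: `posteriors` (4D array,
#'   fourth axis csf/gm/wm, zero outside the mask), `mask`, `class_means`,
#'   `class_sds`, `n_iterations`, `converged`, `loglik` (per-iteration
#'   trace), `voxel_dims`.
#' @export
fit_tissue_model <- function(volume, atlas, mask, config = seg_config()) {
  if (!inherits(volume, "brain_volume")) stop("`volume` must be a brain_volume")
  d <- dim(volume$data)
  if (!identical(dim(atlas$prob)[1:3], d)) stop("atlas grid does not match volume")
  if (!identical(dim(mask), d)) stop("mask shape does not match volume")
  if (!any(mask)) stop("mask is empty")

  x <- volume$data[mask]
  n <- length(x)
  pr <- matrix(0, n, 3)
  for (k in 1:3) pr[, k] <- atlas$prob[, , , k + 1L][mask]
  rs <- rowSums(pr)
  pr[rs == 0, ] <- 1 / 3
  pr <- pr / rowSums(pr)
  w <- config$prior_weight
  pr <- w * pr + (1 - w) / 3

  # deterministic init: prior-weighted moments
  cs <- colSums(pr)
  mu <- colSums(pr * x) / cs
  s2 <- colSums(pr * (outer(x, mu, "-")^2)) / cs
  sd_ <- pmax(sqrt(s2), 1e-6)

  ll_trace <- numeric(0)
  converged <- FALSE
  post <- pr
  it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    a <- log(pr)                      # -Inf where the prior is exactly 0
    for (k in 1:3) a[, k] <- a[, k] + stats::dnorm(x, mu[k], sd_[k], log = TRUE)
    amax <- pmax(a[, 1], a[, 2], a[, 3])
    e <- exp(a - amax)
    tot <- rowSums(e)
    post <- e / tot
    ll <- sum(amax + log(tot))
    ll_trace <- c(ll_trace, ll)

    cs <- colSums(post)
    if (any(cs < 10))
      stop("tissue class collapsed during EM: ",
           paste(c("csf", "gm", "wm")[cs < 10], collapse = ", "),
           " has posterior mass below 10 voxels")
    mu <- colSums(post * x) / cs
    s2 <- colSums(post * (x - matrix(mu, n, 3, byrow = TRUE))^2) / cs
    sd_ <- pmax(sqrt(s2), 1e-6)

    if (it >= 2) {
      rel <- abs(ll - ll_trace[it - 1]) / (abs(ll_trace[it - 1]) + .Machine$double.eps)
      if (rel < config$tol) { converged <- TRUE; break }
    }
  }
  if (!converged)
    warning("EM did not converge within ", config$max_iter, " iterations")

  posteriors <- array(0, c(d, 3L))
  for (k in 1:3) {
    tmp <- array(0, d)
    tmp[mask] <- post[, k]
    posteriors[, , , k] <- tmp
  }
  dimnames(posteriors) <- list(NULL, NULL, NULL, c("csf", "gm", "wm"))

  structure(list(posteriors = posteriors,
                 mask = mask,
                 class_means = stats::setNames(mu, c("csf", "gm", "wm")),
                 class_sds = stats::setNames(sd_, c("csf", "gm", "wm")),
                 n_iterations = it,
                 converged = converged,
                 loglik = ll_trace,
                 voxel_dims = volume$voxel_dims),
            class = "tissue_segmentation")
}

#' @export
print.tissue_segmentation <- function(x, ...) {
  cat(sprintf("<tissue_segmentation> %d masked voxels, %d EM iterations (%s)\n",
              sum(x$mask), x$n_iterations,
              if (x$converged) "converged" else "not converged"))
  m <- rbind(mean = x$class_means, sd = x$class_sds)
  print(round(m, 2))
  invisible(x)
}

#' @export
summary.tissue_segmentation <- function(object, ...) {
  vols <- tissue_volumes(object)
  cat("Atlas-guided EM tissue segmentation\n")
  print(object)
  cat("soft tissue volumes (mm^3):\n")
  print(round(vols, 1))
  invisible(list(volumes = vols, means = object$class_means,
                 sds = object$class_sds))
}

#' Hard tissue labels from posteriors
#'
#' Per-voxel argmax of the CSF/GM/WM posteriors; exact ties resolve in the
#' fixed class order CSF < GM < WM. Voxels outside the segmentation mask
#' get 0 (background).
#'
#' @param seg a `tissue_segmentation`.
#' @return integer array with codes 0 background, 1 CSF, 2 GM, 3 WM.
#' @export
hard_labels <- function(seg) {
  p1 <- seg$posteriors[, , , 1]
  p2 <- seg$posteriors[, , , 2]
  p3 <- seg$posteriors[, , , 3]
  m <- pmax(p1, p2, p3)
  lab <- array(3L, dim(p1))
  lab[p2 >= p3] <- 2L
  lab[p1 >= pmax(p2, p3)] <- 1L
  lab[!seg$mask] <- 0L
  lab
}

#' Soft tissue volumes in mm^3
#'
#' Volume of each class as voxel volume times the sum of its posterior
#' probabilities over the mask (a soft count); `hard = TRUE` counts argmax
#' labels instead.
#'
#' @param seg a `tissue_segmentation`.
#' @param voxel_dims voxel dims (mm); defaults to those stored in `seg`.
#' @param hard use hard-label counts instead of posterior sums.
#' @return named numeric vector `csf`, `gm`, `wm` (mm^3).
#' @export
tissue_volumes <- function(seg, voxel_dims = seg$voxel_dims, hard = FALSE) {
  vv <- prod(voxel_dims)
  if (hard) {
    lab <- hard_labels(seg)
    counts <- vapply(1:3, function(k) sum(lab == k), numeric(1))
  } else {
    counts <- vapply(1:3, function(k) sum(seg$posteriors[, , , k]), numeric(1))
  }
  stats::setNames(counts * vv, c("csf", "gm", "wm"))
}

#' Identify the lateral ventricles
#'
#' CSF-labelled 26-connected components are matched against the atlas
#' ventricle prior: a component qualifies when more than half of its voxels
#' sit on prior >= 0.5. The union of qualifying components is returned;
#' the external CSF rim never qualifies because it carries no ventricle
#' prior.
#'
#' @param seg a `tissue_segmentation`.
#' @param atlas the `tissue_atlas` used for segmentation.
#' @return logical 3D array of ventricle voxels.
#' @export
ventricle_mask <- function(seg, atlas) {
  if (!any(atlas$ventricle_prior >= 0.5))
    stop("ventricles not found: atlas has no ventricle prior mass")
  lab <- hard_labels(seg)
  csf <- lab == 1L
  comp <- label_components(csf, 26)
  ncomp <- max(comp)
  if (ncomp == 0L) stop("ventricles not found: no CSF component")
  vp <- atlas$ventricle_prior >= 0.5
  out <- array(FALSE, dim(csf))
  found <- FALSE
  for (id in seq_len(ncomp)) {
    inside <- comp == id
    if (mean(vp[inside]) > 0.5) {
      out <- out | inside
      found <- TRUE
    }
  }
  if (!found) stop("ventricles not found: no CSF component overlaps the ventricle prior")
  out
}
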