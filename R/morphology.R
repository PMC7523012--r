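# Binary 3D morphology: connected components, in-plane erosion, smoothing.
# Components use padded linear indexing so neighbour offsets never wrap.

neighbour_offsets <- function(dims_padded, connectivity = 26) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6) {
    off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  } else if (connectivity != 26) {
    stop("connectivity must be 6 or 26")
  }
  off[, 1] + off[, 2] * dims_padded[1] + off[, 3] * dims_padded[1] * dims_padded[2]
}

#' Label connected components of a 3D binary mask
#'
#' Breadth-first labelling under 6- or 26-neighbour connectivity. Labels are
#' assigned in first-encounter (column-major) order starting at 1;
#' out-of-mask voxels get 0.
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return integer array of component labels, same shape as `mask`.
#' @export
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  if (length(d) != 3L) stop("`mask` must be a 3D array")
  dp <- d + 2L
  mp <- array(FALSE, dp)
  mp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.logical(mask)
  loff <- neighbour_offsets(dp, connectivity)
  lab <- array(0L, dp)
  todo <- which(mp)
  next_id <- 0L
  for (s in todo) {
    if (lab[s] > 0L) next
    next_id <- next_id + 1L
    lab[s] <- next_id
    frontier <- s
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, loff, `+`)))
      nb <- nb[mp[nb] & lab[nb] == 0L]
      lab[nb] <- next_id
      frontier <- nb
    }
  }
  array(lab[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)], d)
}

#' Keep the largest connected component of a mask
#' @param mask logical 3D array.
#' @param connectivity 6 or 26.
#' @return logical array containing only the largest component.
#' @export
largest_component <- function(mask, connectivity = 26) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# Drop 26-connected components smaller than `min_voxels`.
filter_small_components <- function(mask, min_voxels, connectivity = 26) {
  if (min_voxels <= 1L || !any(mask)) return(mask)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_voxels)
  array(lab %in% keep, dim(mask))
}

# In-plane (axial, 8-neighbour) binary erosion: a voxel survives iff its full
# 3x3 in-plane neighbourhood is in the mask. Slice borders erode.
erode_inplane <- function(mask, iterations = 1) {
  d <- dim(mask)
  m <- as.array(mask)
  for (it in seq_len(iterations)) {
    mp <- array(FALSE, d + c(2L, 2L, 0L))
    mp[2:(d[1] + 1), 2:(d[2] + 1), ] <- m
    out <- array(TRUE, d)
    for (dx in -1:1) for (dy in -1:1) {
      out <- out & mp[(2 + dx):(d[1] + 1 + dx), (2 + dy):(d[2] + 1 + dy), , drop = FALSE]
    }
    m <- out
  }
  m
}

# Separable Gaussian smoothing with sigma given in voxels per axis.
# Truncated at 3 sigma; rows renormalised so flat fields stay flat at borders.
smooth_gaussian <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    n <- d[ax]
    idx <- seq_len(n)
    K <- outer(idx, idx, function(i, j) {
      w <- exp(-((i - j)^2) / (2 * s^2))
      w * (abs(i - j) <= r)
    })
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    dd <- dim(a)
    a <- array(K %*% matrix(a, nrow = n), dd)
    arr <- aperm(a, order(perm))
  }
  arr
}
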