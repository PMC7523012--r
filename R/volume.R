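#' 3D brain volume container
#'
#' A minimal container for a 3D scalar image: a numeric array plus voxel
#' dimensions in millimetres. All internal processing assumes the array is in
#' RAS+ order (first axis left-to-right, second posterior-to-anterior, third
#' inferior-to-superior), so that "above" always means increasing index along
#' the third (axial) axis. [read_volume()] reorients files to this convention
#' on load.
#'
#' @param data numeric 3D array of intensities.
#' @param voxel_dims numeric length-3 vector of voxel edge lengths (mm).
#' @return An object of class `brain_volume`: a list with elements `data`
#'   and `voxel_dims`.
#' @export
brain_volume <- function(data, voxel_dims = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  voxel_dims <- as.numeric(voxel_dims)
  if (length(voxel_dims) != 3L || any(!is.finite(voxel_dims)) || any(voxel_dims <= 0))
    stop("`voxel_dims` must be 3 positive numbers (mm)")
  structure(list(data = data, voxel_dims = voxel_dims), class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<brain_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$voxel_dims[1], x$voxel_dims[2], x$voxel_dims[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.brain_volume <- function(x) dim(x$data)

#' Volume of a single voxel in mm^3
#' @param x a `brain_volume` or a numeric length-3 vector of voxel dims.
#' @return voxel volume in mm^3.
#' @export
voxel_volume <- function(x) {
  if (inherits(x, "brain_volume")) prod(x$voxel_dims) else prod(as.numeric(x))
}

#' Read a 3D NIfTI volume, reorienting to RAS+
#'
#' Loads a NIfTI-1 file, checks that it is 3D and carries orientation
#' information, and reorients the data to canonical RAS+ axis order so that
#' the third array axis runs inferior-to-superior.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [brain_volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D volume, got ", length(dim(img)), "D: ", path)
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code == 0L && hdr$sform_code == 0L)
    stop("volume has no orientation information (qform and sform codes are 0): ",
         path)
  ori <- RNifti::orientation(img)
  if (ori != "RAS") {
    RNifti::orientation(img) <- "RAS"
    message("reoriented ", ori, " -> RAS: ", path)
  }
  brain_volume(array(as.numeric(img), dim(img)), RNifti::pixdim(img))
}

#' Write a 3D volume as NIfTI-1
#'
#' Writes in RAS+ orientation with a diagonal sform built from the voxel
#' dimensions. Masks and label maps are best written with an integer
#' `datatype` so that a write/read round trip is bitwise exact.
#'
#' @param volume a [brain_volume()] or a 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_dims voxel dims, required when `volume` is a bare array.
#' @param datatype NIfTI storage type passed to [RNifti::writeNifti()]
#'   (e.g. `"uint8"` for masks, `"float64"` for intensities).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, voxel_dims = NULL, datatype = "float64") {
  if (inherits(volume, "brain_volume")) {
    arr <- volume$data
    voxel_dims <- volume$voxel_dims
  } else {
    arr <- volume
    if (is.null(voxel_dims)) stop("`voxel_dims` required for a bare array")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_dims
  m <- diag(c(voxel_dims, 1))
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
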