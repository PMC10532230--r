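#' Construct a 3D intensity volume
#'
#' A `Volume` is the package's core container: a 3D array of scalar
#' intensities (Hounsfield units for CT, arbitrary units for MRI) paired
#' with the physical voxel spacing in millimetres along each grid axis.
#' The three axes are treated abstractly as (axis1, axis2, axis3), matched
#' positionally with `spacing`; no anatomical reorientation is performed,
#' since every downstream computation uses only intensities and spacing.
#'
#' @param data numeric 3D array of intensities. All values must be finite.
#' @param spacing numeric length-3 vector of mm-per-voxel, strictly positive.
#' @return An object of class `ihf_volume` with fields `data` and `spacing`.
#' @examples
#' v <- volume(array(rnorm(60), dim = c(5, 4, 3)), spacing = c(1, 1, 1.5))
#' dim(v$data)
#' @export
volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("unsupported dimensionality: 'data' must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive finite values (mm)")
  if (any(!is.finite(data)))
    stop("corrupt input: volume contains non-finite intensities")
  structure(list(data = data, spacing = spacing), class = "ihf_volume")
}

#' Construct a binary mask volume
#'
#' A `MaskVolume` holds a binary occupancy grid (e.g. a segmentation
#' prediction) with the same axis and spacing conventions as [volume()].
#'
#' @param data 3D array whose values are exactly 0 or 1.
#' @param spacing mm-per-voxel triple, as in [volume()].
#' @return An object of class `ihf_mask`.
#' @export
mask_volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("unsupported dimensionality: mask must be a 3D array")
  if (any(!is.finite(data)))
    stop("corrupt input: mask contains non-finite values")
  if (!all(data %in% c(0, 1)))
    stop("mask values must be exactly 0 or 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive finite values (mm)")
  structure(list(data = data, spacing = spacing), class = "ihf_mask")
}

#' @export
print.ihf_volume <- function(x, ...) {
  cat(sprintf("<Volume %s, spacing %s mm, range [%.4g, %.4g]>\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.ihf_mask <- function(x, ...) {
  cat(sprintf("<MaskVolume %s, spacing %s mm, %d foreground voxels>\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              sum(x$data == 1)))
  invisible(x)
}

is_volume <- function(x) inherits(x, "ihf_volume")
is_mask <- function(x) inherits(x, "ihf_mask")

#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file (.nii or .nii.gz) into a [volume()]. Voxel spacing
#' is taken from the header `pixdim`; intensities are passed through
#' unmodified. Orientation and origin information beyond spacing is ignored
#' by all computation in this package.
#'
#' @param path path to a 3D NIfTI file.
#' @return A `Volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("unsupported dimensionality: expected a 3D image, got ", length(d), "D")
  sp <- abs(RNifti::pixdim(img))[seq_len(3)]
  volume(array(as.numeric(img), dim = d), spacing = sp)
}

#' Write a volume or mask to NIfTI
#'
#' Writes `data` and `spacing` to a NIfTI-1 file; a subsequent
#' [read_volume()] / [read_mask()] recovers both (up to header float
#' precision for spacing).
#'
#' @param v a `Volume` or `MaskVolume`.
#' @param path destination path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(is_volume(v) || is_mask(v))
  if (!dir.exists(dirname(path)))
    stop("cannot write '", path, "': directory does not exist")
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' Values must be in \{0, 1\}; anything else within (0, 1) range tolerance
#' is binarised at 0.5 with a warning, and clearly non-binary data is an
#' error.
#'
#' @param path path to a 3D NIfTI mask.
#' @return A `MaskVolume`.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  x <- v$data
  if (!all(x %in% c(0, 1))) {
    if (any(x < -1e-6) || any(x > 1 + 1e-6))
      stop("mask file contains values outside [0, 1]; not binarisable")
    warning("mask contains non-binary values; binarising at 0.5")
    x <- array(as.numeric(x > 0.5), dim = dim(x))
  } else {
    x <- array(as.numeric(x), dim = dim(x))
  }
  mask_volume(x, spacing = v$spacing)
}
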