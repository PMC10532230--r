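#' Preprocessing configuration
#'
#' Settings for the fixed intensity-standardisation pipeline applied to
#' every volume before histogram embedding: resample to a common voxel
#' spacing, clip intensities by a modality-specific rule, then MinMax-scale
#' to [0, 1].
#'
#' Defaults follow the conventions for chest CT / brain MRI studies: a
#' common spacing of 1 x 1 x 1.5 mm, the standard lung window of
#' [-1350, 300] HU for CT, and per-image [1st, 99th] percentile clipping
#' for MRI (whose intensity scale is not calibrated across scanners).
#'
#' @param target_spacing mm triple all volumes are resampled to.
#' @param modality `"CT"` (fixed HU window) or `"MRI"` (per-image
#'   percentile window).
#' @param ct_window length-2 numeric `(low, high)` clip window in HU.
#' @param mri_percentiles length-2 numeric `(p_low, p_high)` percentiles
#'   in percent, `0 <= p_low < p_high <= 100`.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_spacing = c(1, 1, 1.5),
                              modality = c("MRI", "CT"),
                              ct_window = c(-1350, 300),
                              mri_percentiles = c(1, 99)) {
  modality <- match.arg(toupper(modality[1]), c("MRI", "CT"))
  target_spacing <- as.numeric(target_spacing)
  stopifnot(length(target_spacing) == 3L, all(target_spacing > 0),
            all(is.finite(target_spacing)))
  stopifnot(length(ct_window) == 2L, ct_window[1] < ct_window[2])
  stopifnot(length(mri_percentiles) == 2L,
            mri_percentiles[1] >= 0, mri_percentiles[2] <= 100,
            mri_percentiles[1] < mri_percentiles[2])
  structure(list(target_spacing = target_spacing, modality = modality,
                 ct_window = as.numeric(ct_window),
                 mri_percentiles = as.numeric(mri_percentiles)),
            class = "preprocess_config")
}

#' Resample a volume to a target voxel spacing
#'
#' Trilinear interpolation onto a new grid whose shape along each axis is
#' `round(n_in * s_in / s_target)` (at least 1), with rounding half away
#' from zero. Output voxel centres sit at physical coordinates
#' `i * s_target` measured from the first input voxel centre; samples
#' beyond the input extent clamp to the border value. Masks should use
#' [resample_mask()] instead (nearest-neighbour, stays binary).
#'
#' @param v a `Volume`.
#' @param target_spacing mm triple.
#' @return A `Volume` with `spacing == target_spacing`.
#' @export
resample <- function(v, target_spacing) {
  stopifnot(is_volume(v))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0) ||
      any(!is.finite(target_spacing)))
    stop("target spacing must be 3 strictly positive values")
  if (isTRUE(all.equal(v$spacing, target_spacing, tolerance = 1e-12)))
    return(v)
  d_in <- dim(v$data)
  d_out <- pmax(1L, as.integer(floor(d_in * v$spacing / target_spacing + 0.5)))
  ax <- lapply(1:3, function(k) resample_axis(d_out[k], target_spacing[k], v$spacing[k]))
  out <- trilinear_grid(v$data, ax[[1]], ax[[2]], ax[[3]])
  volume(out, spacing = target_spacing)
}

#' Resample a binary mask (nearest-neighbour)
#'
#' Same grid geometry as [resample()] but nearest-neighbour interpolation,
#' so the output remains exactly binary.
#'
#' @param m a `MaskVolume`.
#' @param target_spacing mm triple.
#' @return A `MaskVolume`.
#' @export
resample_mask <- function(m, target_spacing) {
  stopifnot(is_mask(m))
  target_spacing <- as.numeric(target_spacing)
  if (isTRUE(all.equal(m$spacing, target_spacing, tolerance = 1e-12)))
    return(m)
  d_in <- dim(m$data)
  d_out <- pmax(1L, as.integer(floor(d_in * m$spacing / target_spacing + 0.5)))
  ax <- lapply(1:3, function(k) resample_axis(d_out[k], target_spacing[k], m$spacing[k]))
  mask_volume(nearest_grid(m$data, ax[[1]], ax[[2]], ax[[3]]), spacing = target_spacing)
}

#' Clip intensities by the modality rule
#'
#' CT: clip to the fixed window in `config$ct_window` (default the lung
#' window, [-1350, 300] HU). MRI: clip to the volume's own
#' `[p_low, p_high]` intensity percentiles (default [1, 99]), computed with
#' linear interpolation between order statistics.
#'
#' @param v a `Volume`.
#' @param config a [preprocess_config()].
#' @return A `Volume` with all intensities inside the window.
#' @export
clip_intensities <- function(v, config = preprocess_config()) {
  stopifnot(is_volume(v), inherits(config, "preprocess_config"))
  if (config$modality == "CT") {
    lo <- config$ct_window[1]; hi <- config$ct_window[2]
  } else {
    b <- stats::quantile(v$data, probs = config$mri_percentiles / 100,
                         names = FALSE, type = 7)
    lo <- b[1]; hi <- b[2]
  }
  volume(array(pmin(pmax(v$data, lo), hi), dim = dim(v$data)), spacing = v$spacing)
}

#' MinMax-scale intensities to [0, 1]
#'
#' `(x - min) / (max - min)` per voxel, using the volume's own extrema.
#' A constant volume maps to all zeros so that the downstream histogram
#' stays well defined.
#'
#' @param v a `Volume`.
#' @return A `Volume` with intensities in [0, 1].
#' @export
minmax_scale <- function(v) {
  stopifnot(is_volume(v))
  lo <- min(v$data); hi <- max(v$data)
  out <- if (hi > lo) (v$data - lo) / (hi - lo) else array(0, dim = dim(v$data))
  volume(array(out, dim = dim(v$data)), spacing = v$spacing)
}

#' Full preprocessing pipeline
#'
#' Applies, in order: [resample()] to `config$target_spacing`,
#' [clip_intensities()], [minmax_scale()]. Clipping before scaling
#' guarantees the output range is exactly [0, 1] for every input.
#'
#' @param v a `Volume`.
#' @param config a [preprocess_config()].
#' @return A `Volume` at target spacing with intensities in [0, 1].
#' @export
preprocess <- function(v, config = preprocess_config()) {
  stopifnot(is_volume(v), inherits(config, "preprocess_config"))
  minmax_scale(clip_intensities(resample(v, config$target_spacing), config))
}
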