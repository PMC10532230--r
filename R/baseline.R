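#' Physical volume of a binary prediction mask
#'
#' Total volume of the positive class: the count of 1-voxels times the
#' voxel volume `sx * sy * sz` (mm^3).
#'
#' @param mask a `MaskVolume`.
#' @return Volume in mm^3.
#' @export
prediction_volume <- function(mask) {
  stopifnot(is_mask(mask))
  sum(mask$data == 1) * prod(mask$spacing)
}

#' Fit the predicted-volume baseline reference
#'
#' The baseline detector summarises each in-distribution case by the
#' physical volume of its (predicted) segmentation mask and keeps the
#' sorted list of those volumes as its reference distribution.
#'
#' @param masks list of `MaskVolume`s (at least one).
#' @return A `volume_reference` with fields `id_volumes` (sorted, mm^3)
#'   and `n`.
#' @export
fit_volume_reference <- function(masks) {
  if (length(masks) < 1L) stop("need at least one mask")
  vols <- sort(vapply(masks, prediction_volume, numeric(1)))
  structure(list(id_volumes = vols, n = length(vols)), class = "volume_reference")
}

#' Two-sided outlyingness score of a predicted volume
#'
#' `|F(vol) - 0.5|` where `F` is the mid-rank empirical CDF of the
#' reference volumes, `F(v) = (#\{x < v\} + 0.5 #\{x == v\}) / n`. The score
#' lies in [0, 0.5]: 0 at the reference median, 0.5 beyond either extreme.
#' Higher = more outlying (either unusually small or unusually large).
#'
#' @param ref a `volume_reference`.
#' @param vol predicted volume in mm^3 (vectorised).
#' @return Score(s) in [0, 0.5].
#' @export
volume_score <- function(ref, vol) {
  stopifnot(inherits(ref, "volume_reference"))
  vapply(vol, function(v) {
    f <- (sum(ref$id_volumes < v) + 0.5 * sum(ref$id_volumes == v)) / ref$n
    abs(f - 0.5)
  }, numeric(1))
}

#' Two-sided percentile decision rule
#'
#' Flags a case as an outlier when its predicted volume falls strictly
#' below the `q/2`-th or strictly above the `(100 - q/2)`-th percentile of
#' the reference volumes (linear-interpolation percentiles), so that about
#' `100 - q`% of in-distribution cases are retained.
#'
#' @param ref a `volume_reference`.
#' @param vol predicted volume in mm^3 (vectorised).
#' @param q total rejection percentage in (0, 100), split across both tails.
#' @return Logical outlier flag(s).
#' @export
volume_decision <- function(ref, vol, q = 5) {
  stopifnot(inherits(ref, "volume_reference"))
  if (q <= 0 || q >= 100) stop("'q' must be in (0, 100)")
  b <- stats::quantile(ref$id_volumes, probs = c(q / 200, 1 - q / 200),
                       names = FALSE, type = 7)
  vol < b[1] | vol > b[2]
}
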