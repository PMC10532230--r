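#' Score set for OOD evaluation
#'
#' Bundles OOD scores of in-distribution test cases with those of a
#' challenge's OOD cases, under the convention that higher score = more
#' likely OOD.
#'
#' @param id_scores numeric, scores of ID test samples.
#' @param ood_scores numeric, scores of OOD samples.
#' @return A `score_set`.
#' @export
score_set <- function(id_scores, ood_scores) {
  id_scores <- as.numeric(id_scores); ood_scores <- as.numeric(ood_scores)
  if (length(id_scores) == 0L || length(ood_scores) == 0L)
    stop("both score lists must be non-empty")
  if (any(!is.finite(id_scores)) || any(!is.finite(ood_scores)))
    stop("scores must be finite")
  structure(list(id_scores = id_scores, ood_scores = ood_scores),
            class = "score_set")
}

#' False-positive rate at a fixed true-positive rate
#'
#' The detector accepts a sample when its score is at or below a threshold
#' `tau`. Positives are ID samples being accepted; `tau` is set to the
#' smallest observed ID score such that at least `tpr` of the ID samples
#' are accepted (ties accepted, guaranteeing ID acceptance >= `tpr` on
#' finite samples). The FPR is then the fraction of OOD samples wrongly
#' accepted (score <= `tau`). Random, identically distributed scores give
#' FPR close to `tpr` (0.95 for the default), and a perfect detector gives
#' 0; lower is better.
#'
#' @param s a [score_set()].
#' @param tpr target ID acceptance rate in (0, 1); default 0.95.
#' @return FPR in [0, 1].
#' @export
fpr_at_tpr <- function(s, tpr = 0.95) {
  stopifnot(inherits(s, "score_set"), tpr > 0, tpr < 1)
  id <- sort(s$id_scores)
  tau <- id[ceiling(tpr * length(id))]
  mean(s$ood_scores <= tau)
}

#' Area under the ROC curve
#'
#' Probability that a uniformly random OOD score exceeds a uniformly
#' random ID score, with ties counted one half (the all-pairs / Wilcoxon
#' rank formulation). 1 is perfect separation, 0.5 is chance.
#'
#' @param s a [score_set()].
#' @return AUROC in [0, 1].
#' @export
auroc <- function(s) {
  stopifnot(inherits(s, "score_set"))
  n_i <- length(s$id_scores); n_o <- length(s$ood_scores)
  r <- rank(c(s$ood_scores, s$id_scores), ties.method = "average")
  (sum(r[seq_len(n_o)]) - n_o * (n_o + 1) / 2) / (n_i * n_o)
}

#' Fechner (sign-agreement) correlation
#'
#' Mean agreement of the signs of the two variables' deviations from their
#' means: `r = (1/n) sum sign((a_i - mean(a)) (b_i - mean(b)))`, with
#' `sign(0) = 0` so zero-deviation entries are neutral. Ranges over
#' [-1, 1].
#'
#' @param a,b numeric vectors of equal length `n >= 2`.
#' @return Correlation in [-1, 1].
#' @export
fechner_correlation <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  if (length(a) < 2L) stop("need at least 2 observations")
  mean(sign((a - mean(a)) * (b - mean(b))))
}

#' Both OOD metrics for one challenge
#'
#' @param id_scores,ood_scores numeric score vectors (higher = more OOD).
#' @param tpr ID acceptance rate for the FPR metric.
#' @return A one-row `data.frame` with columns `fpr_at_95tpr` and `auroc`.
#' @export
evaluate_challenge <- function(id_scores, ood_scores, tpr = 0.95) {
  s <- score_set(id_scores, ood_scores)
  data.frame(fpr_at_95tpr = fpr_at_tpr(s, tpr), auroc = auroc(s))
}
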