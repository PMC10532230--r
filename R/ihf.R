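#' IHF detector configuration
#'
#' Hyperparameters of the intensity-histogram OOD detector: the number of
#' histogram bins `m`, whether PCA reduction is applied, the explained
#' variance target `v` it preserves, and the outlier scorer (Mahalanobis
#' distance to the training distribution, or Euclidean distance to the
#' nearest training embedding).
#'
#' @param m number of histogram bins over [0, 1] (default 150).
#' @param v explained-variance target in (0, 1] for PCA (default 0.9999).
#' @param use_pca logical; reduce embeddings with PCA before scoring
#'   (default `TRUE`).
#' @param scorer `"mahalanobis"` or `"nn"`.
#' @return An `ihf_config` list.
#' @export
ihf_config <- function(m = 150L, v = 0.9999, use_pca = TRUE,
                       scorer = c("mahalanobis", "nn")) {
  scorer <- match.arg(scorer)
  m <- as.integer(m)
  stopifnot(m >= 2L, v > 0, v <= 1, is.logical(use_pca))
  structure(list(m = m, v = v, use_pca = isTRUE(use_pca), scorer = scorer),
            class = "ihf_config")
}

#' Intensity-histogram embedding of a preprocessed volume
#'
#' Computes the empirical probability density of the voxel intensities in
#' `m` equal bins over [0, 1]: bin i (0-based) covers `[i/m, (i+1)/m)`,
#' with the last bin closed at 1. Values are densities, `count_i * m / N`,
#' so that `sum(values) / m == 1` (the density integrates to one).
#'
#' @param v a preprocessed `Volume` with all intensities in [0, 1].
#' @param m bin count.
#' @return Numeric vector of length `m` of class `ihf_embedding`.
#' @export
compute_histogram <- function(v, m = 150L) {
  stopifnot(is_volume(v))
  m <- as.integer(m)
  stopifnot(m >= 2L)
  x <- v$data
  if (min(x) < 0 || max(x) > 1)
    stop("intensities outside [0, 1]; run preprocess() first")
  idx <- pmin(as.integer(floor(x * m)), m - 1L) + 1L  # value 1 joins the last bin
  counts <- tabulate(idx, nbins = m)
  structure(counts * m / length(x), class = "ihf_embedding", m = m)
}

#' Fit a PCA reducer preserving a target explained variance
#'
#' Centers the training embeddings and keeps the smallest number of
#' principal components `k` whose cumulative explained-variance ratio
#' reaches `v`, capped at `min(n - 1, m)`. Computed by SVD of the centered
#' matrix; component signs are fixed (largest-magnitude loading positive)
#' so fits are canonical.
#'
#' @param train_embeddings n x m matrix of embeddings (rows = volumes).
#' @param v explained-variance target in (0, 1].
#' @return An `ihf_reducer` with fields `center` (length m), `basis`
#'   (m x k, orthonormal columns) and `explained_variance_ratio`.
#' @export
fit_reducer <- function(train_embeddings, v = 0.9999) {
  X <- as.matrix(train_embeddings)
  n <- nrow(X); m <- ncol(X)
  if (n < 2L) stop("need at least 2 training embeddings to fit PCA")
  stopifnot(v > 0, v <= 1)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  s <- svd(Xc)
  ev <- s$d^2
  kmax <- min(n - 1L, m)
  total <- sum(ev)
  if (total <= 0) {          # zero-variance data: keep one arbitrary direction
    basis <- matrix(0, m, 1); basis[1, 1] <- 1
    return(structure(list(center = center, basis = basis,
                          explained_variance_ratio = 1),
                     class = "ihf_reducer"))
  }
  ratio <- cumsum(ev) / total
  k <- which(ratio >= v - 1e-12)[1]
  if (is.na(k) || k > kmax) k <- kmax
  basis <- s$v[, seq_len(k), drop = FALSE]
  # canonical signs
  for (j in seq_len(k)) {
    i <- which.max(abs(basis[, j]))
    if (basis[i, j] < 0) basis[, j] <- -basis[, j]
  }
  structure(list(center = center, basis = basis,
                 explained_variance_ratio = min(ratio[k], 1)),
            class = "ihf_reducer")
}

#' Project an embedding into the reduced PCA space
#'
#' `basis' (e - center)`; with `reducer = NULL` the embedding is returned
#' unchanged (the no-PCA path).
#'
#' @param reducer an `ihf_reducer` or `NULL`.
#' @param e embedding vector of length m.
#' @return Numeric vector of length k (or m when `reducer` is `NULL`).
#' @export
reduce_embedding <- function(reducer, e) {
  e <- as.numeric(e)
  if (is.null(reducer)) return(e)
  stopifnot(inherits(reducer, "ihf_reducer"))
  if (length(e) != length(reducer$center))
    stop("embedding length ", length(e), " does not match reducer (",
         length(reducer$center), ")")
  drop(crossprod(reducer$basis, e - reducer$center))
}

embedding_matrix <- function(volumes, m, preprocess_config) {
  t(vapply(volumes,
           function(v) as.numeric(compute_histogram(preprocess(v, preprocess_config), m)),
           numeric(m)))
}

#' Fit the IHF in-distribution reference
#'
#' Runs the full training pipeline on a set of in-distribution volumes:
#' preprocess, histogram-embed, optionally PCA-reduce, then estimate the
#' reference statistics. The mean and covariance use the population form
#' (divisor n): `mu = mean(e_i)`, `Sigma = (1/n) sum (e_i - mu)(e_i - mu)'`.
#' Before factorisation the covariance receives a relative ridge,
#' `Sigma + 1e-6 * (tr(Sigma)/k) * I` (absolute `1e-6 * I` when the trace
#' vanishes), guarding against ill-conditioning; its Cholesky factor is
#' stored so Mahalanobis scoring never forms an explicit inverse.
#'
#' @param train_volumes list of `Volume`s (at least 2).
#' @param config an [ihf_config()].
#' @param preprocess_config a [preprocess_config()].
#' @return An `ihf_reference` with fields `reducer`, `train_reduced`
#'   (n x k matrix), `mean`, `covariance`, `chol` (upper Cholesky factor of
#'   the regularised covariance), `config`, `preprocess_config`.
#' @export
fit_reference <- function(train_volumes, config = ihf_config(),
                          preprocess_config = preprocess_config()) {
  stopifnot(inherits(config, "ihf_config"),
            inherits(preprocess_config, "preprocess_config"))
  if (length(train_volumes) < 2L) stop("need at least 2 training volumes")
  E <- embedding_matrix(train_volumes, config$m, preprocess_config)
  reducer <- if (config$use_pca) fit_reducer(E, config$v) else NULL
  Z <- if (is.null(reducer)) E else {
    Zr <- apply(E, 1, function(e) reduce_embedding(reducer, e))
    if (is.matrix(Zr)) t(Zr) else matrix(Zr, ncol = 1)  # k == 1
  }
  mu <- colMeans(Z)
  Zc <- sweep(Z, 2, mu)
  Sigma <- crossprod(Zc) / nrow(Z)
  reference_from_moments(reducer, Z, mu, Sigma, config, preprocess_config)
}

# assemble a reference from its moments; applies the relative ridge and
# precomputes the Cholesky factor used by the Mahalanobis solve
reference_from_moments <- function(reducer, Z, mu, Sigma, config,
                                   preprocess_config) {
  k <- length(mu)
  scale <- sum(diag(Sigma)) / k
  if (!is.finite(scale) || scale <= 0) scale <- 1
  Sigma_reg <- Sigma + diag(1e-6 * scale, k)
  R <- chol(Sigma_reg)
  structure(list(reducer = reducer, train_reduced = Z, mean = mu,
                 covariance = Sigma, covariance_reg = Sigma_reg, chol = R,
                 config = config, preprocess_config = preprocess_config),
            class = "ihf_reference")
}

#' @export
print.ihf_reference <- function(x, ...) {
  cat(sprintf("<IHF reference: n = %d, m = %d, k = %d, scorer = %s, PCA %s>\n",
              nrow(x$train_reduced), x$config$m, ncol(x$train_reduced),
              x$config$scorer, if (x$config$use_pca) "on" else "off"))
  invisible(x)
}

#' Mahalanobis OOD score of a reduced embedding
#'
#' `sqrt((e - mu)' Sigma^-1 (e - mu))` against the reference mean and
#' (regularised) covariance, computed through the stored Cholesky factor.
#'
#' @param ref an `ihf_reference`.
#' @param e_reduced reduced embedding vector (length k).
#' @return Nonnegative scalar; higher = more likely OOD.
#' @export
score_mahalanobis <- function(ref, e_reduced) {
  stopifnot(inherits(ref, "ihf_reference"))
  e_reduced <- as.numeric(e_reduced)
  if (length(e_reduced) != length(ref$mean))
    stop("embedding length does not match reference dimension")
  w <- backsolve(ref$chol, e_reduced - ref$mean, transpose = TRUE)
  sqrt(sum(w^2))
}

#' Nearest-neighbour OOD score of a reduced embedding
#'
#' Minimum Euclidean distance from the query embedding to the reduced
#' training embeddings.
#'
#' @inheritParams score_mahalanobis
#' @return Nonnegative scalar; higher = more likely OOD.
#' @export
score_nn <- function(ref, e_reduced) {
  stopifnot(inherits(ref, "ihf_reference"))
  e_reduced <- as.numeric(e_reduced)
  Z <- ref$train_reduced
  if (nrow(Z) == 0L) stop("reference has no training embeddings")
  if (length(e_reduced) != ncol(Z))
    stop("embedding length does not match reference dimension")
  diffs <- sweep(Z, 2, e_reduced)
  sqrt(min(rowSums(diffs^2)))
}

#' OOD score of a raw volume
#'
#' The full scoring pipeline: preprocess, histogram-embed, reduce, then
#' apply the configured scorer. Higher scores mean more likely
#' out-of-distribution.
#'
#' @param ref an `ihf_reference` fitted by [fit_reference()].
#' @param v a raw `Volume`.
#' @return Nonnegative scalar OOD score.
#' @export
ihf_score <- function(ref, v) {
  stopifnot(inherits(ref, "ihf_reference"), is_volume(v))
  e <- compute_histogram(preprocess(v, ref$preprocess_config), ref$config$m)
  z <- reduce_embedding(ref$reducer, e)
  if (ref$config$scorer == "mahalanobis") score_mahalanobis(ref, z)
  else score_nn(ref, z)
}

#' Score a list of volumes
#'
#' @param ref an `ihf_reference`.
#' @param volumes list of `Volume`s.
#' @return Numeric vector of OOD scores.
#' @export
ihf_score_all <- function(ref, volumes) {
  vapply(volumes, function(v) ihf_score(ref, v), numeric(1))
}
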