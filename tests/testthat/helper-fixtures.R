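# Shared fixtures: everything is generated in code at test time.

# a small deterministic random volume with intensities in [0, 1]
rand_volume <- function(seed, d = c(6, 5, 4), spacing = c(1, 1, 1)) {
  set.seed(seed)
  volume(array(runif(prod(d)), dim = d), spacing = spacing)
}

# small phantom configuration for fast pipeline tests
small_cfg <- function(...) phantom_config(shape = c(32, 32, 24), ...)

# reference built directly from moments (exercises the ridge + Cholesky
# path without the image pipeline)
moment_reference <- function(mu, Sigma, Z = NULL) {
  if (is.null(Z)) Z <- matrix(mu, nrow = 1)
  ihf3d:::reference_from_moments(NULL, Z, mu, Sigma,
                                 ihf_config(), preprocess_config())
}

# reference with an exact (unregularised) covariance: tests of the pure
# Mahalanobis kernel, bypassing the ridge
exact_reference <- function(mu, Sigma, Z = matrix(mu, nrow = 1)) {
  structure(list(reducer = NULL, train_reduced = Z, mean = mu,
                 covariance = Sigma, covariance_reg = Sigma,
                 chol = chol(Sigma), config = ihf_config(),
                 preprocess_config = preprocess_config()),
            class = "ihf_reference")
}

# independent type-7 percentile oracle: linear interpolation between
# order statistics, written from the definition
percentile_oracle <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p / 100
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[pmin(lo + 2, n)] - x[lo + 1])
}

# independent trilinear interpolation oracle at a single 0-based point,
# with border clamping
trilinear_oracle <- function(a, x, y, z) {
  d <- dim(a)
  cl <- function(t, n) min(max(t, 0), n - 1)
  x <- cl(x, d[1]); y <- cl(y, d[2]); z <- cl(z, d[3])
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- min(floor(x) + dx, d[1] - 1)
    iy <- min(floor(y) + dy, d[2] - 1)
    iz <- min(floor(z) + dz, d[3] - 1)
    wx <- if (dx == 0) 1 - (x - floor(x)) else x - floor(x)
    wy <- if (dy == 0) 1 - (y - floor(y)) else y - floor(y)
    wz <- if (dz == 0) 1 - (z - floor(z)) else z - floor(z)
    acc <- acc + wx * wy * wz * a[ix + 1, iy + 1, iz + 1]
  }
  acc
}

# structured phantom reused by corruption tests
structured_phantom <- function(seed = 7, shape = c(24, 24, 16))
  generate_id_phantom(phantom_config(shape = shape), seed = seed)$volume
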