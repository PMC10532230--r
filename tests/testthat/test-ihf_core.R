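test_that("histogram embedding bins and density normalisation", {
  vc <- volume(array(0.5, dim = c(3, 3, 3)), c(1, 1, 1))
  expect_equal(as.numeric(compute_histogram(vc, 4)), c(0, 0, 4, 0))

  half <- volume(array(rep(c(0.1, 0.9), each = 4), dim = c(2, 2, 2)), c(1, 1, 1))
  expect_equal(as.numeric(compute_histogram(half, 2)), c(1, 1))

  # value exactly 1 joins the last (closed) bin
  ones <- volume(array(1, dim = c(2, 2, 2)), c(1, 1, 1))
  expect_equal(as.numeric(compute_histogram(ones, 5)), c(0, 0, 0, 0, 5))

  expect_error(compute_histogram(volume(array(1.2, dim = c(2, 2, 2)), c(1, 1, 1)), 4),
               "outside")

  # sum(values)/m == 1 for arbitrary volumes
  for (s in 1:5) {
    v <- rand_volume(s, d = c(7, 5, 6))
    for (m in c(2, 10, 150)) {
      e <- compute_histogram(v, m)
      expect_true(all(e >= 0))
      expect_equal(sum(e) / m, 1, tolerance = 1e-9)
    }
  }
})

test_that("uniform intensities give near-flat densities (counting oracle)", {
  set.seed(99)
  x <- runif(1e5)
  v <- volume(array(x, dim = c(100, 100, 10)), c(1, 1, 1))
  e <- compute_histogram(v, 10)
  expect_true(all(abs(e - 1) < 0.05))
  # independent counting oracle for the bin rule
  oracle <- vapply(0:9, function(i)
    sum(x >= i / 10 & (x < (i + 1) / 10 | (i == 9 & x <= 1))), numeric(1))
  expect_equal(as.numeric(e), oracle * 10 / length(x))
})

test_that("PCA reducer picks the minimal k reaching the variance target", {
  set.seed(41)
  # rank-1: points on a line through the mean
  dirn <- rnorm(20); dirn <- dirn / sqrt(sum(dirn^2))
  X1 <- outer(rnorm(15), dirn) + rep(1, 15) %o% runif(20)
  r1 <- fit_reducer(X1, 0.9999)
  expect_equal(ncol(r1$basis), 1L)
  expect_equal(r1$center, colMeans(X1))

  # isotropic 3-D cloud needs all 3 components at v = 0.9999
  X3 <- matrix(rnorm(1500), 500, 3)
  r3 <- fit_reducer(X3, 0.9999)
  expect_equal(ncol(r3$basis), 3L)
  # independent eigendecomposition oracle for the retained variance
  ev <- sort(eigen(stats::cov(X3), symmetric = TRUE)$values, decreasing = TRUE)
  expect_gte(r3$explained_variance_ratio + 1e-12, sum(ev[1:3]) / sum(ev))

  # v = 1 keeps the full rank of the centered data
  X2 <- cbind(rnorm(30), rnorm(30))
  X2 <- cbind(X2, X2[, 1] + X2[, 2])  # rank 2 after centering
  rfull <- fit_reducer(X2, 1.0)
  expect_equal(ncol(rfull$basis), qr(sweep(X2, 2, colMeans(X2)))$rank)

  expect_error(fit_reducer(matrix(1, 1, 5)), "at least 2")
})

test_that("reducer basis is orthonormal and retains >= v variance", {
  set.seed(42)
  X <- matrix(rnorm(60 * 20), 60, 20) %*% diag(c(10, 5, rep(0.1, 18)))
  r <- fit_reducer(X, 0.9999)
  G <- crossprod(r$basis)
  expect_equal(G, diag(ncol(r$basis)), tolerance = 1e-8)
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  k <- ncol(r$basis)
  expect_gte(r$explained_variance_ratio, 0.9999 - 1e-9)
  expect_equal(r$explained_variance_ratio,
               sum(sort(ev, decreasing = TRUE)[1:k]) / sum(ev),
               tolerance = 1e-9)
})

test_that("reduce projects and reconstructs correctly", {
  set.seed(43)
  dirn <- rnorm(12); dirn <- dirn / sqrt(sum(dirn^2))
  X <- outer(rnorm(10, sd = 3), dirn) + rep(1, 10) %o% runif(12)
  r <- fit_reducer(X, 0.9999)

  expect_equal(reduce_embedding(r, r$center), 0)       # center maps to zero
  expect_equal(reduce_embedding(NULL, X[1, ]), X[1, ]) # no-PCA identity

  for (i in 1:10) {                                    # rank-1 reconstruction
    z <- reduce_embedding(r, X[i, ])
    expect_equal(as.numeric(r$center + r$basis %*% z), X[i, ], tolerance = 1e-8)
  }
  expect_error(reduce_embedding(r, rnorm(5)), "length")
})

test_that("fit_reference estimates population moments of the embeddings", {
  cfg <- small_cfg()
  vols <- lapply(1:12, function(i) generate_id_phantom(cfg, seed = 100 + i)$volume)
  pp <- preprocess_config()
  icfg <- ihf_config(m = 60)
  ref <- fit_reference(vols, icfg, pp)

  # recompute embeddings outside the fit path
  E <- t(sapply(vols, function(v)
    as.numeric(compute_histogram(preprocess(v, pp), 60))))
  Z <- t(apply(E, 1, function(e) reduce_embedding(ref$reducer, e)))
  expect_equal(ref$mean, colMeans(Z), tolerance = 1e-9)
  Zc <- sweep(Z, 2, colMeans(Z))
  expect_equal(ref$covariance, crossprod(Zc) / nrow(Z), tolerance = 1e-9)
  expect_equal(ref$covariance, t(ref$covariance), tolerance = 1e-9)
  expect_true(all(eigen(ref$covariance_reg, symmetric = TRUE,
                        only.values = TRUE)$values > 0))

  # PCA off: reduced width is m
  ref_nopca <- fit_reference(vols[1:4], ihf_config(m = 60, use_pca = FALSE), pp)
  expect_equal(ncol(ref_nopca$train_reduced), 60L)
  expect_null(ref_nopca$reducer)

  expect_error(fit_reference(vols[1], icfg, pp), "at least 2")
})

test_that("degenerate identical training volumes give a ridge-only covariance", {
  v <- generate_id_phantom(small_cfg(), seed = 9)$volume
  ref <- fit_reference(list(v, v), ihf_config(m = 40), preprocess_config())
  e <- compute_histogram(preprocess(v, preprocess_config()), 40)
  z <- reduce_embedding(ref$reducer, e)
  expect_equal(ref$mean, z, tolerance = 1e-9)
  expect_equal(ref$covariance, matrix(0, length(z), length(z)), tolerance = 1e-12)
  expect_equal(ref$covariance_reg, diag(1e-6, length(z)), tolerance = 1e-12)
})

test_that("Mahalanobis score closed forms", {
  ref2 <- moment_reference(c(0, 0), diag(2))
  expect_equal(score_mahalanobis(ref2, c(0, 0)), 0)
  expect_equal(score_mahalanobis(ref2, c(3, 4)), 5, tolerance = 1e-5)

  refd <- moment_reference(c(0, 0), diag(c(4, 1)))
  expect_equal(score_mahalanobis(refd, c(2, 1)), sqrt(2), tolerance = 1e-5)
  expect_error(score_mahalanobis(refd, c(1, 2, 3)), "length")

  # with an exact identity covariance the score is the Euclidean distance
  refe <- exact_reference(c(1, -1, 2), diag(3))
  expect_equal(score_mahalanobis(refe, c(2, 0, 4)), sqrt(1 + 1 + 4))
})

test_that("Mahalanobis kernel is invariant under invertible reparameterisation", {
  set.seed(55)
  for (rep in 1:10) {
    mu <- rnorm(3)
    B <- matrix(rnorm(9), 3, 3)
    Sigma <- crossprod(B) + diag(0.5, 3)
    x <- rnorm(3, sd = 2)
    A <- matrix(rnorm(9), 3, 3)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3, 3)
    s0 <- score_mahalanobis(exact_reference(mu, Sigma), x)
    s1 <- score_mahalanobis(exact_reference(as.numeric(A %*% mu),
                                            A %*% Sigma %*% t(A)),
                            as.numeric(A %*% x))
    expect_equal(s1, s0, tolerance = 1e-6)
  }
})

test_that("nearest-neighbour score matches the brute-force oracle", {
  Z <- rbind(c(0, 0), c(1, 0))
  ref <- moment_reference(colMeans(Z), diag(2), Z = Z)
  expect_equal(score_nn(ref, c(0.2, 0)), 0.2)
  expect_equal(score_nn(ref, c(1, 0)), 0)

  set.seed(66)
  Ztr <- matrix(rnorm(200 * 4), 200, 4)
  refb <- moment_reference(colMeans(Ztr), stats::cov(Ztr), Z = Ztr)
  for (q in 1:50) {
    x <- rnorm(4)
    oracle <- min(apply(Ztr, 1, function(z) sqrt(sum((z - x)^2))))
    expect_equal(score_nn(refb, x), oracle, tolerance = 1e-12)
  }
})

test_that("full scoring pipeline: self-match, chi-square moment, shift ordering", {
  cfg <- small_cfg()
  pp <- preprocess_config()
  vols <- lapply(1:25, function(i) generate_id_phantom(cfg, seed = 300 + i)$volume)

  ref_nn <- fit_reference(vols, ihf_config(m = 60, scorer = "nn"), pp)
  expect_equal(ihf_score(ref_nn, vols[[3]]), 0, tolerance = 1e-12)

  # with divisor-n covariance, the train-set mean squared Mahalanobis
  # distance equals the reduced dimension k (trace identity)
  ref_m <- fit_reference(vols, ihf_config(m = 60, scorer = "mahalanobis"), pp)
  k <- ncol(ref_m$train_reduced)
  msq <- mean(vapply(vols, function(v) ihf_score(ref_m, v)^2, numeric(1)))
  expect_equal(msq, k, tolerance = 0.01)

  # a tissue-level intensity shift scores above the median ID score
  med_id <- stats::median(ihf_score_all(ref_m, vols))
  for (s in 1:20) {
    sh <- generate_shifted_phantom(cfg, "intensity_shift",
                                   magnitude = 3 * cfg$noise_sd, seed = 900 + s)
    expect_gt(ihf_score(ref_m, sh), med_id)
  }
})

test_that("fitting and scoring are deterministic", {
  cfg <- small_cfg()
  vols <- lapply(1:6, function(i) generate_id_phantom(cfg, seed = 40 + i)$volume)
  r1 <- fit_reference(vols, ihf_config(m = 50), preprocess_config())
  r2 <- fit_reference(vols, ihf_config(m = 50), preprocess_config())
  expect_identical(r1$mean, r2$mean)
  expect_identical(r1$covariance, r2$covariance)
  expect_identical(ihf_score(r1, vols[[1]]), ihf_score(r2, vols[[1]]))
})
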