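kinds <- c("local_noise", "elastic", "kspace", "anisotropy", "ghosting", "motion")

test_that("corruptions are deterministic and preserve shape and spacing", {
  v <- structured_phantom(seed = 3)
  for (kind in kinds) {
    a <- corrupt_volume(v, kind, severity = 3, seed = 11)
    b <- corrupt_volume(v, kind, severity = 3, seed = 11)
    expect_identical(a$data, b$data)
    expect_equal(dim(a$data), dim(v$data))
    expect_equal(a$spacing, v$spacing)
    # the seed drives the randomness: some seed in 1:6 changes the output
    # (kinds whose only draw is the axis choice may coincide for two seeds)
    others <- lapply(1:6, function(s) corrupt_volume(v, kind, 3, s)$data)
    expect_false(all(vapply(others, identical, logical(1), y = a$data)))
  }
  expect_error(severity_params("kspace", 6), "1..5")
  expect_error(corrupt_volume(v, "warp", 1, 1), "arg")
})

test_that("local corruption is confined to a crop and zero magnitudes are identity", {
  v <- structured_phantom(seed = 4)
  id <- corrupt_local(v, seed = 5,
                      params = list(noise_sd = 0, blur_sigma = 0, gamma = 1))
  expect_equal(id$data, v$data)

  noise_only <- list(noise_sd = 0.3, blur_sigma = 0, gamma = 1)
  # over several seeds (covering all three variants) changed voxels stay
  # inside a box no larger than half the volume per axis
  for (s in 1:6) {
    out <- corrupt_local(v, severity = 5, seed = s)
    ch <- which(out$data != v$data, arr.ind = TRUE)
    if (nrow(ch) == 0) next  # blur/contrast variants may fix some seeds
    box <- apply(ch, 2, function(i) diff(range(i))) + 1
    expect_true(all(box <= ceiling(0.5 * dim(v$data)) + 1))
    expect_lt(nrow(ch), prod(dim(v$data)))  # some voxels bit-identical
  }
})

test_that("crop noise variance matches the severity table (moment oracle)", {
  const <- volume(array(5, dim = c(40, 40, 30)), c(1, 1, 1))
  # constant input: severity sigma is relative to a unit fallback range
  sigma <- severity_params("local_noise", 5)$noise_sd
  pooled <- numeric(0)
  for (s in 1:20) {
    out <- corrupt_local(const, severity = 5, seed = s)
    changed <- out$data != const$data
    if (!any(changed)) next  # seed picked blur or contrast: both fix constants
    pooled <- c(pooled, out$data[changed] - 5)
  }
  expect_gt(length(pooled), 500)
  expect_equal(stats::var(pooled), sigma^2, tolerance = 0.2)
})

test_that("elastic deformation: identity, constants, Lipschitz bound", {
  v <- structured_phantom(seed = 6)
  expect_identical(corrupt_elastic(v, seed = 2,
                                   params = list(max_disp = 0, grid = 8))$data,
                   v$data)
  const <- volume(array(2.5, dim = c(16, 16, 12)), c(1, 1, 1))
  out_c <- corrupt_elastic(const, severity = 5, seed = 3)
  expect_equal(out_c$data, const$data, tolerance = 1e-6)

  # linear ramp: voxel change bounded by max displacement times the slope
  d <- c(20, 20, 14); slope <- 0.25
  ramp <- volume(array(rep(slope * (0:(d[1] - 1)), times = prod(d[2:3])), dim = d),
                 c(1, 1, 1))
  out_r <- corrupt_elastic(ramp, severity = 5, seed = 4)
  maxd <- severity_params("elastic", 5)$max_disp
  expect_lte(max(abs(out_r$data - ramp$data)), maxd * slope + 1e-9)
})

test_that("k-space spikes: identity, analytic single-spike field, mean preservation", {
  v <- structured_phantom(seed = 8)
  expect_identical(corrupt_kspace(v, seed = 1, params = list(amp = 0, count = 0))$data,
                   v$data)

  d <- c(16, 12, 10)
  zero <- volume(array(0, dim = d), c(1, 1, 1))
  spikes <- data.frame(kx = 3, ky = 2, kz = 0, amp = 2, phase = 0.7)
  out <- corrupt_kspace(zero, spikes = spikes)
  co <- expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1), z = 0:(d[3] - 1))
  expected <- 2 * cos(2 * pi * (3 * co$x / d[1] + 2 * co$y / d[2]) + 0.7)
  expect_equal(as.vector(out$data), expected, tolerance = 1e-6)

  out_s <- corrupt_kspace(v, severity = 4, seed = 21)
  expect_equal(mean(out_s$data), mean(v$data), tolerance = 1e-6)
  expect_gt(stats::sd(out_s$data - v$data), 0)
})

test_that("anisotropy: identity at factor 1, constants, slab invariance", {
  v <- structured_phantom(seed = 9)
  expect_identical(corrupt_anisotropy(v, seed = 2, params = list(factor = 1))$data,
                   v$data)
  const <- volume(array(1.5, dim = c(16, 16, 16)), c(1, 1, 1))
  expect_equal(corrupt_anisotropy(const, severity = 5, seed = 2)$data,
               const$data, tolerance = 1e-12)

  # volume constant on aligned f^3 blocks is fixed by nearest-mode resampling
  f <- severity_params("anisotropy", 3)$factor  # 4
  n <- 16
  set.seed(30)
  coarse <- array(rnorm((n / f)^3), dim = rep(n / f, 3))
  blocky <- coarse[rep(1:(n / f), each = f), rep(1:(n / f), each = f),
                   rep(1:(n / f), each = f)]
  bv <- volume(blocky, c(1, 1, 1))
  out <- corrupt_anisotropy(bv, severity = 3, seed = 5, mode = "nearest")
  expect_identical(out$data, bv$data)
})

test_that("ghosting: identity at w = 0, constants, impulse response", {
  v <- structured_phantom(seed = 10)
  expect_identical(corrupt_ghosting(v, seed = 1,
                                    params = list(w = 0, n_ghosts = 2))$data,
                   v$data)
  const <- volume(array(3, dim = c(12, 12, 12)), c(1, 1, 1))
  expect_equal(corrupt_ghosting(const, severity = 5, seed = 1)$data, const$data,
               tolerance = 1e-12)

  imp <- array(0, dim = c(12, 12, 12)); imp[1, 1, 1] <- 1
  p <- severity_params("ghosting", 1)  # w = 0.05, G = 2, delta = 4
  out <- corrupt_ghosting(volume(imp, c(1, 1, 1)), severity = 1, seed = 3)
  nz <- sort(out$data[out$data != 0])
  expect_equal(length(nz), 3L)
  expect_equal(nz, sort(c(1 - p$w, p$w / 2, p$w / 2)))
})

test_that("motion: identity at zero magnitudes, constants, severity ordering", {
  v <- structured_phantom(seed = 12)
  expect_identical(corrupt_motion(v, seed = 1,
                                  params = list(degrees = 0, translation = 0,
                                                n_transforms = 2))$data,
                   v$data)
  const <- volume(array(4, dim = c(12, 12, 10)), c(1, 1, 1))
  expect_equal(corrupt_motion(const, severity = 5, seed = 2)$data, const$data,
               tolerance = 1e-5)

  nrms <- function(out) sqrt(mean((out$data - v$data)^2)) / stats::sd(v$data)
  d1 <- vapply(1:10, function(s) nrms(corrupt_motion(v, 1, s)), numeric(1))
  d5 <- vapply(1:10, function(s) nrms(corrupt_motion(v, 5, s)), numeric(1))
  expect_gt(mean(d5), mean(d1))
  expect_gt(mean(d5 > d1), 0.7)  # severity 5 dominates seed-by-seed as well
})

test_that("mean absolute difference is non-decreasing in severity for every kind", {
  v <- structured_phantom(seed = 14)
  for (kind in kinds) {
    mad_by_level <- vapply(1:5, function(lev)
      mean(vapply(1:10, function(s)
        mean(abs(corrupt_volume(v, kind, lev, s)$data - v$data)), numeric(1))),
      numeric(1))
    expect_true(all(diff(mad_by_level) > -1e-9 * max(mad_by_level)),
                info = kind)
  }
})
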