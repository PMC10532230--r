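#' Phantom generator configuration
#'
#' Parameters of the synthetic in-distribution volumes used for testing
#' and benchmarking without real data. A phantom is an ellipsoidal "body"
#' at `body_level` embedded in a `background_level` background, carrying a
#' random number of bright Gaussian blobs ("lesions"), plus i.i.d.
#' Gaussian voxel noise. The intensity profile (two tissue plateaus, a
#' sparse bright class, stationary noise) is what the histogram detector
#' keys on; anatomical realism is deliberately out of scope.
#'
#' Defaults give an MRI-like arbitrary-unit scale: background 20, body
#' 100, five flat-top blobs at 180, noise sd 5, on a 64 x 64 x 48 grid at
#' 1 x 1 x 1.5 mm. Geometry (ellipsoid centre and semi-axes, blob
#' placement) is jittered per volume so in-distribution phantoms vary
#' while sharing one stable intensity profile; the blob plateau doubles as
#' a bright reference class that pins the upper percentile anchor of the
#' preprocessing, which is what makes additive tissue shifts visible to a
#' histogram detector after per-image normalisation.
#'
#' @param shape integer voxel triple.
#' @param spacing mm triple.
#' @param background_level,body_level mean intensities of the two tissue
#'   plateaus.
#' @param blob_count_range integer `(min, max)` number of blobs.
#' @param blob_intensity `(mean, sd)` of blob peak intensity.
#' @param noise_sd Gaussian voxel noise standard deviation (>= 0).
#' @param blob_sigma `(min, max)` of the blob Gaussian width in voxels.
#' @param geom_jitter relative jitter of the body semi-axes across volumes
#'   (uniform in `[-geom_jitter, geom_jitter]`).
#' @param seed default seed used when an operation is not given one.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(64, 64, 48), spacing = c(1, 1, 1.5),
                           background_level = 20, body_level = 100,
                           blob_count_range = c(5, 5),
                           blob_intensity = c(180, 0),
                           noise_sd = 5, blob_sigma = c(4, 4),
                           geom_jitter = 0.05, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L),
            length(spacing) == 3L, all(spacing > 0),
            noise_sd >= 0, length(blob_count_range) == 2L,
            blob_count_range[1] >= 0,
            blob_count_range[1] <= blob_count_range[2],
            length(blob_intensity) == 2L, blob_intensity[2] >= 0,
            length(blob_sigma) == 2L, blob_sigma[1] > 0,
            blob_sigma[1] <= blob_sigma[2], geom_jitter >= 0)
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 background_level = background_level, body_level = body_level,
                 blob_count_range = as.integer(blob_count_range),
                 blob_intensity = as.numeric(blob_intensity),
                 noise_sd = noise_sd, blob_sigma = as.numeric(blob_sigma),
                 geom_jitter = geom_jitter, seed = as.integer(seed)),
            class = "phantom_config")
}

# shared generator behind the ID and shifted arms; with one seed the RNG
# draw sequence is identical across arms, so a zero-magnitude shift
# reproduces the ID volume exactly.
make_phantom <- function(config, seed, shift = NULL, magnitude = 0) {
  d <- config$shape
  with_seed(seed, {
    ctr <- d / 2 + stats::runif(3, -2, 2)
    semi <- 0.40 * d * (1 + stats::runif(3, -config$geom_jitter, config$geom_jitter))
    counts <- seq(config$blob_count_range[1], config$blob_count_range[2])
    n_blobs <- counts[sample.int(length(counts), 1)]
    blobs <- list()
    for (b in seq_len(n_blobs)) {
      for (try in 1:50) {
        c_b <- ctr + stats::runif(3, -0.6, 0.6) * semi
        sig <- stats::runif(1, config$blob_sigma[1], config$blob_sigma[2])
        # blob (at half-maximum) must fit inside the body
        if (sum(((c_b - ctr) / semi)^2) <= 0.7^2 &&
            sig * sqrt(2 * log(2)) < min(semi)) break
      }
      amp <- config$blob_intensity[1] +
        stats::rnorm(1, 0, 1) * config$blob_intensity[2]
      blobs[[b]] <- list(center = c_b, sigma = sig, amp = amp)
    }
    noise <- if (config$noise_sd > 0)
      stats::rnorm(prod(d), 0, config$noise_sd) else 0

    bg <- config$background_level
    body <- config$body_level
    shape_exponent <- 2
    if (!is.null(shift)) {
      if (shift == "intensity_shift") {       # protocol-like shift of the
        body <- body + magnitude              # body plateau; background and
      } else if (shift == "anatomy_change") { # the blob reference class keep
        # their calibrated levels -- different body-shape family
        shape_exponent <- 2 + magnitude       # superellipsoid exponent
      } else if (shift != "contrast_change") {
        stop("unknown shift kind: ", shift)
      }
    }

    co <- coord_arrays(d)
    r <- (abs((co$x + 1 - ctr[1]) / semi[1]))^shape_exponent +
         (abs((co$y + 1 - ctr[2]) / semi[2]))^shape_exponent +
         (abs((co$z + 1 - ctr[3]) / semi[3]))^shape_exponent
    inside <- r <= 1
    field <- bg + (body - bg) * inside
    mask <- array(FALSE, dim = d)
    for (bl in blobs) {
      r2 <- (co$x + 1 - bl$center[1])^2 + (co$y + 1 - bl$center[2])^2 +
            (co$z + 1 - bl$center[3])^2
      # flat-top (super-Gaussian) lesion profile: a stable plateau at the
      # blob intensity with sharp margins
      g <- (bl$amp - body) * exp(-(r2 / (2 * bl$sigma^2))^2)
      field <- field + g * inside           # blobs live inside the body
      mask <- mask | (inside & (r2 <= 2 * sqrt(log(2)) * bl$sigma^2))
    }
    if (!is.null(shift) && shift == "contrast_change" && magnitude != 1) {
      lo <- min(field); hi <- max(field)
      if (hi > lo) field <- lo + (hi - lo) * ((field - lo) / (hi - lo))^magnitude
    }
    field <- field + noise
    list(volume = volume(array(field, dim = d), spacing = config$spacing),
         mask = mask_volume(array(as.numeric(mask), dim = d),
                            spacing = config$spacing))
  })
}

#' Generate one in-distribution phantom
#'
#' @param config a [phantom_config()].
#' @param seed integer seed; the same `(config, seed)` always yields the
#'   identical volume and mask.
#' @return List with `volume` (a `Volume`) and `mask` (a `MaskVolume`
#'   marking blob support at half-maximum).
#' @export
generate_id_phantom <- function(config = phantom_config(), seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  make_phantom(config, seed)
}

#' Generate a distribution-shifted phantom
#'
#' Three shift families emulate clinically motivated OOD axes:
#' `"intensity_shift"` adds `magnitude` to the body tissue plateau before
#' noise, like an acquisition-protocol change altering soft-tissue signal
#' (the background and the bright lesion class keep their levels, so the
#' shift changes the shape of the intensity distribution rather than its
#' affine position -- a purely affine change would be removed by the
#' MinMax preprocessing by design); `"contrast_change"` applies a gamma transform with
#' exponent `magnitude` to the normalised noiseless field; and
#' `"anatomy_change"` replaces the ellipsoidal body by a superellipsoid of
#' exponent `2 + magnitude` (a boxier organ shape, changing the tissue
#' volume fractions). With `magnitude = 0` (or gamma 1) and the same seed,
#' the output is identical to the ID phantom.
#'
#' @param config a [phantom_config()].
#' @param shift `"intensity_shift"`, `"contrast_change"` or
#'   `"anatomy_change"`.
#' @param magnitude shift magnitude (intensity units, gamma exponent, or
#'   exponent offset respectively).
#' @param seed integer seed.
#' @return A `Volume`.
#' @export
generate_shifted_phantom <- function(config = phantom_config(),
                                     shift = c("intensity_shift",
                                               "contrast_change",
                                               "anatomy_change"),
                                     magnitude, seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  shift <- match.arg(shift)
  make_phantom(config, seed, shift = shift, magnitude = magnitude)$volume
}

#' Build a complete train/test OOD challenge fixture
#'
#' Deterministically derives per-volume seeds from `base_seed` (disjoint
#' across the train, ID-test, OOD and control arms) and generates an
#' in-distribution training set, an ID test set, an OOD test set from one
#' shift family, and optionally an identically distributed "control" arm
#' for null calibration checks.
#'
#' @param config a [phantom_config()].
#' @param n_train,n_test_id,n_test_ood positive arm sizes.
#' @param shift,magnitude passed to [generate_shifted_phantom()]; the
#'   default magnitude, `3 * noise_sd`, gives a clearly separable but not
#'   degenerate shift.
#' @param base_seed integer master seed.
#' @param n_control size of the ID-distributed control arm (default 0).
#' @return List with `train_id`, `test_id`, `test_ood`, `control`
#'   (lists of `Volume`s), `train_masks` (list of `MaskVolume`s) and
#'   `labels` (data.frame of arm tags).
#' @export
build_fixture <- function(config = phantom_config(), n_train = 50,
                          n_test_id = 30, n_test_ood = 30,
                          shift = "intensity_shift",
                          magnitude = 3 * config$noise_sd,
                          base_seed = 1L, n_control = 0) {
  stopifnot(n_train >= 1, n_test_id >= 1, n_test_ood >= 1, n_control >= 0)
  # per-volume seeds are drawn (without replacement) from the base-seeded
  # stream, so arms never share a seed and different base seeds give
  # fully decorrelated fixtures
  n_tot <- n_train + n_test_id + n_test_ood + n_control
  seeds <- with_seed(base_seed, sample.int(.Machine$integer.max - 1L, n_tot))
  off <- cumsum(c(0L, n_train, n_test_id, n_test_ood))
  arm_seed <- function(arm, i) seeds[off[arm] + i]
  train <- lapply(seq_len(n_train), function(i) generate_id_phantom(config, arm_seed(1L, i)))
  test_id <- lapply(seq_len(n_test_id), function(i) generate_id_phantom(config, arm_seed(2L, i))$volume)
  test_ood <- lapply(seq_len(n_test_ood), function(i)
    generate_shifted_phantom(config, shift, magnitude, arm_seed(3L, i)))
  control <- lapply(seq_len(n_control), function(i) generate_id_phantom(config, arm_seed(4L, i))$volume)
  labels <- data.frame(
    arm = c(rep("train_id", n_train), rep("test_id", n_test_id),
            rep("test_ood", n_test_ood), rep("control", n_control)),
    ood = c(rep(FALSE, n_train + n_test_id), rep(TRUE, n_test_ood),
            rep(FALSE, n_control)))
  list(train_id = lapply(train, `[[`, "volume"),
       train_masks = lapply(train, `[[`, "mask"),
       test_id = test_id, test_ood = test_ood, control = control,
       labels = labels)
}
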