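#' Severity parameter tables for the synthetic corruptions
#'
#' Each corruption kind is driven by a small set of magnitudes indexed by a
#' severity level from 1 (barely noticeable) to 5 (heavily distorted). The
#' tables are fixed and versioned here so severity sweeps are reproducible;
#' the same values ship as a plain-text config in
#' `system.file("extdata", "severity_table.json", package = "ihf3d")`.
#'
#' Magnitudes denoted "of range" are fractions of the input volume's
#' observed intensity range (`max - min`; a unit range is assumed when the
#' input is constant), so the tables apply unchanged to raw CT (HU) and raw
#' MRI (arbitrary-unit) intensities.
#'
#' @param kind one of `"local_noise"`, `"elastic"`, `"kspace"`,
#'   `"anisotropy"`, `"ghosting"`, `"motion"`.
#' @param severity integer level 1-5.
#' @return Named list of the kind's parameters at that level.
#' @export
severity_params <- function(kind, severity) {
  kind <- match.arg(kind, c("local_noise", "elastic", "kspace",
                            "anisotropy", "ghosting", "motion"))
  severity <- as.integer(severity)
  if (severity < 1L || severity > 5L) stop("severity must be in 1..5")
  i <- severity
  switch(kind,
    local_noise = list(noise_sd   = c(0.02, 0.05, 0.1, 0.2, 0.4)[i],  # of range
                       blur_sigma = c(0.5, 1, 2, 4, 8)[i],            # voxels
                       gamma      = c(1.2, 1.5, 2, 3, 5)[i]),
    elastic     = list(max_disp = c(1, 2, 4, 8, 16)[i],               # voxels
                       grid = 8L),
    kspace      = list(amp   = c(0.05, 0.1, 0.25, 0.5, 1.0)[i],       # of sd(v)
                       count = c(1L, 2L, 4L, 8L, 16L)[i]),
    anisotropy  = list(factor = c(2L, 3L, 4L, 6L, 8L)[i]),
    ghosting    = list(w = c(0.05, 0.1, 0.2, 0.35, 0.5)[i],
                       n_ghosts = c(2L, 2L, 3L, 3L, 4L)[i]),
    motion      = list(degrees = c(1, 2, 4, 8, 15)[i],
                       translation = c(0.5, 1, 2, 4, 8)[i],           # voxels
                       n_transforms = 2L))
}

intensity_range <- function(x) {
  r <- max(x) - min(x)
  if (r > 0) r else 1
}

# separable Gaussian blur with replicate padding; sigma in voxels
gauss_blur <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r):r)^2 / (2 * sigma^2)); w <- w / sum(w)
  for (axis in 1:3) {
    n <- dim(a)[axis]
    out <- array(0, dim = dim(a))
    for (t in seq(-r, r)) {
      idx <- pmin(pmax(seq_len(n) + t, 1L), n)
      shifted <- switch(axis, a[idx, , , drop = FALSE],
                        a[, idx, , drop = FALSE], a[, , idx, drop = FALSE])
      out <- out + w[t + r + 1] * shifted
    }
    a <- out
  }
  a
}

circ_shift <- function(a, shift, axis) {
  n <- dim(a)[axis]
  idx <- ((seq_len(n) - 1 - shift) %% n) + 1L
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

#' Local crop corruption (blur / contrast / noise)
#'
#' Emulates a localised acquisition or tissue anomaly: one of three
#' sub-transforms -- Gaussian blur, gamma contrast change or additive
#' Gaussian noise -- is chosen by the seed and applied inside a random
#' axis-aligned crop covering a uniform 10-50% fraction of each axis.
#' Voxels outside the crop are bit-identical to the input.
#'
#' @param v a `Volume` (raw intensities; corruption precedes preprocessing).
#' @param severity integer 1-5.
#' @param seed integer RNG seed; the output is a deterministic function of
#'   `(v, severity, seed)`.
#' @param params optional override of [severity_params()] (e.g. zeroed
#'   magnitudes for identity checks).
#' @return Corrupted `Volume`, same shape and spacing.
#' @export
corrupt_local <- function(v, severity = 3, seed = 1, params = NULL) {
  stopifnot(is_volume(v))
  p <- if (is.null(params)) severity_params("local_noise", severity) else params
  d <- dim(v$data)
  with_seed(seed, {
    variant <- sample(c("blur", "contrast", "noise"), 1)
    frac <- stats::runif(3, 0.1, 0.5)
    len <- pmin(pmax(1L, as.integer(round(frac * d))), d)
    start <- vapply(1:3, function(k) sample.int(d[k] - len[k] + 1L, 1), integer(1))
    ix <- start[1]:(start[1] + len[1] - 1L)
    iy <- start[2]:(start[2] + len[2] - 1L)
    iz <- start[3]:(start[3] + len[3] - 1L)
    crop <- v$data[ix, iy, iz, drop = FALSE]
    crop2 <- switch(variant,
      blur = gauss_blur(crop, p$blur_sigma),
      contrast = {
        lo <- min(crop); hi <- max(crop)
        g <- if (stats::runif(1) < 0.5) p$gamma else 1 / p$gamma
        if (hi > lo && g != 1) lo + (hi - lo) * ((crop - lo) / (hi - lo))^g else crop
      },
      noise = {
        sd_abs <- p$noise_sd * intensity_range(v$data)
        if (sd_abs > 0) crop + array(stats::rnorm(length(crop), 0, sd_abs),
                                     dim = dim(crop)) else crop
      })
    out <- v$data
    out[ix, iy, iz] <- crop2
    volume(out, spacing = v$spacing)
  })
}

#' Elastic deformation corruption
#'
#' Emulates anomalous tissue deformation: a smooth random displacement
#' field is generated on a coarse control grid (offsets drawn uniformly in
#' `[-max_disp, max_disp]` voxels per axis), trilinearly upsampled to full
#' resolution, and the volume is resampled along the displaced coordinates.
#' The displacement magnitude never exceeds the table maximum per axis.
#'
#' @inheritParams corrupt_local
#' @export
corrupt_elastic <- function(v, severity = 3, seed = 1, params = NULL) {
  stopifnot(is_volume(v))
  p <- if (is.null(params)) severity_params("elastic", severity) else params
  d <- dim(v$data)
  g <- as.integer(p$grid)
  if (p$max_disp <= 0) return(v)
  with_seed(seed, {
    ax <- lapply(d, function(n) if (n > 1) (seq_len(n) - 1) / (n - 1) * (g - 1) else 0)
    co <- coord_arrays(d)
    disp <- lapply(1:3, function(k) {
      ctrl <- array(stats::runif(g^3, -p$max_disp, p$max_disp), dim = c(g, g, g))
      trilinear_grid(ctrl, ax[[1]], ax[[2]], ax[[3]])
    })
    out <- trilinear_points(v$data,
                            as.vector(co$x + disp[[1]]),
                            as.vector(co$y + disp[[2]]),
                            as.vector(co$z + disp[[3]]))
    volume(array(out, dim = d), spacing = v$spacing)
  })
}

#' K-space spike (Herringbone) corruption
#'
#' Emulates spike noise in the MRI acquisition domain: the volume's 3D
#' discrete Fourier transform receives complex spikes at random non-DC
#' frequencies, producing global sinusoidal stripe patterns in image
#' space. Each spike's image-domain amplitude is `amp * sd(v)`; the DC bin
#' is untouched, so the mean intensity is preserved.
#'
#' @inheritParams corrupt_local
#' @param spikes optional data.frame with columns `kx, ky, kz` (0-based
#'   frequency indices), `amp` (image-domain amplitude) and `phase`
#'   (radians) for deterministic spike placement; overrides the seeded
#'   draw.
#' @export
corrupt_kspace <- function(v, severity = 3, seed = 1, params = NULL,
                           spikes = NULL) {
  stopifnot(is_volume(v))
  p <- if (is.null(params)) severity_params("kspace", severity) else params
  d <- dim(v$data)
  n_tot <- prod(d)
  if (is.null(spikes)) {
    count <- as.integer(p$count)
    if (count >= 1L && p$amp > 0) {
      spikes <- with_seed(seed, {
        lin <- sample(n_tot - 1L, count)  # 1..n_tot-1, excludes DC (index 0)
        kz <- lin %/% (d[1] * d[2]); rem <- lin %% (d[1] * d[2])
        ky <- rem %/% d[1]; kx <- rem %% d[1]
        data.frame(kx = kx, ky = ky, kz = kz,
                   amp = p$amp * stats::sd(v$data),
                   phase = stats::runif(count, 0, 2 * pi))
      })
    }
  }
  if (is.null(spikes) || nrow(spikes) == 0L) return(v)
  Fv <- stats::fft(v$data)
  for (i in seq_len(nrow(spikes))) {
    ii <- cbind(spikes$kx[i] + 1L, spikes$ky[i] + 1L, spikes$kz[i] + 1L)
    Fv[ii] <- Fv[ii] + spikes$amp[i] * n_tot * exp(1i * spikes$phase[i])
  }
  out <- Re(stats::fft(Fv, inverse = TRUE) / n_tot)
  volume(array(out, dim = d), spacing = v$spacing)
}

# block-mean downsample then linear upsample along one axis (factor f);
# "nearest" subsamples every f-th voxel and block-replicates back, which
# leaves slab-constant volumes unchanged.
aniso_axis <- function(a, axis, f, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  n <- dim(a)[axis]
  f <- min(as.integer(f), n)
  if (f <= 1L) return(a)
  perm <- c(axis, setdiff(1:3, axis))
  b <- aperm(a, perm)
  db <- dim(b)
  bm <- matrix(b, nrow = db[1])
  nd <- ceiling(n / f)
  if (mode == "nearest") {
    down <- bm[seq(1L, by = f, length.out = nd), , drop = FALSE]
    up <- down[pmin(((seq_len(n) - 1L) %/% f) + 1L, nd), , drop = FALSE]
  } else if (nd == 1L) {
    up <- matrix(colMeans(bm), nrow = n, ncol = ncol(bm), byrow = TRUE)
  } else {
    grp <- ((seq_len(n) - 1L) %/% f) + 1L
    down <- rowsum(bm, grp) / as.vector(table(grp))
    centers <- (which(!duplicated(grp)) - 1) + (as.vector(table(grp)) - 1) / 2
    t <- seq_len(n) - 1
    j <- findInterval(t, centers, all.inside = TRUE)
    j <- pmin(j, nd - 1L)
    t0 <- centers[j]; t1 <- centers[j + 1L]
    fr <- ifelse(t1 > t0, (t - t0) / (t1 - t0), 0)
    fr <- pmin(pmax(fr, 0), 1)
    up <- down[j, , drop = FALSE] * (1 - fr) + down[j + 1L, , drop = FALSE] * fr
  }
  out <- array(up, dim = db)
  aperm(out, order(perm))
}

#' Anisotropic resolution corruption
#'
#' Emulates a wrong acquisition resolution: the volume is downsampled by a
#' severity-dependent factor along one seed-chosen axis and upsampled back
#' to the original shape. The default `"linear"` mode uses block-mean
#' downsampling with linear upsampling; `"nearest"` subsamples and
#' block-replicates (and is exactly invariant on slab-constant volumes).
#'
#' @inheritParams corrupt_local
#' @param mode `"linear"` (default) or `"nearest"`.
#' @export
corrupt_anisotropy <- function(v, severity = 3, seed = 1, params = NULL,
                               mode = c("linear", "nearest")) {
  stopifnot(is_volume(v))
  mode <- match.arg(mode)
  p <- if (is.null(params)) severity_params("anisotropy", severity) else params
  axis <- with_seed(seed, sample(1:3, 1))
  volume(aniso_axis(v$data, axis, p$factor, mode), spacing = v$spacing)
}

#' Ghosting corruption
#'
#' Emulates MRI motion ghosts: attenuated circularly shifted copies of the
#' volume are blended with the original along one seed-chosen axis,
#' `out = (1 - w) v + (w/G) sum_g shift(v, g * delta)` with
#' `delta = round(n / (G + 1))`.
#'
#' @inheritParams corrupt_local
#' @export
corrupt_ghosting <- function(v, severity = 3, seed = 1, params = NULL) {
  stopifnot(is_volume(v))
  p <- if (is.null(params)) severity_params("ghosting", severity) else params
  if (p$w <= 0) return(v)
  axis <- with_seed(seed, sample(1:3, 1))
  n <- dim(v$data)[axis]
  G <- as.integer(p$n_ghosts)
  delta <- max(1L, as.integer(round(n / (G + 1))))
  acc <- array(0, dim = dim(v$data))
  for (g in seq_len(G)) acc <- acc + circ_shift(v$data, g * delta, axis)
  out <- (1 - p$w) * v$data + (p$w / G) * acc
  volume(out, spacing = v$spacing)
}

rigid_transform_volume <- function(a, degs, trans) {
  d <- dim(a)
  ctr <- (d - 1) / 2
  th <- degs * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]), 0, -sin(th[1]), cos(th[1])), 3)
  Ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0, sin(th[2]), 0, cos(th[2])), 3)
  Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3)
  R <- Rz %*% Ry %*% Rx
  co <- coord_arrays(d)
  P <- rbind(as.vector(co$x) - ctr[1], as.vector(co$y) - ctr[2],
             as.vector(co$z) - ctr[3])
  # inverse mapping: source = R^-1 (p - t) + c
  S <- t(R) %*% (P - trans)
  out <- trilinear_points(a, S[1, ] + ctr[1], S[2, ] + ctr[2], S[3, ] + ctr[3])
  array(out, dim = d)
}

#' Motion corruption (k-space segment mixing)
#'
#' Emulates mid-acquisition patient motion in the style of the torchIO
#' RandomMotion transform: rigidly perturbed copies of the volume (small
#' random rotations and translations drawn from the severity table) are
#' Fourier-transformed, and contiguous k-space segments along one
#' seed-chosen axis are taken from successive copies (the first segment
#' from the unmoved volume) before inverting back to image space.
#'
#' @inheritParams corrupt_local
#' @export
corrupt_motion <- function(v, severity = 3, seed = 1, params = NULL) {
  stopifnot(is_volume(v))
  p <- if (is.null(params)) severity_params("motion", severity) else params
  d <- dim(v$data)
  if (p$degrees <= 0 && p$translation <= 0) return(v)
  with_seed(seed, {
    Tn <- as.integer(p$n_transforms)
    axis <- sample(1:3, 1)
    Fv <- stats::fft(v$data)
    Fs <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      degs <- stats::runif(3, -p$degrees, p$degrees)
      trans <- stats::runif(3, -p$translation, p$translation)
      Fs[[t]] <- stats::fft(rigid_transform_volume(v$data, degs, trans))
    }
    n <- d[axis]
    bounds <- round(seq(0, n, length.out = Tn + 2))  # Tn + 1 segments
    Fc <- Fv
    for (t in seq_len(Tn)) {
      lo <- bounds[t + 1] + 1L; hi <- bounds[t + 2]
      if (lo > hi) next
      idx <- lo:hi
      if (axis == 1) Fc[idx, , ] <- Fs[[t]][idx, , ]
      else if (axis == 2) Fc[, idx, ] <- Fs[[t]][, idx, ]
      else Fc[, , idx] <- Fs[[t]][, , idx]
    }
    out <- Re(stats::fft(Fc, inverse = TRUE) / prod(d))
    volume(out, spacing = v$spacing)
  })
}

#' Apply a corruption by name
#'
#' Dispatcher over the six corruption kinds; see the individual
#' `corrupt_*` functions.
#'
#' @param v a `Volume`.
#' @param kind corruption kind (see [severity_params()]).
#' @param severity integer 1-5.
#' @param seed integer RNG seed.
#' @return Corrupted `Volume`.
#' @export
corrupt_volume <- function(v, kind, severity = 3, seed = 1) {
  kind <- match.arg(kind, c("local_noise", "elastic", "kspace",
                            "anisotropy", "ghosting", "motion"))
  switch(kind,
    local_noise = corrupt_local(v, severity, seed),
    elastic = corrupt_elastic(v, severity, seed),
    kspace = corrupt_kspace(v, severity, seed),
    anisotropy = corrupt_anisotropy(v, severity, seed),
    ghosting = corrupt_ghosting(v, severity, seed),
    motion = corrupt_motion(v, severity, seed))
}
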