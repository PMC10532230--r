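# Internal numerics shared by preprocessing, corruptions and phantoms.

# Evaluate an expression with a private RNG stream: the global .Random.seed
# is saved and restored, so seeded operations never perturb user code.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Per-axis linear-interpolation weights for sampling a length-n grid at
# (0-based, possibly fractional) coordinates t, clamped to the border.
axis_weights <- function(t, n) {
  t <- pmin(pmax(t, 0), n - 1)
  i0 <- floor(t)
  f <- t - i0
  i0 <- pmin(i0, n - 1)
  i1 <- pmin(i0 + 1, n - 1)
  list(i0 = as.integer(i0) + 1L, i1 = as.integer(i1) + 1L, f = f)
}

# Trilinear interpolation of a 3D array on the tensor grid given by
# per-axis 0-based coordinates tx, ty, tz (vectors). Returns an array of
# dim c(length(tx), length(ty), length(tz)). Border-clamped.
trilinear_grid <- function(a, tx, ty, tz) {
  d <- dim(a)
  wx <- axis_weights(tx, d[1]); wy <- axis_weights(ty, d[2]); wz <- axis_weights(tz, d[3])
  nx <- length(tx); ny <- length(ty); nz <- length(tz)
  fx <- array(wx$f, dim = c(nx, ny, nz))
  fy <- array(rep(wy$f, each = nx), dim = c(nx, ny, nz))
  fz <- array(rep(wz$f, each = nx * ny), dim = c(nx, ny, nz))
  a[wx$i0, wy$i0, wz$i0, drop = FALSE] * (1 - fx) * (1 - fy) * (1 - fz) +
  a[wx$i1, wy$i0, wz$i0, drop = FALSE] * fx       * (1 - fy) * (1 - fz) +
  a[wx$i0, wy$i1, wz$i0, drop = FALSE] * (1 - fx) * fy       * (1 - fz) +
  a[wx$i1, wy$i1, wz$i0, drop = FALSE] * fx       * fy       * (1 - fz) +
  a[wx$i0, wy$i0, wz$i1, drop = FALSE] * (1 - fx) * (1 - fy) * fz +
  a[wx$i1, wy$i0, wz$i1, drop = FALSE] * fx       * (1 - fy) * fz +
  a[wx$i0, wy$i1, wz$i1, drop = FALSE] * (1 - fx) * fy       * fz +
  a[wx$i1, wy$i1, wz$i1, drop = FALSE] * fx       * fy       * fz
}

# Trilinear interpolation at scattered 0-based coordinates (equal-length
# vectors xs, ys, zs). Returns a vector. Border-clamped.
trilinear_points <- function(a, xs, ys, zs) {
  d <- dim(a)
  wx <- axis_weights(xs, d[1]); wy <- axis_weights(ys, d[2]); wz <- axis_weights(zs, d[3])
  lin <- function(i, j, k) a[cbind(i, j, k)]
  fx <- wx$f; fy <- wy$f; fz <- wz$f
  lin(wx$i0, wy$i0, wz$i0) * (1 - fx) * (1 - fy) * (1 - fz) +
  lin(wx$i1, wy$i0, wz$i0) * fx       * (1 - fy) * (1 - fz) +
  lin(wx$i0, wy$i1, wz$i0) * (1 - fx) * fy       * (1 - fz) +
  lin(wx$i1, wy$i1, wz$i0) * fx       * fy       * (1 - fz) +
  lin(wx$i0, wy$i0, wz$i1) * (1 - fx) * (1 - fy) * fz +
  lin(wx$i1, wy$i0, wz$i1) * fx       * (1 - fy) * fz +
  lin(wx$i0, wy$i1, wz$i1) * (1 - fx) * fy       * fz +
  lin(wx$i1, wy$i1, wz$i1) * fx       * fy       * fz
}

# Nearest-neighbour interpolation on a tensor grid (used for masks and for
# slab-preserving anisotropic resampling). Ties round half down toward the
# lower index, matching floor(t + 0.5) on the clamped coordinate.
nearest_grid <- function(a, tx, ty, tz) {
  d <- dim(a)
  idx <- function(t, n) pmin(pmax(as.integer(floor(pmin(pmax(t, 0), n - 1) + 0.5)), 0L), n - 1L) + 1L
  a[idx(tx, d[1]), idx(ty, d[2]), idx(tz, d[3]), drop = FALSE]
}

# 0-based voxel-centre coordinate axes of an output grid of size n_out
# mapped into an input grid: i_out * s_out / s_in.
resample_axis <- function(n_out, s_out, s_in) (seq_len(n_out) - 1) * s_out / s_in

# full 3D coordinate arrays (0-based voxel indices) for a given dim
coord_arrays <- function(d) {
  list(x = array(rep(seq_len(d[1]) - 1, times = d[2] * d[3]), dim = d),
       y = array(rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]), dim = d),
       z = array(rep(seq_len(d[3]) - 1, each = d[1] * d[2]), dim = d))
}
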