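# Low-level separable filters and trilinear sampling shared by the phantom,
# registration, meshing and strain stages.  Everything here works on plain 3D
# arrays in voxel units; callers handle spacing/origin bookkeeping.

# Trilinear interpolation of a 3D array at continuous 1-based voxel
# coordinates.  Outside the lattice either clamp to the edge (clamp = TRUE,
# replicate-edge extrapolation) or return `fill`.
.interp3 <- function(a, x, y, z, fill = 0, clamp = FALSE) {
  d <- dim(a)
  outside <- x < 1 | x > d[1] | y < 1 | y > d[2] | z < 1 | z > d[3]
  if (clamp || any(outside)) {
    x <- pmin(pmax(x, 1), d[1])
    y <- pmin(pmax(y, 1), d[2])
    z <- pmin(pmax(z, 1), d[3])
  }
  x0 <- pmin(floor(x), d[1] - 1L); x0 <- pmax(x0, 1)
  y0 <- pmin(floor(y), d[2] - 1L); y0 <- pmax(y0, 1)
  z0 <- pmin(floor(z), d[3] - 1L); z0 <- pmax(z0, 1)
  if (d[1] == 1L) x0 <- rep(1, length(x))
  if (d[2] == 1L) y0 <- rep(1, length(y))
  if (d[3] == 1L) z0 <- rep(1, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  if (d[1] == 1L) fx <- fx * 0
  if (d[2] == 1L) fy <- fy * 0
  if (d[3] == 1L) fz <- fz * 0
  n1 <- d[1]; n12 <- d[1] * d[2]
  sx <- if (d[1] == 1L) 0L else 1L
  sy <- if (d[2] == 1L) 0L else n1
  sz <- if (d[3] == 1L) 0L else n12
  i000 <- x0 + (y0 - 1) * n1 + (z0 - 1) * n12
  v <- (1 - fx) * (1 - fy) * (1 - fz) * a[i000] +
       fx       * (1 - fy) * (1 - fz) * a[i000 + sx] +
       (1 - fx) * fy       * (1 - fz) * a[i000 + sy] +
       fx       * fy       * (1 - fz) * a[i000 + sx + sy] +
       (1 - fx) * (1 - fy) * fz       * a[i000 + sz] +
       fx       * (1 - fy) * fz       * a[i000 + sx + sz] +
       (1 - fx) * fy       * fz       * a[i000 + sy + sz] +
       fx       * fy       * fz       * a[i000 + sx + sy + sz]
  if (!clamp && any(outside)) v[outside] <- fill
  v
}

# Apply a symmetric 1D kernel along one axis with replicate-edge padding.
.filter_axis <- function(a, k, axis) {
  d <- dim(a)
  n <- d[axis]
  r <- (length(k) - 1L) %/% 2L
  out <- array(0, d)
  base <- seq_len(n)
  for (t in seq_along(k)) {
    ci <- pmin(pmax(base + (t - r - 1L), 1L), n)
    out <- out + k[t] * switch(axis,
      a[ci, , , drop = FALSE],
      a[, ci, , drop = FALSE],
      a[, , ci, drop = FALSE])
  }
  out
}

.gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing (sigma in voxels; replicate-edge padding).
.gauss3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  k <- .gauss_kernel(sigma)
  .filter_axis(.filter_axis(.filter_axis(a, k, 1L), k, 2L), k, 3L)
}

# Windowed (box) sum over the cubic window of the given radius, zero outside
# the grid, i.e. windows truncated at the edges.
.box_axis <- function(a, r, axis) {
  d <- dim(a)
  n <- d[axis]
  out <- array(0, d)
  for (off in -r:r) {
    lo <- max(1L, 1L - off); hi <- min(n, n - off)
    if (lo > hi) next
    dst <- lo:hi
    src <- dst + off
    out <- out + switch(axis,
      {tmp <- array(0, d); tmp[dst, , ] <- a[src, , , drop = FALSE]; tmp},
      {tmp <- array(0, d); tmp[, dst, ] <- a[, src, , drop = FALSE]; tmp},
      {tmp <- array(0, d); tmp[, , dst] <- a[, , src, drop = FALSE]; tmp})
  }
  out
}

.box3 <- function(a, r) .box_axis(.box_axis(.box_axis(a, r, 1L), r, 2L), r, 3L)

# Central-difference gradient along one axis (one-sided at the edges), in
# per-voxel units.
.grad_axis <- function(a, axis) {
  d <- dim(a); n <- d[axis]
  if (n == 1L) return(array(0, d))
  ip <- pmin(seq_len(n) + 1L, n)
  im <- pmax(seq_len(n) - 1L, 1L)
  den <- ip - im
  g <- switch(axis,
    a[ip, , , drop = FALSE] - a[im, , , drop = FALSE],
    a[, ip, , drop = FALSE] - a[, im, , drop = FALSE],
    a[, , ip, drop = FALSE] - a[, , im, drop = FALSE])
  sweep_den <- switch(axis,
    array(den, d),
    aperm(array(den, d[c(2, 1, 3)]), c(2, 1, 3)),
    aperm(array(den, d[c(3, 1, 2)]), c(2, 3, 1)))
  g / sweep_den
}

# Factor-2 decimation with Gaussian anti-aliasing; dims of 1 are kept.
.downsample2 <- function(a) {
  sm <- .gauss3(a, 1)
  d <- dim(a)
  ix <- seq(1L, d[1], by = if (d[1] > 1) 2L else 1L)
  iy <- seq(1L, d[2], by = if (d[2] > 1) 2L else 1L)
  iz <- seq(1L, d[3], by = if (d[3] > 1) 2L else 1L)
  sm[ix, iy, iz, drop = FALSE]
}

# Trilinear upsampling of a coarse array onto a target grid whose coarse
# counterpart was produced by .downsample2 (coarse voxel i maps to fine
# voxel 2i-1).
.upsample_to <- function(a, target_dim) {
  g <- expand.grid(x = seq_len(target_dim[1]), y = seq_len(target_dim[2]),
                   z = seq_len(target_dim[3]))
  cx <- (g$x + 1) / 2; cy <- (g$y + 1) / 2; cz <- (g$z + 1) / 2
  array(.interp3(a, cx, cy, cz, clamp = TRUE), dim = target_dim)
}
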