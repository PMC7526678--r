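# Independent brute-force oracles used to validate the vectorized
# implementations, plus small shared fixtures.

# A compact phantom that meshes in a few thousand elements.
small_geom <- function(...) {
  args <- utils::modifyList(list(grid_shape = c(48L, 48L, 16L),
                                 inner_radius = 3.5, outer_radius = 8,
                                 peripheral_height = 4.5,
                                 inner_height = 1.5),
                            list(...))
  do.call(phantom_geometry, args)
}

# Brute-force windowed Pearson correlation (truncated windows at edges).
brute_lcc <- function(f, m, radius) {
  d <- dim(f)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    ii <- max(1, i - radius):min(d[1], i + radius)
    jj <- max(1, j - radius):min(d[2], j + radius)
    kk <- max(1, k - radius):min(d[3], k + radius)
    fw <- as.vector(f[ii, jj, kk]); mw <- as.vector(m[ii, jj, kk])
    vf <- stats::var(fw); vm <- stats::var(mw)
    out[i, j, k] <- if (vf > 1e-12 && vm > 1e-12)
      stats::cor(fw, mw) else 0
  }
  out
}

# Brute-force Dice on label arrays.
brute_dice <- function(a, b, label) {
  A <- a == label; B <- b == label
  if (sum(A) + sum(B) == 0) return(1)
  2 * sum(A & B) / (sum(A) + sum(B))
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
enum_mann_whitney <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  U_of <- function(ida) {
    ra <- rank(pooled)[ida]
    sum(ra) - n * (n + 1) / 2
  }
  U_obs <- U_of(seq_len(n))
  combs <- utils::combn(length(pooled), n)
  Us <- apply(combs, 2L, U_of)
  mu <- length(a) * length(b) / 2
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
}

# Exact two-sided Wilcoxon signed-rank p by enumeration of sign patterns.
enum_wilcoxon <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% r
  mu <- n * (n + 1) / 4
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
}

# Trilinear interpolation at a single point, written independently.
point_trilinear <- function(a, p) {
  d <- dim(a)
  p <- pmin(pmax(p, 1), d)
  i0 <- pmin(floor(p), d - 1)
  f <- p - i0
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) *
         (if (dy) f[2] else 1 - f[2]) *
         (if (dz) f[3] else 1 - f[3])
    v <- v + w * a[i0[1] + dx, i0[2] + dy, i0[3] + dz]
  }
  v
}
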