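# Independent reference implementations used as oracles. These are written
# for clarity, not speed, and deliberately avoid the package's computational
# paths.

# triple-loop 3x3x3 convolution, zero padding 1; x: (X,Y,Z,cin) array,
# w: (3,3,3,cin,cout) array; stride 1 or 2
conv3d_ref <- function(x, w, stride = 1) {
  d <- dim(x)[1:3]
  cin <- dim(x)[4]
  cout <- dim(w)[5]
  od <- if (stride == 1) d else (d - 1) %/% 2 + 1
  y <- array(0, c(od, cout))
  for (co in seq_len(cout))
    for (oz in seq_len(od[3])) for (oy in seq_len(od[2])) for (ox in seq_len(od[1])) {
      acc <- 0
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        ix <- (ox - 1) * stride + dx + 1
        iy <- (oy - 1) * stride + dy + 1
        iz <- (oz - 1) * stride + dz + 1
        if (ix >= 1 && ix <= d[1] && iy >= 1 && iy <= d[2] && iz >= 1 && iz <= d[3])
          for (ci in seq_len(cin))
            acc <- acc + x[ix, iy, iz, ci] * w[dx + 2, dy + 2, dz + 2, ci, co]
      }
      y[ox, oy, oz, co] <- acc
    }
  y
}

# boundary voxels by definition: foreground with a 6-neighbour outside the
# mask or on the volume border
boundary_ref <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (!mask[x, y, z]) next
    nb <- c(
      x == 1 || !mask[x - 1, y, z], x == d[1] || !mask[x + 1, y, z],
      y == 1 || !mask[x, y - 1, z], y == d[2] || !mask[x, y + 1, z],
      z == 1 || !mask[x, y, z - 1], z == d[3] || !mask[x, y, z + 1])
    out[x, y, z] <- any(nb)
  }
  out
}

# all-pairs brute-force ASSD between two masks
assd_ref <- function(a, b, spacing) {
  pa <- which(boundary_ref(a), arr.ind = TRUE)
  pb <- which(boundary_ref(b), arr.ind = TRUE)
  mm <- function(p) sweep(p - 1, 2, spacing, "*")
  pa <- mm(pa); pb <- mm(pb)
  dmin <- function(from, to) {
    vapply(seq_len(nrow(from)), function(i)
      sqrt(min(colSums((t(to) - from[i, ])^2))), 0)
  }
  mean(c(dmin(pa, pb), dmin(pb, pa)))
}

# exact two-sided signed-rank p-value by full enumeration of sign assignments
wilcoxon_enum_ref <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(m) {
    signs <- bitwAnd(m, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, 0)
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# random blobby mask on a small grid (a few overlapping boxes)
random_mask <- function(dims, n_boxes = 3) {
  m <- array(FALSE, dims)
  for (i in seq_len(n_boxes)) {
    lo <- pmax(1, sapply(dims, function(d) sample.int(d, 1)) - sample(1:3, 3, TRUE))
    hi <- pmin(dims, lo + sample(0:4, 3, TRUE))
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  }
  m
}

# small noise-free phantom used across tests
tiny_phantom <- function(n_muscles = 4, infiltration = 0,
                         grid = c(64, 64, 16), noise = 0, seed = 1, ...) {
  generate_phantom(phantom_config(grid_shape = grid, n_muscles = n_muscles,
                                  infiltration = infiltration,
                                  noise_sigma = noise, seed = seed, ...))
}
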