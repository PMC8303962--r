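# Independent brute-force oracles and shared fixtures for the test suite.
# These deliberately avoid the package's own computational kernels.

# nested-loop trilinear interpolation at a single world point
trilinear_oracle <- function(vol, pt) {
  u <- (pt - vol$origin) / vol$spacing
  d <- dim(vol$voxels)
  if (any(u < 0) || any(u > d - 1)) return(0)
  i0 <- pmin(pmax(floor(u), 0), d - 2)
  f <- u - i0
  s <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
    s <- s + w * vol$voxels[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  s
}

# nested-loop mean squared error
mse_oracle <- function(a, b) {
  d <- dim(a)
  s <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    s <- s + (a[i, j, k] - b[i, j, k])^2
  s / prod(d)
}

# analytic chord length of the segment src->dst through the axis-aligned box
chord_oracle <- function(src, dst, lo, hi) {
  d <- dst - src
  len <- sqrt(sum(d^2))
  u <- d / len
  tmin <- 0; tmax <- len
  for (a in 1:3) {
    if (abs(u[a]) < 1e-12) {
      if (src[a] < lo[a] || src[a] > hi[a]) return(0)
    } else {
      t1 <- (lo[a] - src[a]) / u[a]
      t2 <- (hi[a] - src[a]) / u[a]
      if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp }
      tmin <- max(tmin, t1); tmax <- min(tmax, t2)
    }
  }
  max(0, tmax - tmin)
}

# anisotropic, compactly supported smooth blob used wherever a smooth
# phantom is needed (gradient checks, resampling error bounds)
make_smooth_blob <- function(n = 48, extent = 96, amp = 100,
                             sigmas = c(13, 9, 11), offsets = c(6, -4, 0)) {
  sp <- extent / n
  w <- (n - 1) * sp / 2
  x <- seq(-w, w, length.out = n)
  X <- array(rep(x, times = n * n), c(n, n, n))
  Y <- array(rep(rep(x, each = n), times = n), c(n, n, n))
  Z <- array(rep(x, each = n * n), c(n, n, n))
  f <- amp * exp(-((X - offsets[1])^2 / (2 * sigmas[1]^2) +
                     (Y - offsets[2])^2 / (2 * sigmas[2]^2) +
                     (Z - offsets[3])^2 / (2 * sigmas[3]^2)))
  f[f < 1e-3 * amp / 100] <- 0
  new_volume(f, rep(sp, 3), c(0, 0, 0))
}

# 6-connected region growing from one seed voxel, by vectorized dilation
connected_from_seed <- function(mask, seed_idx) {
  grown <- array(FALSE, dim(mask))
  grown[seed_idx[1], seed_idx[2], seed_idx[3]] <- TRUE
  d <- dim(mask)
  repeat {
    nxt <- grown
    nxt[-1, , ] <- nxt[-1, , ] | grown[-d[1], , ]
    nxt[-d[1], , ] <- nxt[-d[1], , ] | grown[-1, , ]
    nxt[, -1, ] <- nxt[, -1, ] | grown[, -d[2], ]
    nxt[, -d[2], ] <- nxt[, -d[2], ] | grown[, -1, ]
    nxt[, , -1] <- nxt[, , -1] | grown[, , -d[3]]
    nxt[, , -d[3]] <- nxt[, , -d[3]] | grown[, , -1]
    nxt <- nxt & mask
    if (identical(nxt, grown)) break
    grown <- nxt
  }
  grown
}

random_pose <- function(rot = 10, trans = 20) {
  pose_from_degrees(runif(1, -rot, rot), runif(1, -rot, rot), runif(1, -rot, rot),
                    runif(1, -trans, trans), runif(1, -trans, trans),
                    runif(1, -trans, trans))
}
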