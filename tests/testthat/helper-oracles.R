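# Independent oracles used across tests. These deliberately avoid the
# package's own computational paths.

# Exact volume of the {piecewise-linear interpolant >= 1/2} superlevel set on
# the Kuhn triangulation of the padded binary grid: every tetrahedron has unit
# values at its corners, and the enclosed fraction of a tetrahedron depends
# only on how many of its 4 corners are inside: 0, 1/8, 1/2, 7/8, 1.
# This is the exact value the mesh-based estimator must reproduce.
pl_superlevel_volume <- function(mask, spacing) {
  dims <- dim(mask)
  p <- array(0L, dims + 2L)
  p[seq_len(dims[1]) + 1L, seq_len(dims[2]) + 1L, seq_len(dims[3]) + 1L] <-
    as.integer(mask)
  d <- dim(p)
  corner <- function(o) {
    p[(1 + o[1]):(d[1] - 1 + o[1]),
      (1 + o[2]):(d[2] - 1 + o[2]),
      (1 + o[3]):(d[3] - 1 + o[3])]
  }
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  g <- c(0, 1 / 8, 1 / 2, 7 / 8, 1)
  tetvol <- prod(spacing) / 6
  c000 <- corner(c(0, 0, 0))
  c111 <- corner(c(1, 1, 1))
  total <- 0
  for (pm in perms) {
    o1 <- c(0, 0, 0); o1[pm[1]] <- 1
    o2 <- o1; o2[pm[2]] <- 1
    nin <- c000 + corner(o1) + corner(o2) + c111
    total <- total + sum(g[nin + 1]) * tetvol
  }
  total
}

# From-scratch two-way ANOVA sums of squares for the consistency ICC.
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  bms <- k * sum((rowm - gm)^2) / (n - 1)
  resid <- m - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + gm
  ems <- sum(resid^2) / ((n - 1) * (k - 1))
  (bms - ems) / (bms + (k - 1) * ems)
}

# Mid-rank Pearson correlation, written out longhand.
midrank <- function(v) {
  sv <- sort(v)
  vapply(v, function(x) mean(which(sv == x)), numeric(1))
}
pearson_oracle <- function(a, b) {
  ca <- a - mean(a); cb <- b - mean(b)
  sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
}

# Voxelize a union of balls at voxel centers: the same continuous object can
# be rendered at any grid resolution, which makes it the fixture of choice
# for refinement-convergence checks.
ball_union_mask <- function(dims, spacing, centers, radii) {
  gx <- (seq_len(dims[1]) - 0.5) * spacing[1]
  gy <- (seq_len(dims[2]) - 0.5) * spacing[2]
  gz <- (seq_len(dims[3]) - 0.5) * spacing[3]
  mask <- array(FALSE, dims)
  for (b in seq_len(nrow(centers))) {
    dx2 <- (gx - centers[b, 1])^2
    dy2 <- (gy - centers[b, 2])^2
    dz2 <- (gz - centers[b, 3])^2
    mask <- mask | (outer(outer(dx2, dy2, "+"), dz2, "+") <= radii[b]^2)
  }
  mask
}

# Small random smoothed mask for permutation/monotonicity checks.
random_smooth_mask <- function(dims, p = 0.3, seed = 1) {
  withr::with_seed(seed, {
    f <- array(rnorm(prod(dims)), dims)
    for (i in 1:2) {  # cheap smoothing: average with shifted copies
      f <- (f +
              f[c(2:dims[1], dims[1]), , ] + f[c(1, 1:(dims[1] - 1)), , ] +
              f[, c(2:dims[2], dims[2]), ] + f[, c(1, 1:(dims[2] - 1)), ] +
              f[, , c(2:dims[3], dims[3])] + f[, , c(1, 1:(dims[3] - 1))]) / 7
    }
    f >= quantile(f, 1 - p)
  })
}

# Tiny phantom geometry used where full-size volumes are unnecessary.
small_spec <- function(target, seed = 1, ...) {
  phantom_spec(target, voi_extent = c(2.4, 2.4, 2.4), fine_spacing = 0.05,
               seed = seed, ...)
}
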