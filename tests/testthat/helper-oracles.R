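# Independent oracles used by the tests.  These deliberately avoid the
# package's fitting/statistics code paths.

# Exact minimiser of the mono-exponential SSE over a dense 2-D grid of
# (s0, t).  For each candidate t the SSE is a quadratic in s0, so the
# minimum over the discrete s0 grid is attained at the grid point nearest
# the vertex B/A (clamped to the grid ends); evaluating it there is
# algebraically identical to brute-force enumeration of the full grid.
grid_fit_oracle <- function(y, tsl, s0_range = c(80, 120),
                            t_range = c(40, 120), step = 0.01) {
  t_grid <- seq(t_range[1], t_range[2], by = step)
  E <- exp(outer(-tsl, 1 / t_grid))
  A <- colSums(E * E)
  B <- colSums(y * E)
  C <- sum(y * y)
  s0_star <- round((B / A - s0_range[1]) / step) * step + s0_range[1]
  s0_star <- pmin(pmax(s0_star, s0_range[1]), s0_range[2])
  sse <- C - 2 * s0_star * B + s0_star^2 * A
  k <- which.min(sse)
  list(t_ms = t_grid[k], s0 = s0_star[k], sse = sse[k])
}

# Two-sided permutation p-value for the Cochran-Armitage trend statistic:
# scores of items assigned to group 1 under random relabelling.
perm_trend_p <- function(counts, n_perm = 20000, scores = seq_len(ncol(counts))) {
  z <- rep(scores, colSums(counts))
  r1 <- sum(counts[1, ])
  t_obs <- sum(scores * counts[1, ])
  et <- r1 * mean(z)
  t_perm <- vapply(seq_len(n_perm),
                   function(i) sum(sample(z, r1)), numeric(1))
  mean(abs(t_perm - et) >= abs(t_obs - et) - 1e-9)
}

# Elliptical in-plane mask rotated by theta (degrees), as voxel index
# coordinates (ap, si) on an integer grid.
ellipse_coords <- function(a = 16, b = 6, theta_deg = 0, n = 81) {
  g <- expand.grid(ap = seq(-n, n), si = seq(-n, n))
  th <- theta_deg * pi / 180
  u <- cos(th) * g$ap + sin(th) * g$si
  v <- -sin(th) * g$ap + cos(th) * g$si
  as.matrix(g[(u / a)^2 + (v / b)^2 <= 1, ])
}

# Direct second-moment computation (centroid + covariance about it),
# independent of principal_axes().
moment_oracle <- function(coords) {
  ctr <- colMeans(coords)
  X <- sweep(coords, 2, ctr)
  list(centroid = ctr, tensor = crossprod(X) / nrow(X))
}

# Build a disc_segmentation holding one rectangular disc on k slices.
rect_segmentation <- function(n_cols = 20, n_rows = 9, slices = 4,
                              level = 1L, offset_cols = rep(0L, slices)) {
  lab <- array(0L, dim = c(slices, n_rows + 10, n_cols + 10))
  for (s in seq_len(slices)) {
    rows <- 5 + seq_len(n_rows)
    cols <- 5 + offset_cols[s] + seq_len(n_cols)
    lab[s, rows, cols] <- level
  }
  disc_segmentation(lab, spacing_mm = c(4, 1, 1))
}
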