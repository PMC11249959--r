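# Independent oracles and small fixture builders used across tests.

# Brute-force sphere rasterization: exhaustive distance check over the
# whole grid, no bounding box.
brute_force_sphere <- function(center, radius, affine, dim3) {
  mask <- array(FALSE, dim3)
  for (k in seq_len(dim3[3])) for (j in seq_len(dim3[2]))
    for (i in seq_len(dim3[1])) {
      w <- affine %*% c(i - 1, j - 1, k - 1, 1)
      if (sum((w[1:3] - center)^2) <= radius^2) mask[i, j, k] <- TRUE
    }
  mask
}

# Brute-force Benjamini-Hochberg step-up: sort, apply p*(n/rank), enforce
# monotonicity from the largest rank down, cap at 1.
brute_force_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * n / seq_len(n)
  for (i in seq(n - 1, 1, length.out = max(n - 1, 0)))
    adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Uniform tensor field: every voxel carries the same 6-vector
# (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz).
uniform_tensor_volume <- function(comp6, dim3 = c(12L, 12L, 12L),
                                  voxel_mm = 1) {
  arr <- array(rep(comp6, each = prod(dim3)), c(dim3, 6L))
  tensor_volume(arr, dtialps:::centered_affine(dim3, voxel_mm))
}

# Random positive-definite tensor with eigenvalues in [lo, hi] mm^2/s.
random_psd_tensor <- function(lo = 1e-4, hi = 3e-3) {
  A <- matrix(rnorm(9), 3)
  Q <- qr.Q(qr(A))
  lam <- runif(3, lo, hi)
  D <- Q %*% diag(lam) %*% t(Q)
  c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3])
}

# A small ROI set centred inside a grid with a centred affine.
small_roi_set <- function(radius = 3, px = 3, ax = 7) {
  roi_set(
    sphere_roi("projection_left", c(-px, 0, 0), radius),
    sphere_roi("projection_right", c(px, 0, 0), radius),
    sphere_roi("association_left", c(-ax, 0, 0), radius),
    sphere_roi("association_right", c(ax, 0, 0), radius))
}

expect_rel_error <- function(actual, expected, tol) {
  err <- max(abs(actual - expected)) / max(abs(expected))
  expect_lt(err, tol)
}
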