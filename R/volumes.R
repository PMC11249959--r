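# Core volume containers. All world coordinates are RAS millimetres:
# x = left-right (R positive), y = posterior-anterior (A positive),
# z = inferior-superior (S positive). Affines map 0-based voxel indices
# to world mm (NIfTI convention).

TENSOR_COMPONENTS <- c("Dxx", "Dxy", "Dxz", "Dyy", "Dyz", "Dzz")

#' Diffusion-weighted volume
#'
#' Container for a 4-D diffusion-weighted acquisition with its gradient
#' table. Signals are in arbitrary scanner units; b-values in s/mm^2;
#' b-vectors are unit 3-vectors (the zero vector is only allowed where the
#' b-value is 0).
#'
#' @param signal 4-D non-negative numeric array (x, y, z, volume).
#' @param bvals numeric vector, one b-value per volume.
#' @param bvecs numeric matrix with one row per volume and 3 columns
#'   (gradient direction in world axes).
#' @param affine 4x4 voxel-to-world matrix (RAS mm, 0-based indices).
#' @param mask optional logical 3-D array selecting voxels to fit.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(signal, bvals, bvecs, affine, mask = NULL) {
  signal <- as.array(signal)
  if (length(dim(signal)) != 4L)
    stop("`signal` must be a 4-D array (x, y, z, volume)", call. = FALSE)
  nvol <- dim(signal)[4L]
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (length(bvals) != nvol)
    stop(sprintf("length(bvals) [%d] != number of volumes [%d]",
                 length(bvals), nvol), call. = FALSE)
  if (nrow(bvecs) == 3L && ncol(bvecs) == nvol && nvol != 3L)
    bvecs <- t(bvecs)
  if (nrow(bvecs) != nvol || ncol(bvecs) != 3L)
    stop("`bvecs` must be an n_volumes x 3 matrix", call. = FALSE)
  if (any(signal < 0, na.rm = TRUE))
    stop("negative signal values are not allowed", call. = FALSE)
  if (!any(bvals == 0))
    stop("at least one b=0 volume is required", call. = FALSE)
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- which(bvals > 0 & abs(nrm - 1) > 1e-6)
  if (length(bad))
    stop(sprintf("b-vectors of weighted volumes must be unit norm (volumes: %s)",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  if (any(bvals == 0 & nrm > 1e-6 & abs(nrm - 1) > 1e-6))
    stop("b=0 volumes must have zero or unit b-vectors", call. = FALSE)
  check_affine(affine)
  dm <- design_matrix(bvals, bvecs)
  if (qr(dm)$rank < 7L)
    stop("gradient scheme is rank deficient: need at least 6 distinct non-collinear directions with b > 0",
         call. = FALSE)
  if (!is.null(mask)) {
    mask <- array(as.logical(mask), dim = dim(signal)[1:3])
    if (!identical(dim(mask), dim(signal)[1:3]))
      stop("mask shape does not match signal grid", call. = FALSE)
  }
  structure(list(signal = signal, bvals = bvals, bvecs = bvecs,
                 affine = affine, mask = mask),
            class = "dwi_volume")
}

#' Diffusion tensor volume
#'
#' 3-D grid of symmetric diffusion tensors stored as 6 unique components in
#' the order (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz), units mm^2/s, with a
#' voxel-to-world affine. The axis convention is fixed: world x is
#' left-right, y anterior-posterior, z head-foot.
#'
#' @param components 4-D array (x, y, z, 6) of tensor components.
#' @param affine 4x4 voxel-to-world matrix (RAS mm).
#' @param flags optional list of logical 3-D arrays (`unfittable`,
#'   `clamped`) carrying per-voxel fit quality flags.
#' @return An object of class `tensor_volume`.
#' @export
tensor_volume <- function(components, affine, flags = NULL) {
  components <- as.array(components)
  if (length(dim(components)) != 4L || dim(components)[4L] != 6L)
    stop("`components` must be a 4-D array with 6 components (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)",
         call. = FALSE)
  check_affine(affine)
  structure(list(components = components, affine = affine,
                 flags = flags), class = "tensor_volume")
}

#' Scalar map volume
#'
#' @param values 3-D numeric array; dimensionless for FA, mm^2/s for MD.
#' @param affine 4x4 voxel-to-world matrix (RAS mm).
#' @param kind one of "FA", "MD" or "other".
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, affine, kind = c("FA", "MD", "other")) {
  kind <- match.arg(kind)
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  if (kind == "FA" && any(values < -1e-9 | values > 1 + 1e-9, na.rm = TRUE))
    stop("FA values must lie in [0, 1]", call. = FALSE)
  if (kind == "MD" && any(values < -1e-15, na.rm = TRUE))
    stop("MD values must be non-negative", call. = FALSE)
  check_affine(affine)
  structure(list(values = values, affine = affine, kind = kind),
            class = "scalar_volume")
}

check_affine <- function(affine) {
  if (!is.matrix(affine) || !identical(dim(affine), c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix", call. = FALSE)
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("`affine` is singular", call. = FALSE)
  invisible(affine)
}

# Design matrix of the log-linear tensor model:
#   ln S = ln S0 - b g' D g
# columns: (lnS0, Dxx, Dxy, Dxz, Dyy, Dyz, Dzz) matching TENSOR_COMPONENTS.
design_matrix <- function(bvals, bvecs) {
  gx <- bvecs[, 1]; gy <- bvecs[, 2]; gz <- bvecs[, 3]
  cbind(lnS0 = 1,
        Dxx = -bvals * gx * gx,
        Dxy = -2 * bvals * gx * gy,
        Dxz = -2 * bvals * gx * gz,
        Dyy = -bvals * gy * gy,
        Dyz = -2 * bvals * gy * gz,
        Dzz = -bvals * gz * gz)
}

# Flatten tensor components to an n_voxel x 6 matrix.
component_matrix <- function(t) {
  d <- dim(t$components)
  matrix(t$components, nrow = prod(d[1:3]), ncol = 6L,
         dimnames = list(NULL, TENSOR_COMPONENTS))
}

# Analytic eigenvalues of symmetric 3x3 tensors, vectorised over rows of a
# 6-column component matrix. Returns n x 3 matrix, descending order.
tensor_eigenvalues <- function(cm) {
  a <- cm[, 1]; d <- cm[, 2]; e <- cm[, 3]
  b <- cm[, 4]; f <- cm[, 5]; c <- cm[, 6]
  q <- (a + b + c) / 3
  p2 <- (a - q)^2 + (b - q)^2 + (c - q)^2 + 2 * (d^2 + e^2 + f^2)
  p <- sqrt(pmax(p2, 0) / 6)
  l1 <- l2 <- l3 <- q
  nz <- p > 0
  if (any(nz)) {
    aa <- (a[nz] - q[nz]) / p[nz]; bb <- (b[nz] - q[nz]) / p[nz]
    cc <- (c[nz] - q[nz]) / p[nz]
    dd <- d[nz] / p[nz]; ee <- e[nz] / p[nz]; ff <- f[nz] / p[nz]
    detB <- aa * (bb * cc - ff^2) - dd * (dd * cc - ff * ee) +
      ee * (dd * ff - bb * ee)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1[nz] <- q[nz] + 2 * p[nz] * cos(phi)
    l3[nz] <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    l2[nz] <- 3 * q[nz] - l1[nz] - l3[nz]
  }
  cbind(l1, l2, l3)
}

# Build a symmetric 3x3 matrix from a 6-vector in storage order.
tensor_matrix <- function(v) {
  matrix(c(v[1], v[2], v[3],
           v[2], v[4], v[5],
           v[3], v[5], v[6]), 3, 3)
}

tensor_to_vec <- function(m) {
  c(m[1, 1], m[1, 2], m[1, 3], m[2, 2], m[2, 3], m[3, 3])
}

# World coordinates (mm) of all voxel centres, n_voxel x 3, voxel order
# matching R's column-major array layout.
voxel_centers_world <- function(affine, dim3) {
  idx <- as.matrix(expand.grid(i = seq_len(dim3[1]) - 1,
                               j = seq_len(dim3[2]) - 1,
                               k = seq_len(dim3[3]) - 1))
  xyz1 <- cbind(idx, 1) %*% t(affine)
  xyz1[, 1:3, drop = FALSE]
}

# Centre-anchored RAS affine for an isotropic grid: world origin at the
# grid centre so left-hemisphere voxels have x < 0.
centered_affine <- function(dim3, voxel_mm = c(1, 1, 1)) {
  voxel_mm <- rep(voxel_mm, length.out = 3)
  aff <- diag(4)
  diag(aff)[1:3] <- voxel_mm
  aff[1:3, 4] <- -voxel_mm * (dim3 - 1) / 2
  aff
}

#' @exportS3Method base::print
print.tensor_volume <- function(x, ...) {
  d <- dim(x$components)
  cat(sprintf("<tensor_volume> %d x %d x %d voxels, 6 components (mm^2/s)\n",
              d[1], d[2], d[3]))
  if (!is.null(x$flags))
    cat(sprintf("  flagged: %d unfittable, %d clamped\n",
                sum(x$flags$unfittable %||% 0), sum(x$flags$clamped %||% 0)))
  invisible(x)
}

#' @exportS3Method base::print
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<dwi_volume> %d x %d x %d voxels, %d volumes (%d b0, %d weighted)\n",
              d[1], d[2], d[3], d[4], sum(x$bvals == 0), sum(x$bvals > 0)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
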