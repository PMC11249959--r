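# Digital periventricular tensor phantoms with known ground-truth ALPS.
#
# Geometry (world mm, RAS, origin at grid centre): per hemisphere a
# projection-fibre block (head-foot fibres, principal axis z) medial to an
# association-fibre block (anterior-posterior fibres, principal axis y),
# embedded in isotropic background. A perivascular diffusivity increment
# eps is added to Dxx in both fibre regions, emulating fluid movement
# along the left-right medullary veins, so the ground-truth index is
# (lambda_perp + eps) / lambda_perp.

#' Specification of a periventricular tensor phantom
#'
#' @param dim3 grid shape in voxels (default 56 x 36 x 36).
#' @param voxel_mm isotropic voxel size in mm (default 1).
#' @param lambda_par fibre-parallel eigenvalue, mm^2/s (default 1.7e-3).
#' @param lambda_perp fibre-perpendicular eigenvalue, mm^2/s (default 4e-4).
#' @param eps perivascular increment added to Dxx inside both fibre
#'   regions, mm^2/s (default 1.2e-4, giving a ground-truth index of 1.3).
#' @param d_iso isotropic background diffusivity, mm^2/s (default 8e-4).
#' @param tensor_noise_sd SD of Gaussian noise added to the diagonal
#'   tensor entries inside fibre regions (mm^2/s; default 0 = noise-free).
#'   Noisy diagonals are re-projected onto the PSD cone (clamped at 0).
#' @param roi_radius ROI radius in mm (default 5).
#' @param proj_x,assoc_x absolute world-x extents (mm) of the projection
#'   and association blocks; mirrored across the mid-sagittal plane.
#' @param yz_halfwidth half-extent of the fibre blocks in y and z (mm).
#' @param seed integer seed for the noise stream.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim3 = c(56L, 36L, 36L), voxel_mm = 1,
                         lambda_par = 1.7e-3, lambda_perp = 4e-4,
                         eps = 1.2e-4, d_iso = 8e-4,
                         tensor_noise_sd = 0, roi_radius = 5,
                         proj_x = c(2, 12), assoc_x = c(13, 24),
                         yz_halfwidth = 15, seed = 1L) {
  if (!(lambda_par > lambda_perp && lambda_perp > 0))
    stop("need lambda_par > lambda_perp > 0", call. = FALSE)
  if (eps < 0) stop("`eps` must be >= 0", call. = FALSE)
  if (tensor_noise_sd < 0) stop("`tensor_noise_sd` must be >= 0", call. = FALSE)
  if (proj_x[1] >= proj_x[2] || assoc_x[1] >= assoc_x[2] ||
      proj_x[2] > assoc_x[1])
    stop("fibre blocks must satisfy proj_x[1] < proj_x[2] <= assoc_x[1] < assoc_x[2]",
         call. = FALSE)
  structure(list(dim3 = as.integer(dim3), voxel_mm = voxel_mm,
                 lambda_par = lambda_par, lambda_perp = lambda_perp,
                 eps = eps, d_iso = d_iso,
                 tensor_noise_sd = tensor_noise_sd,
                 roi_radius = roi_radius, proj_x = proj_x,
                 assoc_x = assoc_x, yz_halfwidth = yz_halfwidth,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a periventricular tensor phantom
#'
#' Projection regions receive `diag(lambda_perp + eps, lambda_perp,
#' lambda_par)` (+ optional diagonal noise), association regions
#' `diag(lambda_perp + eps, lambda_par, lambda_perp)`, background is
#' isotropic `d_iso`. The returned ground truth is the closed form
#' `(lambda_perp + eps) / lambda_perp` for both hemispheres.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `tensor` ([tensor_volume()]), `fa`
#'   ([scalar_volume()]), `rois` ([roi_set()]), `ground_truth` (list with
#'   `left`, `right`, `mean`) and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d3 <- spec$dim3
  aff <- centered_affine(d3, spec$voxel_mm)
  xyz <- voxel_centers_world(aff, d3)
  ax <- abs(xyz[, 1])
  in_yz <- abs(xyz[, 2]) <= spec$yz_halfwidth &
    abs(xyz[, 3]) <= spec$yz_halfwidth
  proj <- in_yz & ax >= spec$proj_x[1] & ax <= spec$proj_x[2]
  assoc <- in_yz & ax >= spec$assoc_x[1] & ax <= spec$assoc_x[2]

  nvox <- prod(d3)
  cm <- matrix(0, nvox, 6, dimnames = list(NULL, TENSOR_COMPONENTS))
  cm[, "Dxx"] <- cm[, "Dyy"] <- cm[, "Dzz"] <- spec$d_iso
  dxx_fiber <- spec$lambda_perp + spec$eps
  cm[proj, "Dxx"] <- dxx_fiber
  cm[proj, "Dyy"] <- spec$lambda_perp
  cm[proj, "Dzz"] <- spec$lambda_par
  cm[assoc, "Dxx"] <- dxx_fiber
  cm[assoc, "Dyy"] <- spec$lambda_par
  cm[assoc, "Dzz"] <- spec$lambda_perp

  if (spec$tensor_noise_sd > 0) {
    fib <- which(proj | assoc)
    withr_seed(spec$seed, {
      for (comp in c("Dxx", "Dyy", "Dzz"))
        cm[fib, comp] <- cm[fib, comp] +
          rnorm(length(fib), 0, spec$tensor_noise_sd)
    })
    # PSD re-projection: diagonal tensors, so clamp the diagonal at 0
    cm[fib, c("Dxx", "Dyy", "Dzz")] <-
      pmax(cm[fib, c("Dxx", "Dyy", "Dzz")], 0)
  }

  tv <- tensor_volume(array(cm, c(d3, 6L)), aff)
  cx_proj <- mean(spec$proj_x)
  cx_assoc <- mean(spec$assoc_x)
  rois <- roi_set(
    sphere_roi("projection_left", c(-cx_proj, 0, 0), spec$roi_radius),
    sphere_roi("projection_right", c(cx_proj, 0, 0), spec$roi_radius),
    sphere_roi("association_left", c(-cx_assoc, 0, 0), spec$roi_radius),
    sphere_roi("association_right", c(cx_assoc, 0, 0), spec$roi_radius))
  for (r in rois) {
    half <- if (r$region == "projection") spec$proj_x else spec$assoc_x
    fits_x <- abs(r$center[1]) - r$radius >= half[1] &&
      abs(r$center[1]) + r$radius <= half[2]
    fits_yz <- all(abs(r$center[2:3]) + r$radius <= spec$yz_halfwidth)
    if (!fits_x || !fits_yz)
      stop(sprintf("ROI '%s' does not fit inside its fibre region; enlarge the blocks or shrink the radius",
                   r$label), call. = FALSE)
  }
  gt <- (spec$lambda_perp + spec$eps) / spec$lambda_perp
  list(tensor = tv, fa = fa_map(tv), rois = rois,
       ground_truth = list(left = gt, right = gt, mean = gt),
       spec = spec)
}

#' Uniformly spread unit directions (spherical Fibonacci lattice)
#'
#' Deterministic set of approximately uniform gradient directions.
#'
#' @param n number of directions.
#' @return An n x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(n) - 1)
  cbind(r * cos(th), r * sin(th), z)
}

#' Default diffusion acquisition protocol
#'
#' Emulates the multi-site study protocol: `n_b0` unweighted volumes
#' followed by `n_dir` diffusion-weighted volumes at a single b-value of
#' 1000 s/mm^2 (default 5 b0 + 61 directions = 66 volumes; a 4 b0 + 64
#' direction dialect is equally valid input).
#'
#' @param n_b0 number of b = 0 volumes (default 5).
#' @param n_dir number of weighted directions (default 61).
#' @param b b-value in s/mm^2 (default 1000).
#' @return A list with `bvals` and `bvecs` (n x 3).
#' @export
default_protocol <- function(n_b0 = 5, n_dir = 61, b = 1000) {
  list(bvals = c(rep(0, n_b0), rep(b, n_dir)),
       bvecs = rbind(matrix(0, n_b0, 3), fibonacci_directions(n_dir)))
}

#' Simulate diffusion-weighted signals from a tensor volume
#'
#' Noise-free signal `S = S0 * exp(-b g' D g)` per voxel and volume, with
#' optional Rician noise (magnitude of two independent Gaussian channels)
#' or additive Gaussian noise.
#'
#' @param t a [tensor_volume()].
#' @param bvals,bvecs gradient table; defaults to [default_protocol()].
#' @param S0 unweighted signal level (default 1000).
#' @param noise_sd noise standard deviation in signal units (default 0).
#' @param noise `"rician"` (default) or `"gaussian"`.
#' @param seed integer seed used when `noise_sd > 0`.
#' @return A [dwi_volume()].
#' @export
simulate_dwi <- function(t, bvals = NULL, bvecs = NULL, S0 = 1000,
                         noise_sd = 0, noise = c("rician", "gaussian"),
                         seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(inherits(t, "tensor_volume"))
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (is.null(bvals) || is.null(bvecs)) {
    proto <- default_protocol()
    bvals <- bvals %||% proto$bvals
    bvecs <- bvecs %||% proto$bvecs
  }
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) == 3L && ncol(bvecs) == length(bvals) && length(bvals) != 3L)
    bvecs <- t(bvecs)
  cm <- component_matrix(t)
  d3 <- dim(t$components)[1:3]
  nvol <- length(bvals)
  sig <- matrix(0, prod(d3), nvol)
  for (v in seq_len(nvol)) {
    g <- bvecs[v, ]
    quad <- cm[, 1] * g[1]^2 + cm[, 4] * g[2]^2 + cm[, 6] * g[3]^2 +
      2 * (cm[, 2] * g[1] * g[2] + cm[, 3] * g[1] * g[3] +
             cm[, 5] * g[2] * g[3])
    sig[, v] <- S0 * exp(-bvals[v] * quad)
  }
  if (noise_sd > 0) {
    withr_seed(seed, {
      if (noise == "rician") {
        n1 <- matrix(rnorm(length(sig), 0, noise_sd), nrow(sig))
        n2 <- matrix(rnorm(length(sig), 0, noise_sd), nrow(sig))
        sig <- sqrt((sig + n1)^2 + n2^2)
      } else {
        sig <- pmax(sig + matrix(rnorm(length(sig), 0, noise_sd), nrow(sig)),
                    .Machine$double.eps)
      }
    })
  }
  dwi_volume(array(sig, c(d3, nvol)), bvals, bvecs, t$affine)
}

# Run code under a local RNG state.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
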