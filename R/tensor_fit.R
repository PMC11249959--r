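# Diffusion tensor estimation and scalar maps.

#' Fit a diffusion tensor model at each voxel
#'
#' Two-stage log-linear fit of the single-tensor model
#' \eqn{\ln S = \ln S_0 - b\, g^T D g}: an ordinary least-squares pass on the
#' log signals followed by one weighted pass with weights equal to the
#' squared predicted signals (the standard WLS estimator, matching
#' DTIFIT-class behaviour without iterative nonlinear optimisation).
#'
#' Voxels with non-positive signals have the offending volumes excluded; if
#' fewer than 7 usable volumes remain (or the remaining design is rank
#' deficient) the voxel is marked unfittable and its tensor set to zero.
#' Tensors with negative eigenvalues after the fit are clamped to the
#' nearest positive semi-definite tensor (negative eigenvalues set to 0)
#' and flagged.
#'
#' @param dwi a [dwi_volume()].
#' @param method `"wls"` (default, two-stage) or `"ols"` (log-linear only).
#' @return A [tensor_volume()] whose `flags` element carries logical
#'   `unfittable` and `clamped` grids.
#' @export
fit_tensor <- function(dwi, method = c("wls", "ols")) {
  method <- match.arg(method)
  stopifnot(inherits(dwi, "dwi_volume"))
  d4 <- dim(dwi$signal)
  d3 <- d4[1:3]
  nvox <- prod(d3)
  nvol <- d4[4]
  X <- design_matrix(dwi$bvals, dwi$bvecs)

  S <- matrix(dwi$signal, nrow = nvox, ncol = nvol)
  in_mask <- if (is.null(dwi$mask)) rep(TRUE, nvox) else as.vector(dwi$mask)
  unfittable <- rep(FALSE, nvox)

  theta <- matrix(0, nrow = nvox, ncol = 7L,
                  dimnames = list(NULL, colnames(X)))
  pos_ok <- rowSums(S <= 0) == 0L
  batch <- which(in_mask & pos_ok)
  singles <- which(in_mask & !pos_ok)

  XtXinvXt <- solve(crossprod(X), t(X))
  if (length(batch)) {
    Y <- log(t(S[batch, , drop = FALSE]))      # nvol x n
    B <- XtXinvXt %*% Y                        # 7 x n  (OLS)
    if (method == "wls") {
      for (i in seq_along(batch)) {
        y <- Y[, i]
        w <- exp(2 * as.vector(X %*% B[, i]))  # squared predicted signals
        sw <- sqrt(w)
        Xw <- X * sw
        b <- tryCatch(solve(crossprod(Xw), crossprod(Xw, y * sw)),
                      error = function(e) B[, i, drop = FALSE])
        B[, i] <- b
      }
    }
    theta[batch, ] <- t(B)
  }

  for (v in singles) {
    use <- S[v, ] > 0
    if (sum(use) < 7L) { unfittable[v] <- TRUE; next }
    Xv <- X[use, , drop = FALSE]
    if (qr(Xv)$rank < 7L) { unfittable[v] <- TRUE; next }
    y <- log(S[v, use])
    b <- solve(crossprod(Xv), crossprod(Xv, y))
    if (method == "wls") {
      w <- exp(2 * as.vector(Xv %*% b))
      sw <- sqrt(w)
      Xw <- Xv * sw
      b <- tryCatch(solve(crossprod(Xw), crossprod(Xw, y * sw)),
                    error = function(e) b)
    }
    theta[v, ] <- b
  }
  unfit <- !in_mask | unfittable
  theta[unfit, ] <- 0

  cm <- theta[, c("Dxx", "Dxy", "Dxz", "Dyy", "Dyz", "Dzz"), drop = FALSE]
  clamped <- rep(FALSE, nvox)
  fitted <- which(!unfit)
  if (length(fitted)) {
    ev <- tensor_eigenvalues(cm[fitted, , drop = FALSE])
    neg <- fitted[ev[, 3] < 0]
    for (v in neg) {
      es <- eigen(tensor_matrix(cm[v, ]), symmetric = TRUE)
      lam <- pmax(es$values, 0)
      cm[v, ] <- tensor_to_vec(es$vectors %*% (lam * t(es$vectors)))
      clamped[v] <- TRUE
    }
  }

  tensor_volume(array(cm, dim = c(d3, 6L)), dwi$affine,
                flags = list(unfittable = array(unfittable, d3),
                             clamped = array(clamped, d3)))
}

#' Fractional anisotropy map
#'
#' Standard FA from the tensor eigenvalues,
#' \eqn{FA = \sqrt{3/2}\,\lVert\lambda - \bar\lambda\rVert / \lVert\lambda\rVert},
#' evaluated through the rotation-invariant component form (the two are
#' algebraically identical). Zero tensors map to FA = 0.
#'
#' @param t a [tensor_volume()].
#' @return A [scalar_volume()] of kind `"FA"` with values in \[0, 1\].
#' @export
fa_map <- function(t) {
  stopifnot(inherits(t, "tensor_volume"))
  cm <- component_matrix(t)
  md <- (cm[, 1] + cm[, 4] + cm[, 6]) / 3
  dev2 <- (cm[, 1] - md)^2 + (cm[, 4] - md)^2 + (cm[, 6] - md)^2 +
    2 * (cm[, 2]^2 + cm[, 3]^2 + cm[, 5]^2)
  nrm2 <- cm[, 1]^2 + cm[, 4]^2 + cm[, 6]^2 +
    2 * (cm[, 2]^2 + cm[, 3]^2 + cm[, 5]^2)
  fa <- ifelse(nrm2 > 0, sqrt(1.5 * dev2 / nrm2), 0)
  fa <- pmin(pmax(fa, 0), 1)
  scalar_volume(array(fa, dim(t$components)[1:3]), t$affine, "FA")
}

#' Mean diffusivity map
#'
#' MD = trace(D)/3 per voxel, in mm^2/s.
#'
#' @param t a [tensor_volume()].
#' @return A [scalar_volume()] of kind `"MD"`.
#' @export
md_map <- function(t) {
  stopifnot(inherits(t, "tensor_volume"))
  cm <- component_matrix(t)
  md <- (cm[, 1] + cm[, 4] + cm[, 6]) / 3
  scalar_volume(array(md, dim(t$components)[1:3]), t$affine, "MD")
}
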