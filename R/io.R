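# NIfTI and gradient-table I/O. Volumes are written as NIfTI-1 with
# double-precision data so tensor round trips are bitwise exact; on read,
# any volume whose stored orientation is not RAS is reoriented so that
# world x = left-right, y = anterior-posterior, z = head-foot.

#' Read a diffusion-weighted series with its gradient table
#'
#' @param nifti path to a 4-D NIfTI file.
#' @param bval_file path to a whitespace-separated b-value sidecar (one row).
#' @param bvec_file path to a b-vector sidecar; both the FSL dialect
#'   (3 rows x n volumes) and the transposed dialect (n volumes x 3 columns)
#'   are accepted.
#' @param mask optional logical array.
#' @return A [dwi_volume()].
#' @export
read_dwi <- function(nifti, bval_file, bvec_file, mask = NULL) {
  img <- read_ras(nifti)
  arr <- plain_array(img)
  if (length(dim(arr)) != 4L)
    stop(sprintf("format error in '%s': field 'signal' must be 4-D", nifti),
         call. = FALSE)
  nvol <- dim(arr)[4]
  bvals <- scan(bval_file, quiet = TRUE)
  if (length(bvals) != nvol)
    stop(sprintf("format error in '%s': field 'bvals' has %d entries for %d volumes",
                 bval_file, length(bvals), nvol), call. = FALSE)
  bvecs <- parse_bvecs(bvec_file, nvol)
  dwi_volume(arr, bvals, bvecs, affine_of(img), mask = mask)
}

parse_bvecs <- function(path, nvol) {
  rows <- strsplit(trimws(readLines(path, warn = FALSE)), "\\s+")
  rows <- rows[vapply(rows, function(r) length(r) > 0 && nzchar(r[1]), TRUE)]
  m <- tryCatch(do.call(rbind, lapply(rows, as.numeric)),
                warning = function(w) stop(sprintf(
                  "format error in '%s': field 'bvecs' is not numeric", path),
                  call. = FALSE))
  if (nrow(m) == 3L && ncol(m) == nvol) m <- t(m)
  if (nrow(m) != nvol || ncol(m) != 3L)
    stop(sprintf("format error in '%s': field 'bvecs' is %d x %d but %d volumes x 3 expected",
                 path, nrow(m), ncol(m), nvol), call. = FALSE)
  m
}

#' Read / write tensor volumes
#'
#' Tensor volumes are stored as 4-D NIfTI with 6 components in the fixed
#' order (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz), double precision.
#'
#' @param path NIfTI file path.
#' @param t a [tensor_volume()].
#' @return `read_tensor` returns a [tensor_volume()]; `write_tensor`
#'   returns `path` invisibly.
#' @export
read_tensor <- function(path) {
  img <- read_ras(path)
  arr <- plain_array(img)
  if (length(dim(arr)) != 4L || dim(arr)[4] != 6L)
    stop(sprintf("format error in '%s': field 'components' must be 4-D with 6 components",
                 path), call. = FALSE)
  tensor_volume(arr, affine_of(img))
}

#' @rdname read_tensor
#' @export
write_tensor <- function(t, path) {
  stopifnot(inherits(t, "tensor_volume"))
  write_nifti_ras(t$components, t$affine, path)
  invisible(path)
}

#' Read / write scalar maps
#'
#' @param path NIfTI file path.
#' @param s a [scalar_volume()].
#' @param kind scalar kind to assign on read.
#' @return `read_scalar` returns a [scalar_volume()].
#' @export
read_scalar <- function(path, kind = "other") {
  img <- read_ras(path)
  arr <- plain_array(img)
  if (length(dim(arr)) != 3L)
    stop(sprintf("format error in '%s': field 'values' must be 3-D", path),
         call. = FALSE)
  scalar_volume(arr, affine_of(img), kind)
}

#' @rdname read_scalar
#' @export
write_scalar <- function(s, path) {
  stopifnot(inherits(s, "scalar_volume"))
  write_nifti_ras(s$values, s$affine, path)
  invisible(path)
}

#' Write a gradient table in FSL sidecar format
#'
#' @param bvals,bvecs gradient table (bvecs as n x 3 matrix).
#' @param bval_file,bvec_file output paths.
#' @param dialect `"rows"` writes the 3 x n FSL layout, `"cols"` the n x 3
#'   transposed layout.
#' @return invisibly, the two paths.
#' @export
write_gradients <- function(bvals, bvecs, bval_file, bvec_file,
                            dialect = c("rows", "cols")) {
  dialect <- match.arg(dialect)
  writeLines(paste(format(bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), bval_file)
  m <- if (dialect == "rows") t(bvecs) else bvecs
  writeLines(apply(m, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), bvec_file)
  invisible(c(bval_file, bvec_file))
}

read_ras <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  if (!identical(RNifti::orientation(img), "RAS"))
    RNifti::orientation(img) <- "RAS"
  img
}

affine_of <- function(img) {
  aff <- RNifti::xform(img)
  matrix(as.numeric(aff), 4, 4)
}

# Strip RNifti header attributes down to a plain numeric array.
plain_array <- function(img) {
  arr <- as.array(img)
  array(as.numeric(arr), dim = dim(arr))
}

write_nifti_ras <- function(arr, affine, path) {
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  attr(arr, "pixdim") <- c(vox, rep(1, length(dim(arr)) - 3L))
  img <- RNifti::asNifti(arr, datatype = "double", internal = FALSE)
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
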