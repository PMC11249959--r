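# Spherical ROIs in world coordinates.

ROI_LABELS <- c("projection_left", "projection_right",
                "association_left", "association_right")

#' Spherical region of interest
#'
#' A 5 mm sphere (by default) at a world-space centre, labelled as a
#' projection- or association-fibre ROI in the left or right hemisphere.
#' Left-labelled centres must have x < 0 and right-labelled x > 0 in RAS
#' world coordinates.
#'
#' @param label one of `"projection_left"`, `"projection_right"`,
#'   `"association_left"`, `"association_right"`.
#' @param center numeric length-3 world centre (mm).
#' @param radius sphere radius in mm (default 5).
#' @return An object of class `sphere_roi`.
#' @export
sphere_roi <- function(label, center, radius = 5) {
  label <- match.arg(label, ROI_LABELS)
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("`center` must be a finite length-3 vector (mm)", call. = FALSE)
  if (!is.finite(radius) || radius <= 0)
    stop("`radius` must be > 0", call. = FALSE)
  side <- if (grepl("_left$", label)) "left" else "right"
  if (side == "left" && center[1] >= 0)
    stop(sprintf("ROI '%s' must have a centre with x < 0 (got x = %g)",
                 label, center[1]), call. = FALSE)
  if (side == "right" && center[1] <= 0)
    stop(sprintf("ROI '%s' must have a centre with x > 0 (got x = %g)",
                 label, center[1]), call. = FALSE)
  structure(list(label = label, center = center, radius = radius,
                 side = side,
                 region = if (grepl("^projection", label)) "projection" else "association"),
            class = "sphere_roi")
}

#' The four-ROI set of the ALPS scheme
#'
#' Exactly one projection and one association ROI per hemisphere.
#'
#' @param ... four [sphere_roi()] objects (or a single list of them).
#' @return An object of class `roi_set`: a named list keyed by label.
#' @export
roi_set <- function(...) {
  rois <- list(...)
  if (length(rois) == 1L && !inherits(rois[[1]], "sphere_roi"))
    rois <- rois[[1]]
  labels <- vapply(rois, function(r) r$label, "")
  if (!setequal(labels, ROI_LABELS) || anyDuplicated(labels))
    stop("roi_set requires exactly one ROI for each of: ",
         paste(ROI_LABELS, collapse = ", "), call. = FALSE)
  names(rois) <- labels
  for (side in c("left", "right")) {
    p <- rois[[paste0("projection_", side)]]$center
    a <- rois[[paste0("association_", side)]]$center
    if (all(abs(p - a) < 1e-9))
      stop(sprintf("projection and association centres coincide in the %s hemisphere",
                   side), call. = FALSE)
  }
  structure(rois[ROI_LABELS], class = "roi_set")
}

#' Rasterize a spherical ROI onto a voxel grid
#'
#' A voxel is included iff the Euclidean distance from its world-space
#' centre point to the ROI centre is <= the radius (voxel-centre-in-sphere
#' rule with closed boundary).
#'
#' @param roi a [sphere_roi()].
#' @param affine 4x4 voxel-to-world matrix of the target grid.
#' @param dim3 integer length-3 grid shape.
#' @return A logical 3-D array mask.
#' @export
rasterize_sphere <- function(roi, affine, dim3) {
  stopifnot(inherits(roi, "sphere_roi"))
  check_affine(affine)
  dim3 <- as.integer(dim3)
  inv <- solve(affine)
  cvox <- as.vector(inv %*% c(roi$center, 1))[1:3]        # 0-based index
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  lo <- pmax(floor(cvox - roi$radius / vox) - 1, 0)
  hi <- pmin(ceiling(cvox + roi$radius / vox) + 1, dim3 - 1)
  mask <- array(FALSE, dim3)
  if (any(hi < lo))
    stop(sprintf("ROI '%s' lies entirely outside the grid", roi$label),
         call. = FALSE)
  ii <- seq.int(lo[1], hi[1]); jj <- seq.int(lo[2], hi[2])
  kk <- seq.int(lo[3], hi[3])
  idx <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  xyz <- cbind(idx, 1) %*% t(affine)
  d2 <- (xyz[, 1] - roi$center[1])^2 + (xyz[, 2] - roi$center[2])^2 +
    (xyz[, 3] - roi$center[3])^2
  inside <- d2 <= roi$radius^2
  if (!any(inside))
    stop(sprintf("ROI '%s' contains no voxel centres on this grid", roi$label),
         call. = FALSE)
  mask[idx[inside, , drop = FALSE] + 1L] <- TRUE
  mask
}

#' Read / write an ROI set as a structured config block
#'
#' The YAML layout is a mapping from label to `{center: [x, y, z], radius}`.
#'
#' @param x a [roi_set()] or (for reading) a file path or parsed list.
#' @param path output file.
#' @return `roi_set_from_config` returns a [roi_set()].
#' @export
roi_set_from_config <- function(x) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  if (!is.null(x$rois)) x <- x$rois
  rois <- lapply(names(x), function(lab)
    sphere_roi(lab, unlist(x[[lab]]$center), x[[lab]]$radius %||% 5))
  roi_set(rois)
}

#' @rdname roi_set_from_config
#' @export
write_roi_config <- function(x, path) {
  stopifnot(inherits(x, "roi_set"))
  block <- lapply(x, function(r) list(center = r$center, radius = r$radius))
  yaml::write_yaml(list(rois = block), path)
  invisible(path)
}

#' @exportS3Method base::print
print.roi_set <- function(x, ...) {
  cat("<roi_set>\n")
  for (r in x)
    cat(sprintf("  %-18s centre (%6.1f, %6.1f, %6.1f) mm, radius %.1f mm\n",
                r$label, r$center[1], r$center[2], r$center[3], r$radius))
  invisible(x)
}
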