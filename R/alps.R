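# DTI-ALPS index computation and placement quality control.

#' Mean axis diffusivities within a mask
#'
#' Arithmetic mean of the tensor diagonal entries (Dxx, Dyy, Dzz, world
#' axes) over in-mask voxels. Voxels with non-finite diagonals are excluded
#' and counted; if all voxels are excluded an error is raised.
#'
#' @param t a [tensor_volume()].
#' @param mask logical 3-D array on the same grid.
#' @return A list with `dxx`, `dyy`, `dzz` (mm^2/s), `n_voxels` used and
#'   `n_excluded`.
#' @export
extract_axis_diffusivities <- function(t, mask) {
  stopifnot(inherits(t, "tensor_volume"))
  d3 <- dim(t$components)[1:3]
  if (!identical(dim(mask), d3))
    stop("mask and tensor volume are on different grids", call. = FALSE)
  idx <- which(as.vector(mask))
  if (!length(idx)) stop("mask is empty", call. = FALSE)
  cm <- component_matrix(t)[idx, , drop = FALSE]
  ok <- is.finite(cm[, "Dxx"]) & is.finite(cm[, "Dyy"]) & is.finite(cm[, "Dzz"])
  if (!any(ok))
    stop("all in-mask voxels have non-finite diffusivities", call. = FALSE)
  list(dxx = mean(cm[ok, "Dxx"]), dyy = mean(cm[ok, "Dyy"]),
       dzz = mean(cm[ok, "Dzz"]),
       n_voxels = sum(ok), n_excluded = sum(!ok))
}

#' Default thresholds for automated ROI placement QC
#'
#' A reproducible proxy for the visual inspection used in ALPS studies:
#' an ROI fails if its mean FA is below `fa_min`, if fewer than `align_min`
#' of its voxels have a principal eigenvector within `cone_deg` degrees of
#' the expected fibre axis (projection: z; association: y), or if it
#' contains fewer than `count_min` voxels.
#'
#' @param fa_min minimum mean FA (default 0.15).
#' @param align_min minimum aligned-voxel fraction (default 0.5).
#' @param cone_deg alignment cone half-angle in degrees (default 30).
#' @param count_min minimum voxel count (default 10).
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(fa_min = 0.15, align_min = 0.5, cone_deg = 30,
                          count_min = 10) {
  list(fa_min = fa_min, align_min = align_min, cone_deg = cone_deg,
       count_min = count_min)
}

#' Automated QC of ROI placement
#'
#' @param fa a [scalar_volume()] of kind FA on the tensor grid.
#' @param t the [tensor_volume()].
#' @param rois a [roi_set()].
#' @param thresholds see [qc_thresholds()].
#' @return An object of class `qc_report`: per-ROI mean FA, alignment
#'   fraction and voxel count, overall `pass` flag and `reasons` codes.
#' @export
qc_placement <- function(fa, t, rois, thresholds = qc_thresholds()) {
  stopifnot(inherits(fa, "scalar_volume"), inherits(t, "tensor_volume"),
            inherits(rois, "roi_set"))
  d3 <- dim(t$components)[1:3]
  if (!identical(dim(fa$values), d3))
    stop("FA map and tensor volume are on different grids", call. = FALSE)
  cos_min <- cos(thresholds$cone_deg * pi / 180)
  cm <- component_matrix(t)
  per_roi <- list()
  reasons <- character()
  for (r in rois) {
    mask <- rasterize_sphere(r, t$affine, d3)
    idx <- which(as.vector(mask))
    axis <- if (r$region == "projection") c(0, 0, 1) else c(0, 1, 0)
    aligned <- vapply(idx, function(v) {
      es <- eigen(tensor_matrix(cm[v, ]), symmetric = TRUE)
      v1 <- es$vectors[, 1]
      abs(sum(v1 * axis)) >= cos_min
    }, TRUE)
    stats <- list(label = r$label,
                  mean_fa = mean(fa$values[idx]),
                  align_fraction = mean(aligned),
                  n_voxels = length(idx))
    if (stats$mean_fa < thresholds$fa_min)
      reasons <- c(reasons, paste0("low_fa:", r$label))
    if (stats$align_fraction < thresholds$align_min)
      reasons <- c(reasons, paste0("misaligned:", r$label))
    if (stats$n_voxels < thresholds$count_min)
      reasons <- c(reasons, paste0("too_few_voxels:", r$label))
    per_roi[[r$label]] <- stats
  }
  structure(list(per_roi = per_roi, pass = length(reasons) == 0L,
                 reasons = reasons, thresholds = thresholds),
            class = "qc_report")
}

#' Compute the DTI-ALPS indices
#'
#' For each hemisphere the index is
#' `mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)`, where the
#' numerator collects left-right (perivascular-axis) diffusivities and the
#' denominator the fibre-perpendicular diffusivities of the projection
#' (head-foot fibres) and association (anterior-posterior fibres) regions.
#' The bilateral index is the average of the left and right indices.
#'
#' @param t a [tensor_volume()] co-registered with the ROI coordinates.
#' @param rois a [roi_set()].
#' @param fa optional FA [scalar_volume()]; computed from `t` when `NULL`.
#' @param qc logical; run [qc_placement()] (default TRUE). A QC failure
#'   does not suppress the indices, it flags the result.
#' @param thresholds QC thresholds, see [qc_thresholds()].
#' @return An object of class `alps_result` with per-ROI mean axis
#'   diffusivities, voxel counts, `alps_left`, `alps_right`, `alps_mean`
#'   and the attached `qc_report`.
#' @export
compute_alps <- function(t, rois, fa = NULL, qc = TRUE,
                         thresholds = qc_thresholds()) {
  stopifnot(inherits(t, "tensor_volume"), inherits(rois, "roi_set"))
  d3 <- dim(t$components)[1:3]
  diff_means <- list()
  counts <- integer()
  for (r in rois) {
    mask <- rasterize_sphere(r, t$affine, d3)
    diff_means[[r$label]] <- extract_axis_diffusivities(t, mask)
    counts[[r$label]] <- diff_means[[r$label]]$n_voxels
  }
  index_for <- function(side) {
    proj <- diff_means[[paste0("projection_", side)]]
    asso <- diff_means[[paste0("association_", side)]]
    num <- mean(c(proj$dxx, asso$dxx))
    den <- mean(c(proj$dyy, asso$dzz))
    if (!is.finite(den) || den <= 0)
      stop(sprintf("non-positive denominator diffusivity in the %s hemisphere (projection_%s / association_%s)",
                   side, side, side), call. = FALSE)
    list(index = num / den,
         dxx_proj = proj$dxx, dxx_assoc = asso$dxx,
         dyy_proj = proj$dyy, dzz_assoc = asso$dzz)
  }
  left <- index_for("left")
  right <- index_for("right")
  report <- if (qc) {
    fa <- fa %||% fa_map(t)
    qc_placement(fa, t, rois, thresholds)
  } else NULL
  structure(list(
    alps_left = left$index, alps_right = right$index,
    alps_mean = (left$index + right$index) / 2,
    diffusivities = list(left = left[-1], right = right[-1]),
    voxel_counts = counts,
    qc = report), class = "alps_result")
}

#' @exportS3Method base::print
print.alps_result <- function(x, ...) {
  cat(sprintf("<alps_result>  left %.4f  right %.4f  bilateral mean %.4f\n",
              x$alps_left, x$alps_right, x$alps_mean))
  if (!is.null(x$qc))
    cat(sprintf("  QC: %s%s\n", if (x$qc$pass) "pass" else "FAIL",
                if (length(x$qc$reasons))
                  paste0(" (", paste(x$qc$reasons, collapse = ", "), ")")
                else ""))
  invisible(x)
}

#' Flatten an ALPS result to a one-row data frame
#'
#' @param x an `alps_result`.
#' @param row.names,optional,... passed over from the generic, unused.
#' @return A one-row data frame suitable for per-subject CSV output.
#' @export
as.data.frame.alps_result <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  d <- x$diffusivities
  data.frame(
    alps_left = x$alps_left, alps_right = x$alps_right,
    alps_mean = x$alps_mean,
    dxx_proj_left = d$left$dxx_proj, dxx_assoc_left = d$left$dxx_assoc,
    dyy_proj_left = d$left$dyy_proj, dzz_assoc_left = d$left$dzz_assoc,
    dxx_proj_right = d$right$dxx_proj, dxx_assoc_right = d$right$dxx_assoc,
    dyy_proj_right = d$right$dyy_proj, dzz_assoc_right = d$right$dzz_assoc,
    qc_pass = if (is.null(x$qc)) NA else x$qc$pass,
    qc_reasons = if (is.null(x$qc)) "" else paste(x$qc$reasons, collapse = ";"),
    stringsAsFactors = FALSE)
}

#' Serialize an ALPS result (with QC report) to JSON
#'
#' @param x an `alps_result`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
alps_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "alps_result"))
  payload <- list(
    alps_left = x$alps_left, alps_right = x$alps_right,
    alps_mean = x$alps_mean, diffusivities = x$diffusivities,
    voxel_counts = as.list(x$voxel_counts),
    qc = if (is.null(x$qc)) NULL else
      list(pass = x$qc$pass, reasons = x$qc$reasons,
           per_roi = x$qc$per_roi))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
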