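#' Segmentation parameters
#'
#' Parameters of the bone isolation chain: median denoising, contrast-based
#' (Bernsen) local thresholding, largest-connected-component extraction and
#' the condyle cut plane. Defaults follow the processing chain the pipeline
#' models: median kernel 2, local window 50 voxels, 26-connectivity. The
#' contrast threshold must sit between the internal cortical/trabecular grey
#' contrast and the bone/background contrast of the data at hand.
#'
#' @param median_radius Spherical median filter radius, voxels (>= 1).
#' @param window Local threshold window edge length, voxels (>= 3).
#' @param contrast Contrast threshold in grey units.
#' @param connectivity 6, 18 or 26.
#' @param cut_fraction Fraction of the bone's long-axis extent retained by
#'   [crop_condyle()], in (0, 1].
#' @param cut_side `"low"` or `"high"`: which end of the long axis is distal.
#' @param slicewise Run the local threshold with in-plane (2D) windows?
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(median_radius = 2, window = 50, contrast = 1000,
                                connectivity = 26, cut_fraction = 1,
                                cut_side = c("low", "high"), slicewise = FALSE) {
  if (median_radius < 1) stop("`median_radius` must be >= 1", call. = FALSE)
  if (window < 3) stop("`window` must be >= 3", call. = FALSE)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  if (cut_fraction <= 0 || cut_fraction > 1)
    stop("`cut_fraction` must lie in (0, 1]", call. = FALSE)
  structure(list(
    median_radius = as.integer(median_radius), window = as.integer(window),
    contrast = contrast, connectivity = as.integer(connectivity),
    cut_fraction = cut_fraction, cut_side = match.arg(cut_side),
    slicewise = isTRUE(slicewise)
  ), class = "segmentation_params")
}

#' Median denoising over a spherical neighbourhood
#'
#' Each voxel is replaced by the median of the values within a spherical
#' neighbourhood of the given radius (all offsets with squared norm
#' `<= radius^2`, 33 voxels at radius 2); boundary voxels use the truncated
#' neighbourhood.
#'
#' @param grid A [voxel_grid()].
#' @param radius Radius in voxels (>= 1).
#' @return The filtered [voxel_grid()].
#' @export
median_denoise <- function(grid, radius = 2) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (radius < 1) stop("`radius` must be >= 1", call. = FALSE)
  out <- cpp_median_filter(grid$values, dim(grid), as.integer(radius))
  dim(out) <- dim(grid)
  with_values(grid, out)
}

#' Contrast-based (Bernsen) local thresholding
#'
#' For each voxel, let `lo`/`hi` be the minimum and maximum within the
#' centred cubic window. Where the local contrast `hi - lo` reaches the
#' contrast threshold, the voxel is foreground when its value is at least
#' the local mid-grey `(hi + lo) / 2`. Low-contrast regions are classified
#' wholesale: foreground when their local mid-grey exceeds the volume's
#' global mid-grey (midpoint of the 0.5% and 99.5% intensity quantiles).
#'
#' @param grid A [voxel_grid()] (typically median-denoised CT).
#' @param window Window edge length in voxels (>= 3).
#' @param contrast Contrast threshold in grey units.
#' @param slicewise Use in-plane 2D windows (per k-slice)?
#' @return A logical-valued [voxel_grid()].
#' @export
local_threshold <- function(grid, window = 50, contrast = 1000, slicewise = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (window < 3) stop("`window` must be >= 3", call. = FALSE)
  mm <- cpp_local_minmax(grid$values, dim(grid), as.integer(window), isTRUE(slicewise))
  lo <- mm$lo; hi <- mm$hi
  mid <- (hi + lo) / 2
  # robust global mid-grey: midpoint of the 0.5% and 99.5% quantiles, so a
  # handful of extreme noise voxels cannot shift the low-contrast fallback
  qq <- stats::quantile(grid$values, c(0.005, 0.995), names = FALSE)
  global_mid <- (qq[1] + qq[2]) / 2
  v <- as.numeric(grid$values)
  fg <- ifelse(hi - lo >= contrast, v >= mid, mid > global_mid)
  with_values(grid, array(fg, dim(grid)))
}

#' Keep only the largest connected component
#'
#' Components are found under the chosen connectivity; ties in size are
#' broken in favour of the component containing the lowest linear voxel
#' index. An empty input yields an empty output.
#'
#' @param mask A logical-valued [voxel_grid()].
#' @param connectivity 6, 18 or 26.
#' @return A logical-valued [voxel_grid()].
#' @export
largest_component <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "voxel_grid"))
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  m <- as.logical(mask$values)
  if (!any(m)) return(with_values(mask, array(FALSE, dim(mask))))
  labels <- cpp_label_components(array(m, dim(mask)), dim(mask), as.integer(connectivity))
  sizes <- tabulate(labels)
  best <- which(sizes == max(sizes))[1] # labels are in scan order: first wins ties
  with_values(mask, array(labels == best, dim(mask)))
}

#' Crop a bone mask to its distal portion
#'
#' Places an axis-aligned cut plane at `fraction` of the mask's bounding-box
#' extent along its long axis (the bounding-box axis of maximal physical
#' extent) and keeps the voxels on the distal side (`cut_side`). Replaces
#' the manual diaphysis removal of an interactive workflow with a
#' reproducible parametric cut.
#'
#' @param mask A non-empty logical-valued [voxel_grid()].
#' @param fraction Fraction of the long-axis extent retained, in (0, 1].
#' @param cut_side `"low"` (keep the low-coordinate end, default) or `"high"`.
#' @return The cropped mask.
#' @export
crop_condyle <- function(mask, fraction, cut_side = c("low", "high")) {
  stopifnot(inherits(mask, "voxel_grid"))
  cut_side <- match.arg(cut_side)
  if (fraction <= 0 || fraction > 1)
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  m <- array(as.logical(mask$values), dim(mask))
  if (!any(m)) stop("empty mask", call. = FALSE)
  if (fraction == 1) return(mask)
  d <- dim(mask)
  present <- list(
    which(apply(m, 1, any)), which(apply(m, 2, any)), which(apply(m, 3, any))
  )
  extent <- vapply(1:3, function(a) {
    (max(present[[a]]) - min(present[[a]])) * mask$spacing[a]
  }, numeric(1))
  axis <- which.max(extent)
  lohi <- range(present[[axis]])
  span <- lohi[2] - lohi[1]
  keep <- if (cut_side == "low") {
    seq_len(d[axis]) <= lohi[1] + fraction * span
  } else {
    seq_len(d[axis]) >= lohi[2] - fraction * span
  }
  out <- m
  if (axis == 1) out[!keep, , ] <- FALSE
  else if (axis == 2) out[, !keep, ] <- FALSE
  else out[, , !keep] <- FALSE
  if (!any(out)) stop("cut removes all voxels", call. = FALSE)
  with_values(mask, out)
}

#' Run the full bone segmentation chain
#'
#' Median denoising, Bernsen local thresholding and largest-component
#' extraction, optionally followed by the condyle crop when
#' `params$cut_fraction < 1`.
#'
#' @param ct CT [voxel_grid()].
#' @param params A [segmentation_params()].
#' @return List with `bone` (full segmented mask) and `roi` (after the
#'   condyle crop; identical to `bone` when `cut_fraction = 1`).
#' @export
segment_bone <- function(ct, params = segmentation_params()) {
  stopifnot(inherits(ct, "voxel_grid"), inherits(params, "segmentation_params"))
  den <- median_denoise(ct, params$median_radius)
  bin <- local_threshold(den, params$window, params$contrast, params$slicewise)
  bone <- largest_component(bin, params$connectivity)
  roi <- if (params$cut_fraction < 1) {
    crop_condyle(bone, params$cut_fraction, params$cut_side)
  } else {
    bone
  }
  list(bone = bone, roi = roi)
}
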