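#' Resample a volume onto a reference geometry
#'
#' Every output voxel takes the value of `moving` at the world point obtained
#' by mapping the output voxel centre through `transform` (reference world to
#' moving world). Points falling outside `moving` receive `fill`. Linear
#' interpolation is the default; use `"nearest"` for masks and label maps.
#'
#' @param moving A [voxel_grid()] supplying values.
#' @param transform An [affine3d()] mapping reference world coordinates into
#'   the moving world frame (identity by default).
#' @param reference A [voxel_grid()] supplying the output geometry
#'   (defaults to `moving`).
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill Value for points outside the moving volume (default 0,
#'   the background level of masked CT/MR data).
#' @return A [voxel_grid()] with the geometry of `reference`.
#' @export
resample <- function(moving, transform = identity_affine(), reference = moving,
                     interpolation = c("linear", "nearest"), fill = 0) {
  stopifnot(inherits(moving, "voxel_grid"), inherits(reference, "voxel_grid"),
            inherits(transform, "affine3d"))
  interpolation <- match.arg(interpolation)
  map <- index_map(reference, transform, moving)
  d <- dim(reference)
  idx <- index_vectors(d)
  ui <- map$m[1, 1] * idx$i + map$m[1, 2] * idx$j + map$m[1, 3] * idx$k + map$b[1]
  uj <- map$m[2, 1] * idx$i + map$m[2, 2] * idx$j + map$m[2, 3] * idx$k + map$b[2]
  uk <- map$m[3, 1] * idx$i + map$m[3, 2] * idx$j + map$m[3, 3] * idx$k + map$b[3]
  mv <- moving$values
  if (is.logical(mv)) mv <- array(as.numeric(mv), dim(mv))
  out <- if (interpolation == "linear") {
    cpp_sample_trilinear(mv, dim(moving), ui, uj, uk, fill)
  } else {
    cpp_sample_nearest(mv, dim(moving), ui, uj, uk, fill)
  }
  dim(out) <- d
  if (is.logical(moving$values)) {
    out <- array(out > 0.5, d)
  }
  voxel_grid(out, reference$spacing, reference$origin, reference$direction)
}

# Combined affine taking 0-based reference indices to continuous 0-based
# moving indices: u = m %*% ijk + b.
index_map <- function(reference, transform, moving) {
  a_ref <- reference$direction %*% diag(reference$spacing) # index -> world
  a_mov_inv <- diag(1 / moving$spacing) %*% t(moving$direction) # world -> index
  m <- a_mov_inv %*% transform$matrix %*% a_ref
  b <- drop(a_mov_inv %*% (transform$matrix %*% reference$origin +
                             transform$translation - moving$origin))
  list(m = m, b = b)
}

#' Downsample a grid by block averaging
#'
#' Averages `factor`^3 blocks (trailing partial blocks use the voxels
#' present), multiplying the spacing by `factor`. Used for the registration
#' pyramid.
#'
#' @param grid A [voxel_grid()].
#' @param factor Positive integer.
#' @return A coarser [voxel_grid()].
#' @export
downsample_grid <- function(grid, factor) {
  stopifnot(inherits(grid, "voxel_grid"), factor >= 1)
  factor <- as.integer(factor)
  if (factor == 1L) return(grid)
  vals <- grid$values
  if (is.logical(vals)) vals <- array(as.numeric(vals), dim(vals))
  out <- cpp_block_mean(vals, dim(grid), factor)
  # new voxel (0,0,0) centre sits at the centroid of the first block
  shift <- drop(grid$direction %*% ((factor - 1) / 2 * grid$spacing))
  voxel_grid(out, grid$spacing * factor, grid$origin + shift, grid$direction)
}
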