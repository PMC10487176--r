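#' 3D voxel grid with world-space geometry
#'
#' The common carrier for CT, BMD, MR echo, porosity-index and mask volumes.
#' A `voxel_grid` couples a 3D array (index order `(i, j, k)`, `i` fastest,
#' 0-based in all world-coordinate formulas) with voxel spacing in mm, the
#' world position of the centre of voxel `(0, 0, 0)`, and an orthonormal
#' direction matrix. World coordinates of voxel `(i, j, k)` are
#' `origin + direction %*% (c(i, j, k) * spacing)`.
#'
#' @param values 3D numeric or logical array.
#' @param spacing Positive length-3 numeric, voxel size in mm per axis.
#' @param origin Length-3 numeric, world mm coordinates of the centre of
#'   voxel `(0, 0, 0)`.
#' @param direction 3x3 orthonormal matrix mapping index axes to world axes.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(0, c(8, 8, 8)), spacing = c(0.273, 0.273, 0.4))
#' dim(g)
#' @export
voxel_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       direction = diag(3)) {
  if (!is.array(values) || length(dim(values)) != 3L || length(values) == 0L)
    stop("`values` must be a non-empty 3D array", call. = FALSE)
  if (!is.numeric(values) && !is.logical(values))
    stop("`values` must be numeric or logical", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers", call. = FALSE)
  direction <- as.matrix(direction)
  if (!all(dim(direction) == c(3L, 3L)) ||
      max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("`direction` must be a 3x3 orthonormal matrix", call. = FALSE)
  structure(
    list(values = values, spacing = spacing, origin = origin, direction = direction),
    class = "voxel_grid"
  )
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

#' @export
as.array.voxel_grid <- function(x, ...) x$values

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<voxel_grid> %d x %d x %d (%s)\n", d[1], d[2], d[3],
              if (is.logical(x$values)) "logical" else "numeric"))
  cat(sprintf("  spacing: %s mm\n", paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  origin : (%s) mm\n", paste(signif(x$origin, 4), collapse = ", ")))
  if (is.logical(x$values)) {
    cat(sprintf("  true voxels: %d\n", sum(x$values)))
  } else {
    rng <- range(x$values, na.rm = TRUE)
    cat(sprintf("  range  : [%.4g, %.4g]\n", rng[1], rng[2]))
  }
  invisible(x)
}

#' Replace the value array of a grid, keeping its geometry
#'
#' @param grid A [voxel_grid()].
#' @param values Array of the same dimensions.
#' @return A `voxel_grid` with the same spacing/origin/direction.
#' @export
with_values <- function(grid, values) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!all(dim(values) == dim(grid)))
    stop("replacement values have different dimensions", call. = FALSE)
  voxel_grid(values, grid$spacing, grid$origin, grid$direction)
}

#' Convert a grid to a binary mask
#'
#' @param grid A [voxel_grid()].
#' @param threshold Values strictly above this become `TRUE` (ignored when the
#'   grid is already logical).
#' @return A logical-valued `voxel_grid`.
#' @export
as_mask <- function(grid, threshold = 0) {
  stopifnot(inherits(grid, "voxel_grid"))
  v <- grid$values
  if (!is.logical(v)) {
    v <- v > threshold
    dim(v) <- dim(grid)
  }
  with_values(grid, v)
}

#' Number of TRUE voxels in a mask
#'
#' @param mask A logical-valued [voxel_grid()].
#' @return Integer count.
#' @export
mask_count <- function(mask) {
  stopifnot(inherits(mask, "voxel_grid"), is.logical(mask$values))
  sum(mask$values)
}

#' Dice overlap coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)`; returns `NaN` when both masks are empty.
#'
#' @param a,b Logical-valued [voxel_grid()]s on the same geometry.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "voxel_grid"), inherits(b, "voxel_grid"))
  if (!all(dim(a) == dim(b)))
    stop("masks have different dimensions", call. = FALSE)
  av <- as.logical(a$values); bv <- as.logical(b$values)
  2 * sum(av & bv) / (sum(av) + sum(bv))
}

same_geometry <- function(a, b, tol = 1e-6) {
  all(dim(a) == dim(b)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$direction - b$direction)) < tol
}

# 0-based index coordinates of every voxel, as three vectors in linear order
index_vectors <- function(d) {
  list(
    i = rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
    j = rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
    k = rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  )
}

#' World coordinates of voxel centres
#'
#' @param grid A [voxel_grid()].
#' @param ijk N x 3 matrix of 0-based voxel indices (may be fractional).
#' @return N x 3 matrix of world mm coordinates.
#' @export
index_to_world <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(t(grid$direction %*% (t(ijk) * grid$spacing)), 2, grid$origin, "+")
}

#' Continuous voxel indices of world points
#'
#' @param grid A [voxel_grid()].
#' @param xyz N x 3 matrix of world mm coordinates.
#' @return N x 3 matrix of 0-based (possibly fractional) voxel indices.
#' @export
world_to_index <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  t((t(grid$direction) %*% (t(xyz) - grid$origin)) / grid$spacing)
}

#' World extent of a grid
#'
#' Physical size in mm spanned by the voxel centres along each axis.
#'
#' @param grid A [voxel_grid()].
#' @return Length-3 numeric, `(dim - 1) * spacing`.
#' @export
grid_extent <- function(grid) (dim(grid) - 1) * grid$spacing

#' World coordinates of the grid centre
#'
#' @param grid A [voxel_grid()].
#' @return Length-3 numeric.
#' @export
grid_center <- function(grid) {
  drop(index_to_world(grid, matrix((dim(grid) - 1) / 2, ncol = 3)))
}
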