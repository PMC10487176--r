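#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file (`.nii` or `.nii.gz`) into a [voxel_grid()]. Spacing,
#' origin and direction are taken from the sform/qform; integer stored types
#' are promoted to double. Files whose direction matrix is not orthonormal
#' are rejected.
#'
#' @param path File path.
#' @return A [voxel_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop("unsupported volume format (expected .nii or .nii.gz): ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 3L) {
    if (all(d[-(1:3)] == 1L)) d <- d[1:3]
    else stop("only 3D volumes are supported: ", path, call. = FALSE)
  }
  if (length(d) != 3L) stop("only 3D volumes are supported: ", path, call. = FALSE)
  x <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[1:3]
  if (attr(x, "code") == 0L) {
    origin <- c(0, 0, 0)
    direction <- diag(3)
  } else {
    origin <- x[1:3, 4]
    lin <- x[1:3, 1:3]
    norms <- sqrt(colSums(lin^2))
    direction <- sweep(lin, 2, norms, "/")
    if (max(abs(norms - spacing)) > 1e-3 * max(spacing))
      spacing <- norms
    if (max(abs(crossprod(direction) - diag(3))) > 1e-4)
      stop("non-orthonormal direction matrix in ", path, call. = FALSE)
  }
  vals <- as.numeric(img)
  dim(vals) <- d
  voxel_grid(vals, spacing, origin, direction)
}

#' Write a grid as a NIfTI volume
#'
#' Geometry is stored in the sform (code 2). `datatype = "double"` gives a
#' lossless round trip through [read_volume()]; masks are written as uint8.
#'
#' @param grid A [voxel_grid()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param datatype One of `"double"`, `"float"`, `"uint8"`, `"int16"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path, datatype = "double") {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  datatype <- match.arg(datatype, c("double", "float", "uint8", "int16"))
  vals <- grid$values
  if (is.logical(vals)) {
    vals <- array(as.numeric(vals), dim(vals))
    if (missing(datatype)) datatype <- "uint8"
  }
  lin <- grid$direction %*% diag(grid$spacing)
  hdr <- RNifti::niftiHeader(list(
    dim = c(3L, dim(grid), 1L, 1L, 1L, 1L),
    pixdim = c(1, grid$spacing, 0, 0, 0, 0),
    sform_code = 2L, qform_code = 0L,
    srow_x = c(lin[1, ], grid$origin[1]),
    srow_y = c(lin[2, ], grid$origin[2]),
    srow_z = c(lin[3, ], grid$origin[3])
  ))
  img <- RNifti::asNifti(vals, reference = hdr, datatype = datatype)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
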