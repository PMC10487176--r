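#' World-space 3D affine transform
#'
#' Maps world points `x` to `matrix %*% x + translation`. Used both for the
#' simulated CT-MR misalignment and as the output of [register_affine()]. In
#' the resampling convention of [resample()], the transform maps points in
#' the *reference* (fixed) world frame to points in the *moving* world frame.
#'
#' @param matrix 3x3 invertible matrix.
#' @param translation Length-3 numeric, mm.
#' @return An object of class `affine3d`.
#' @export
affine3d <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 3, 3)
  translation <- as.numeric(translation)
  if (length(translation) != 3L || any(!is.finite(translation)))
    stop("`translation` must be 3 finite numbers", call. = FALSE)
  if (any(!is.finite(matrix)) || abs(det(matrix)) <= 1e-12)
    stop("`matrix` must be finite and invertible", call. = FALSE)
  structure(list(matrix = matrix, translation = translation), class = "affine3d")
}

#' Identity transform
#' @return An `affine3d` equal to the identity map.
#' @export
identity_affine <- function() affine3d()

#' @export
print.affine3d <- function(x, ...) {
  cat("<affine3d>\n")
  m <- cbind(x$matrix, x$translation)
  dimnames(m) <- list(c("x", "y", "z"), c("m1", "m2", "m3", "t"))
  print(round(m, 6))
  invisible(x)
}

#' Apply a transform to world points
#'
#' @param transform An [affine3d()].
#' @param xyz N x 3 matrix (or length-3 vector) of world points.
#' @return N x 3 matrix of mapped points.
#' @export
apply_affine <- function(transform, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(xyz %*% t(transform$matrix), 2, transform$translation, "+")
}

#' Compose two transforms
#'
#' `compose_affine(a, b)` is the map `x -> a(b(x))`.
#'
#' @param a,b [affine3d()] objects.
#' @return The composed `affine3d`.
#' @export
compose_affine <- function(a, b) {
  affine3d(a$matrix %*% b$matrix, drop(a$matrix %*% b$translation) + a$translation)
}

#' Invert a transform
#'
#' @param transform An [affine3d()].
#' @return The inverse `affine3d`.
#' @export
invert_affine <- function(transform) {
  mi <- solve(transform$matrix)
  affine3d(mi, -drop(mi %*% transform$translation))
}

#' Build a transform from pose parameters
#'
#' The linear part is `Rz %*% Ry %*% Rx %*% diag(scale) %*% shear` applied
#' about `center`, followed by `translation`. Shear entries fill the upper
#' triangle (xy, xz, yz) of a unit-diagonal matrix.
#'
#' @param translation Length-3, mm.
#' @param rotation Length-3 rotation angles about x, y, z in degrees.
#' @param scale Length-3 scale factors.
#' @param shear Length-3 shear coefficients (xy, xz, yz).
#' @param center Length-3 world point the linear part pivots about.
#' @return An `affine3d`.
#' @export
affine_from_params <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                               scale = c(1, 1, 1), shear = c(0, 0, 0),
                               center = c(0, 0, 0)) {
  r <- rotation * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  sh <- diag(3)
  sh[1, 2] <- shear[1]; sh[1, 3] <- shear[2]; sh[2, 3] <- shear[3]
  m <- rz %*% ry %*% rx %*% diag(scale) %*% sh
  affine3d(m, center + translation - drop(m %*% center))
}

#' Decompose the linear part of a transform
#'
#' Polar decomposition `M = R P` via SVD: `R` is the nearest rotation,
#' the singular values are the scale factors, and `angle_deg` is the total
#' rotation angle of `R`.
#'
#' @param transform An [affine3d()].
#' @return List with `rotation` (3x3), `scales` (length 3, sorted decreasing),
#'   and `angle_deg` (scalar).
#' @export
decompose_affine <- function(transform) {
  s <- svd(transform$matrix)
  r <- s$u %*% t(s$v)
  if (det(r) < 0) {
    # reflection: flip the smallest singular direction
    u <- s$u; u[, 3] <- -u[, 3]
    r <- u %*% t(s$v)
  }
  ang <- acos(pmin(1, pmax(-1, (sum(diag(r)) - 1) / 2))) * 180 / pi
  list(rotation = r, scales = s$d, angle_deg = ang)
}

#' Rotation angle between two transforms
#'
#' Angle of the relative rotation between the polar-decomposed rotation parts,
#' in degrees.
#'
#' @param a,b [affine3d()] objects.
#' @return Scalar angle in degrees.
#' @export
rotation_between <- function(a, b) {
  ra <- decompose_affine(a)$rotation
  rb <- decompose_affine(b)$rotation
  rel <- ra %*% t(rb)
  acos(pmin(1, pmax(-1, (sum(diag(rel)) - 1) / 2))) * 180 / pi
}

#' Write a transform as a plain-text 4x4 matrix
#'
#' Row-major homogeneous matrix, one row per line, whitespace separated.
#'
#' @param transform An [affine3d()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_affine <- function(transform, path) {
  m <- rbind(cbind(transform$matrix, transform$translation), c(0, 0, 0, 1))
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), path)
  invisible(path)
}

#' Read a transform written by [write_affine()]
#'
#' @param path File path.
#' @return An `affine3d`.
#' @export
read_affine <- function(path) {
  if (!file.exists(path)) stop("transform file not found: ", path, call. = FALSE)
  rows <- lapply(readLines(path, n = 4), function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, rows)
  if (!all(dim(m) == c(4, 4)) || any(!is.finite(m)))
    stop("not a 4x4 transform file: ", path, call. = FALSE)
  affine3d(m[1:3, 1:3], m[1:3, 4])
}
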