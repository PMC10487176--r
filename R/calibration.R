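#' Fit the CT grey-to-BMD calibration from phantom inserts
#'
#' Ordinary least squares of known insert density on per-insert mean grey
#' value, giving the linear map `BMD = a * grey + b` applied by
#' [apply_calibration()]. With two inserts the fit is the exact line through
#' the two points. Density is regressed on grey (not the reverse) so that
#' applying the model is a direct affine map of the image.
#'
#' @param ct CT [voxel_grid()] in raw grey values.
#' @param inserts List of `list(mask = <mask grid>, density = <mg HA/cm^3>)`
#'   entries, one per phantom insert; at least two distinct densities.
#' @return An object of class `bmd_calibration`: slope `a`
#'   ((mg HA/cm^3) per grey unit), intercept `b` (mg HA/cm^3), `diagnostics`
#'   tibble (density, mean grey, n voxels, fitted, residual) and `r_squared`.
#' @export
fit_calibration <- function(ct, inserts) {
  stopifnot(inherits(ct, "voxel_grid"))
  if (length(inserts) < 2) stop("need at least 2 inserts", call. = FALSE)
  density <- vapply(inserts, function(x) as.numeric(x$density), numeric(1))
  if (length(unique(density)) < 2)
    stop("insert densities are all equal; cannot fit a line", call. = FALSE)
  masks <- lapply(inserts, function(x) x$mask)
  for (m in masks) {
    stopifnot(inherits(m, "voxel_grid"))
    if (mask_count(m) == 0) stop("empty insert mask", call. = FALSE)
  }
  total <- Reduce(`+`, lapply(masks, function(m) as.numeric(m$values)))
  if (any(total > 1)) stop("insert masks overlap", call. = FALSE)
  grey <- vapply(masks, function(m) mean(ct$values[m$values]), numeric(1))
  n_vox <- vapply(masks, mask_count, integer(1))
  if (diff(range(grey)) == 0)
    stop("degenerate insert greys: identical means with distinct densities",
         call. = FALSE)
  fit <- lm(density ~ grey)
  a <- unname(coef(fit)[2])
  b <- unname(coef(fit)[1])
  fitted <- a * grey + b
  ss_res <- sum((density - fitted)^2)
  ss_tot <- sum((density - mean(density))^2)
  structure(list(
    a = a, b = b,
    diagnostics = tibble::tibble(
      density = density, mean_grey = grey, n_voxels = n_vox,
      fitted = fitted, residual = density - fitted
    ),
    r_squared = 1 - ss_res / ss_tot
  ), class = "bmd_calibration")
}

#' @export
print.bmd_calibration <- function(x, ...) {
  cat(sprintf("<bmd_calibration> BMD = %.6g * grey + %.6g  (R^2 = %.5f, %d inserts)\n",
              x$a, x$b, x$r_squared, nrow(x$diagnostics)))
  invisible(x)
}

#' @export
tidy.bmd_calibration <- function(x, ...) {
  tibble::tibble(term = c("slope", "intercept"), estimate = c(x$a, x$b))
}

#' @export
glance.bmd_calibration <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, n_inserts = nrow(x$diagnostics),
                 max_abs_residual = max(abs(x$diagnostics$residual)))
}

#' Apply a grey-to-BMD calibration to a CT volume
#'
#' Voxel-wise `BMD = a * grey + b`, preserving geometry. Negative calibrated
#' values are retained by default (noise-faithful; clamping would bias the
#' voxel-wise regression) unless `clamp = TRUE`.
#'
#' @param ct CT [voxel_grid()].
#' @param model A [fit_calibration()] result.
#' @param clamp Clamp negative BMD to 0?
#' @return BMD [voxel_grid()] in mg HA/cm^3.
#' @export
apply_calibration <- function(ct, model, clamp = FALSE) {
  stopifnot(inherits(ct, "voxel_grid"), inherits(model, "bmd_calibration"))
  bmd <- model$a * ct$values + model$b
  if (clamp) bmd[bmd < 0] <- 0
  with_values(ct, bmd)
}

#' Insert masks from the synthetic rod geometry
#'
#' Convenience detector for volumes produced by the synthetic generator:
#' reconstructs the rod masks parametrically from the phantom specification
#' (optionally eroded by `margin` mm to avoid boundary voxels) and pairs them
#' with the known densities. Real scans require user-supplied masks.
#'
#' @param spec A [phantom_spec()].
#' @param margin Radial erosion in mm.
#' @return List of `list(mask, density)` entries for [fit_calibration()].
#' @export
detect_inserts <- function(spec, margin = 0.3) {
  sp <- spec
  sp$insert_radius <- max(spec$insert_radius - margin, spec$insert_radius / 2)
  masks <- insert_rod_masks(sp)
  purrr::map2(masks, spec$insert_densities,
              function(m, d) list(mask = m, density = d))
}
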