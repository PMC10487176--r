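#' Compute the porosity-index map from two UTE echoes
#'
#' `PI = 100 * echo2 / echo1` wherever the short-echo signal exceeds the
#' background floor; other voxels are invalid and carry `NaN`. Values above
#' 100 % (possible under noise) are kept, not clipped, and counted in the
#' result. The default floor is five times the background noise SD estimated
#' from the volume's corner patches.
#'
#' @param echo1 Short-echo [voxel_grid()].
#' @param echo2 Long-echo [voxel_grid()] on the identical geometry.
#' @param floor Intensity threshold (same units as `echo1`); `NULL` for the
#'   automatic estimate.
#' @return An object of class `pi_map`: `values` (grid, % with `NaN` where
#'   invalid), `valid` (mask grid), `floor`, `n_above_100`.
#' @export
compute_pi <- function(echo1, echo2, floor = NULL) {
  stopifnot(inherits(echo1, "voxel_grid"), inherits(echo2, "voxel_grid"))
  if (!same_geometry(echo1, echo2))
    stop("echo volumes must share identical geometry", call. = FALSE)
  if (is.null(floor)) floor <- estimate_noise_floor(echo1)
  if (floor < 0) stop("`floor` must be non-negative", call. = FALSE)
  valid <- echo1$values > floor
  pi_vals <- array(NaN, dim(echo1))
  pi_vals[valid] <- 100 * echo2$values[valid] / echo1$values[valid]
  structure(list(
    values = with_values(echo1, pi_vals),
    valid = with_values(echo1, valid),
    floor = floor,
    n_above_100 = sum(pi_vals[valid] > 100)
  ), class = "pi_map")
}

#' @export
print.pi_map <- function(x, ...) {
  nv <- mask_count(x$valid)
  cat(sprintf("<pi_map> %s voxels, %d valid (floor %.4g), %d above 100%%\n",
              paste(dim(x$values), collapse = "x"), nv, x$floor, x$n_above_100))
  if (nv > 0)
    cat(sprintf("  PI over valid voxels: mean %.2f%%, range [%.2f, %.2f]\n",
                mean(x$values$values[x$valid$values]),
                min(x$values$values[x$valid$values]),
                max(x$values$values[x$valid$values])))
  invisible(x)
}

#' Background noise floor estimate
#'
#' Five times the median SD over the eight corner patches of the volume,
#' assumed to contain background only.
#'
#' @param grid A [voxel_grid()].
#' @param patch Patch edge length in voxels.
#' @param factor Multiplier on the noise SD.
#' @return Scalar intensity threshold.
#' @export
estimate_noise_floor <- function(grid, patch = 5, factor = 5) {
  d <- dim(grid)
  patch <- min(patch, min(d))
  idx <- function(n) list(seq_len(patch), n - patch + seq_len(patch))
  sds <- c()
  for (ii in idx(d[1])) for (jj in idx(d[2])) for (kk in idx(d[3]))
    sds <- c(sds, sd(grid$values[ii, jj, kk]))
  factor * median(sds)
}

#' Summary diagnostics of a PI map over a mask
#'
#' @param pi A [compute_pi()] result.
#' @param mask Mask [voxel_grid()] on the PI geometry.
#' @return One-row tibble: n in mask, mean/median/SD of PI over the valid
#'   masked voxels, fraction invalid, fraction above 100 %.
#' @export
pi_diagnostics <- function(pi, mask) {
  stopifnot(inherits(pi, "pi_map"), inherits(mask, "voxel_grid"))
  if (!all(dim(mask) == dim(pi$values)))
    stop("mask geometry does not match the PI map", call. = FALSE)
  m <- as.logical(mask$values)
  if (!any(m)) stop("empty mask", call. = FALSE)
  ok <- m & pi$valid$values
  v <- pi$values$values[ok]
  tibble::tibble(
    n = sum(m),
    n_valid = sum(ok),
    mean = if (length(v)) mean(v) else NA_real_,
    median = if (length(v)) median(v) else NA_real_,
    sd = if (length(v)) sd(v) else NA_real_,
    frac_invalid = 1 - sum(ok) / sum(m),
    frac_above_100 = if (length(v)) mean(v > 100) else NA_real_
  )
}

#' Write a PI map as NIfTI
#'
#' Invalid voxels are stored as NaN.
#'
#' @param pi A [compute_pi()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pi_map <- function(pi, path) {
  write_volume(pi$values, path, "double")
}
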