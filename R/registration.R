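#' Registration configuration
#'
#' Controls the multi-resolution affine registration: pyramid factors,
#' mutual-information histogram bins, the per-level line-search ranges of
#' the pose parameters, sweep budget and convergence tolerance, and the
#' metric sampling cap.
#'
#' @param factors Integer downsampling factors, coarse to fine.
#' @param bins Joint-histogram bins per image (>= 8).
#' @param max_sweeps Maximum coordinate-descent sweeps per level.
#' @param tol Convergence tolerance on the metric gain (bits) per sweep.
#' @param max_samples Cap on fixed-image voxels sampled per metric
#'   evaluation (deterministic stride unless `sampling < 1`).
#' @param sampling Fraction of voxels sampled at random instead of the
#'   stride (1 = deterministic stride).
#' @param seed RNG seed used only when `sampling < 1`.
#' @param dof `"affine"` (12 parameters) or `"rigid"` (6).
#' @param translation_range,rotation_range,scale_range,shear_range Half-width
#'   of the line search at the coarsest level for each parameter class
#'   (mm, degrees, log-scale, shear); translation and rotation ranges are
#'   halved at each finer level, while the scale/shear trust region is fixed.
#' @return An object of class `registration_config`.
#' @export
registration_config <- function(factors = c(4, 2, 1), bins = 32,
                                max_sweeps = 6, tol = 1e-4,
                                max_samples = 40000, sampling = 1, seed = 1,
                                dof = c("affine", "rigid"),
                                translation_range = 8, rotation_range = 8,
                                scale_range = 0.03, shear_range = 0.03) {
  if (length(factors) < 1) stop("need at least one pyramid level", call. = FALSE)
  if (bins < 8) stop("`bins` must be >= 8", call. = FALSE)
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  structure(list(
    factors = as.integer(factors), bins = as.integer(bins),
    max_sweeps = as.integer(max_sweeps), tol = tol,
    max_samples = as.integer(max_samples), sampling = sampling, seed = seed,
    dof = match.arg(dof),
    translation_range = translation_range, rotation_range = rotation_range,
    scale_range = scale_range, shear_range = shear_range
  ), class = "registration_config")
}

# sampled fixed-image voxel world coordinates + values (deterministic stride)
metric_samples <- function(fixed, config) {
  n <- prod(dim(fixed))
  take <- seq_len(n)
  if (config$sampling < 1) {
    take <- with_seed(config$seed, sort(sample.int(n, ceiling(config$sampling * n))))
  }
  if (length(take) > config$max_samples) {
    stride <- ceiling(length(take) / config$max_samples)
    take <- take[seq(1, length(take), by = stride)]
  }
  d <- dim(fixed)
  i0 <- (take - 1) %% d[1]
  j0 <- ((take - 1) %/% d[1]) %% d[2]
  k0 <- (take - 1) %/% (d[1] * d[2])
  xyz <- index_to_world(fixed, cbind(i0, j0, k0))
  list(xyz = xyz, values = as.numeric(fixed$values)[take])
}

mi_from_samples <- function(samples, moving, transform, bins, f_range, m_range) {
  mapped <- apply_affine(transform, samples$xyz)
  u <- world_to_index(moving, mapped)
  mv <- moving$values
  if (is.logical(mv)) mv <- array(as.numeric(mv), dim(mv))
  if (diff(f_range) == 0 || diff(m_range) == 0) {
    # degenerate marginal; still demand a non-empty overlap
    vals <- cpp_sample_trilinear(mv, dim(moving), u[, 1], u[, 2], u[, 3], NA_real_)
    if (all(is.na(vals)))
      stop("empty overlap between fixed and moving volumes", call. = FALSE)
    return(0)
  }
  bf <- pmin(bins, pmax(1L, floor((samples$values - f_range[1]) /
                                    diff(f_range) * bins) + 1L))
  # partial-volume joint histogram: smooth in the transform parameters
  jm <- cpp_joint_hist_pv(mv, dim(moving), u[, 1], u[, 2], u[, 3],
                          as.integer(bf), as.integer(bins),
                          m_range[1], m_range[2])
  total <- sum(jm)
  if (total == 0)
    stop("empty overlap between fixed and moving volumes", call. = FALSE)
  jm <- jm / total
  pf <- rowSums(jm)
  pm <- colSums(jm)
  outer_p <- outer(pf, pm)
  nz <- jm > 0
  sum(jm[nz] * log2(jm[nz] / outer_p[nz]))
}

#' Mutual information between two volumes under a transform
#'
#' Joint-histogram mutual information (in bits) between the fixed image and
#' the moving image resampled through `transform`, over their overlap.
#' Histogram bin edges are equal-width over each image's global intensity
#' range, making the metric symmetric for identical geometries. Degenerate
#' (constant) images give 0.
#'
#' @param fixed,moving [voxel_grid()] objects.
#' @param transform An [affine3d()] mapping fixed world to moving world.
#' @param bins Histogram bins per image.
#' @param max_samples Cap on sampled fixed voxels (deterministic stride).
#' @return Scalar MI in bits.
#' @export
mutual_information <- function(fixed, moving, transform = identity_affine(),
                               bins = 32, max_samples = Inf) {
  stopifnot(inherits(fixed, "voxel_grid"), inherits(moving, "voxel_grid"))
  config <- registration_config(bins = bins,
                                max_samples = if (is.finite(max_samples)) max_samples
                                              else .Machine$integer.max)
  samples <- metric_samples(fixed, config)
  mi_from_samples(samples, moving, transform, bins,
                  range(fixed$values), range(as.numeric(moving$values)))
}

params_to_affine <- function(p, center, dof) {
  if (dof == "rigid") p <- c(p[1:6], 0, 0, 0, 0, 0, 0)
  affine_from_params(translation = p[1:3], rotation = p[4:6],
                     scale = exp(p[7:9]), shear = p[10:12], center = center)
}

#' Multi-resolution affine registration by mutual information
#'
#' Maximises the joint-histogram mutual information over a 12-parameter
#' affine (translation, rotation, log-scale, shear about the fixed-image
#' centre) composed with the initial transform, using coarse-to-fine
#' block-mean pyramids and cyclic one-dimensional line searches (a
#' derivative-free Powell-style scheme). Deterministic for a fixed
#' configuration.
#'
#' The initial transform plays the role of a manual rigid pre-alignment;
#' identity suffices for misalignments within the coarse-level capture
#' range (a few voxels and degrees).
#'
#' @param fixed Fixed [voxel_grid()] (the CT in the PI-to-CT use case).
#' @param moving Moving [voxel_grid()] (the PI map or an echo volume).
#' @param init Initial [affine3d()] (fixed world to moving world).
#' @param config A [registration_config()].
#' @return An object of class `bone_registration`: `transform` (the full
#'   fixed-to-moving affine), `params`, `mi` (final metric), and `trace`
#'   (tibble of per-level, per-sweep metric values).
#' @export
register_affine <- function(fixed, moving, init = identity_affine(),
                            config = registration_config()) {
  stopifnot(inherits(fixed, "voxel_grid"), inherits(moving, "voxel_grid"),
            inherits(init, "affine3d"))
  # pivot the pose parameters about the fixed image's intensity centroid:
  # rotations then leave the anatomy's centre of mass in place, decoupling
  # the rotation and translation line searches
  center <- intensity_centroid(fixed)
  n_par <- if (config$dof == "rigid") 6L else 12L
  p <- rep(0, 12)
  m_range <- range(as.numeric(moving$values))
  trace <- list()
  n_levels <- length(config$factors)
  for (lev in seq_len(n_levels)) {
    f <- config$factors[lev]
    fx <- downsample_grid(fixed, f)
    mv <- downsample_grid(moving, f)
    samples <- metric_samples(fx, config)
    f_range <- range(fx$values)
    shrink <- 2^-(lev - 1) # halve the translation search at each finer level
    # rotation keeps its full range everywhere: on blob-like anatomy the
    # coarse, smoothed levels constrain rotation only weakly, so the finer
    # levels must still be able to reach the true angle
    hw <- c(rep(config$translation_range * shrink, 3),
            rep(config$rotation_range, 3),
            rep(config$scale_range, 3),
            rep(config$shear_range, 3))
    objective <- function(pp) {
      t_total <- compose_affine(init, params_to_affine(pp, center, config$dof))
      # a probe without overlap is simply a bad candidate, not a failure
      tryCatch(
        mi_from_samples(samples, mv, t_total, config$bins, f_range, m_range),
        error = function(e) -Inf
      )
    }
    cur <- objective(p)
    if (!is.finite(cur))
      stop("no overlap between fixed and moving volumes at the initial transform",
           call. = FALSE)
    # rigid stage first; the full affine refinement only at the finest level
    # and within a tight trust region, so that scale/shear cannot soak up an
    # unresolved rotation at the heavily smoothed coarse levels
    stages <- if (n_par == 6L || lev < n_levels) list(1:6) else list(1:6, 1:12)
    for (st in seq_along(stages)) {
      active <- stages[[st]]
      for (sweep in seq_len(config$max_sweeps)) {
        prev <- cur
        for (q in active) {
          lo <- p[q] - hw[q]; hi <- p[q] + hw[q]
          opt <- optimize(function(v) {
            pp <- p; pp[q] <- v; -objective(pp)
          }, interval = c(lo, hi), tol = max(hw[q] / 200, 1e-6))
          if (-opt$objective > cur) {
            p[q] <- opt$minimum
            cur <- -opt$objective
          }
        }
        trace[[length(trace) + 1]] <- tibble::tibble(
          level = lev, factor = f, stage = st, sweep = sweep, mi = cur
        )
        if (cur - prev < config$tol) break
      }
    }
  }
  transform <- compose_affine(init, params_to_affine(p, center, config$dof))
  structure(list(
    transform = transform, params = p[seq_len(n_par)], mi = cur,
    trace = dplyr::bind_rows(trace), center = center, config = config
  ), class = "bone_registration")
}

#' @export
print.bone_registration <- function(x, ...) {
  cat(sprintf("<bone_registration> %s, final MI = %.4f bits\n",
              x$config$dof, x$mi))
  print(x$transform)
  invisible(x)
}

#' Resample a PI map onto the CT grid
#'
#' PI values are linearly interpolated onto the CT geometry through the
#' given fixed-to-moving transform (invalid voxels contribute as gaps); the
#' validity mask is resampled nearest-neighbour. Output voxels whose nearest
#' source voxel is invalid, or whose interpolated value is not finite, are
#' invalid.
#'
#' @param pi A [compute_pi()] result.
#' @param ct CT [voxel_grid()] supplying the target geometry.
#' @param transform An [affine3d()] from [register_affine()] (or the ground
#'   truth), mapping CT world to MR world.
#' @return A `pi_map` on the CT geometry.
#' @export
align_pi_to_ct <- function(pi, ct, transform) {
  stopifnot(inherits(pi, "pi_map"), inherits(ct, "voxel_grid"),
            inherits(transform, "affine3d"))
  vals <- pi$values$values
  vals[!pi$valid$values] <- 0 # placeholder; masked out again below
  src <- with_values(pi$values, vals)
  res_vals <- resample(src, transform, ct, "linear", fill = NaN)
  res_valid <- resample(pi$valid, transform, ct, "nearest", fill = 0)
  ok <- res_valid$values & is.finite(res_vals$values)
  out <- res_vals$values
  out[!ok] <- NaN
  structure(list(
    values = with_values(res_vals, out),
    valid = with_values(res_valid, ok),
    floor = pi$floor,
    n_above_100 = sum(out[ok] > 100)
  ), class = "pi_map")
}

# box-blur a grid (per axis) so its effective resolution approaches `target`
blur_to_match <- function(grid, target) {
  r <- pmax(0L, as.integer(round((target / grid$spacing - 1) / 2)))
  if (all(r == 0L)) return(grid)
  vals <- grid$values
  if (is.logical(vals)) vals <- array(as.numeric(vals), dim(vals))
  with_values(grid, cpp_box_blur(vals, dim(grid), r[1], r[2], r[3]))
}

# world-space centre of mass of the image's bright structures (weights are
# intensities above the median, so a dominant dark background drops out)
intensity_centroid <- function(grid) {
  v <- as.numeric(grid$values)
  w <- pmax(v - median(v), 0)
  if (sum(w) == 0) return(grid_center(grid))
  d <- dim(grid)
  idx <- index_vectors(d)
  ij <- cbind(sum(idx$i * w), sum(idx$j * w), sum(idx$k * w)) / sum(w)
  drop(index_to_world(grid, ij))
}
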