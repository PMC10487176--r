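#' Specification of a synthetic condyle phantom
#'
#' Collects every parameter of the paired CT / dual-echo UTE MR simulation:
#' grid geometries, the condyle-like bone shape (ellipsoid cap plus
#' cylindrical shaft), the spatial porosity field, the porosity-to-BMD
#' coupling, the CT grey model with hydroxyapatite calibration rods, the
#' two-pool (bound water / pore water) T2* signal model, noise levels, and
#' the simulated CT-MR misalignment.
#'
#' Default CT spacing is 0.273 x 0.273 x 0.4 mm and MR spacing 0.66 mm
#' isotropic, so the resolution-matching step of the registration stage is
#' genuinely exercised. Cortical and trabecular porosity default to 0.035
#' and 0.793. Bound and pore water T2* default to 0.39 ms and 10 ms with
#' echo times 0.04 / 2.52 ms.
#'
#' @param ct_dim,ct_spacing,ct_origin CT grid geometry (voxels, mm, mm).
#' @param mr_dim,mr_spacing MR grid geometry; `mr_origin = NULL` centres the
#'   MR field of view on the CT volume.
#' @param mr_origin Optional explicit MR origin (mm).
#' @param bone_center World centre of the ellipsoid cap (mm).
#' @param cap_radius Ellipsoid cap semi-axes, mm (scalar recycled to 3). The
#'   default is wider mediolaterally than dorsopalmarly, as a distal condyle
#'   is; the asymmetry also makes rotations about the long axis observable.
#' @param shaft_radius,shaft_length Cylindrical diaphysis radius / length, mm.
#' @param shell Cortical shell thickness, mm (must be below min cap radius).
#' @param phi_cort,phi_trab Cortical and trabecular porosity levels in [0, 1].
#' @param phi_smooth Correlation length of the spatial porosity variation, mm.
#' @param phi_sd Standard deviation of the spatial porosity variation.
#' @param rho_max Mineral density at zero porosity, mg HA/cm^3.
#' @param coupling Porosity-BMD coupling slope: BMD = rho_max (1 - coupling phi).
#' @param bmd_noise_sd BMD field noise SD, mg HA/cm^3.
#' @param g0,g1 CT grey model: grey = g0 + g1 BMD.
#' @param ct_noise_sd CT grey noise SD.
#' @param background_grey Soft-tissue background grey level.
#' @param insert_densities Calibration rod densities, mg HA/cm^3 (>= 2 distinct).
#' @param insert_radius Rod radius, mm.
#' @param insert_x Rod axis x position, mm (rods run along z).
#' @param te_short,te_long Echo times, ms.
#' @param t2s_bw,t2s_pw Bound / pore water T2*, ms (t2s_bw < t2s_pw).
#' @param a_bw,a_pw Proton-density scalars of the two pools.
#' @param mr_noise_sd MR echo noise SD (signal units; pure-bone short-echo
#'   signal is about `a_bw`).
#' @param noise_model `"gaussian"` (additive, default) or `"rician"`.
#' @param misalignment An [affine3d()] mapping CT world to MR world: the true
#'   transform that aligns the MR/PI volume to CT. Default: translation
#'   (3.2, -1.5, 0.8) mm plus a 5 degree rotation about z, pivoted at the CT
#'   volume centre.
#' @param seed Optional default RNG seed used by the generator functions.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(ct_dim = c(96, 96, 96),
                         ct_spacing = c(0.273, 0.273, 0.4),
                         ct_origin = c(0, 0, 0),
                         mr_dim = c(64, 64, 64),
                         mr_spacing = c(0.66, 0.66, 0.66),
                         mr_origin = NULL,
                         bone_center = c(11, 13.1, 12),
                         cap_radius = c(9, 7, 8),
                         shaft_radius = 5,
                         shaft_length = 14,
                         shell = 2,
                         phi_cort = 0.035,
                         phi_trab = 0.793,
                         phi_smooth = 3,
                         phi_sd = 0.05,
                         rho_max = 1200,
                         coupling = 0.5,
                         bmd_noise_sd = 30,
                         g0 = 40,
                         g1 = 1.8,
                         ct_noise_sd = 25,
                         background_grey = 60,
                         insert_densities = c(0, 200, 400),
                         insert_radius = 1.5,
                         insert_x = 22.5,
                         te_short = 0.04,
                         te_long = 2.52,
                         t2s_bw = 0.39,
                         t2s_pw = 10,
                         a_bw = 1,
                         a_pw = 1,
                         mr_noise_sd = 0.01,
                         noise_model = c("gaussian", "rician"),
                         misalignment = NULL,
                         seed = NULL) {
  cap_radius <- rep(as.numeric(cap_radius), length.out = 3)
  spec <- list(
    ct_dim = as.integer(ct_dim), ct_spacing = as.numeric(ct_spacing),
    ct_origin = as.numeric(ct_origin),
    mr_dim = as.integer(mr_dim), mr_spacing = as.numeric(mr_spacing),
    mr_origin = mr_origin,
    bone_center = as.numeric(bone_center), cap_radius = cap_radius,
    shaft_radius = shaft_radius, shaft_length = shaft_length, shell = shell,
    phi_cort = phi_cort, phi_trab = phi_trab,
    phi_smooth = phi_smooth, phi_sd = phi_sd,
    rho_max = rho_max, coupling = coupling, bmd_noise_sd = bmd_noise_sd,
    g0 = g0, g1 = g1, ct_noise_sd = ct_noise_sd,
    background_grey = background_grey,
    insert_densities = as.numeric(insert_densities),
    insert_radius = insert_radius, insert_x = insert_x,
    te_short = te_short, te_long = te_long,
    t2s_bw = t2s_bw, t2s_pw = t2s_pw, a_bw = a_bw, a_pw = a_pw,
    mr_noise_sd = mr_noise_sd,
    noise_model = match.arg(noise_model),
    misalignment = misalignment, seed = seed
  )
  class(spec) <- "phantom_spec"
  ctg <- ct_geometry(spec)
  if (is.null(spec$mr_origin))
    spec$mr_origin <- grid_center(ctg) - (spec$mr_dim - 1) * spec$mr_spacing / 2
  if (is.null(spec$misalignment))
    spec$misalignment <- affine_from_params(
      translation = c(3.2, -1.5, 0.8), rotation = c(0, 0, 5),
      center = grid_center(ctg)
    )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$ct_dim) == 3, length(spec$mr_dim) == 3)
  if (spec$phi_cort < 0 || spec$phi_cort > 1 || spec$phi_trab < 0 || spec$phi_trab > 1)
    stop("porosity levels must lie in [0, 1]", call. = FALSE)
  if (spec$rho_max <= 0) stop("`rho_max` must be positive", call. = FALSE)
  if (spec$g1 == 0) stop("`g1` must be nonzero", call. = FALSE)
  if (!(spec$te_short < spec$te_long))
    stop("`te_short` must be strictly below `te_long`", call. = FALSE)
  if (spec$t2s_bw <= 0 || spec$t2s_pw <= 0)
    stop("T2* values must be positive", call. = FALSE)
  if (!(spec$t2s_bw < spec$t2s_pw))
    stop("bound-water T2* must be below pore-water T2*", call. = FALSE)
  if (length(unique(spec$insert_densities)) < 2)
    stop("need at least 2 distinct insert densities", call. = FALSE)
  if (spec$shell >= min(spec$cap_radius))
    stop("shell thickness must be below the cap radius", call. = FALSE)
  if (!inherits(spec$misalignment, "affine3d"))
    stop("`misalignment` must be an affine3d", call. = FALSE)
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>\n")
  cat(sprintf("  CT %s @ %s mm | MR %s @ %s mm\n",
              paste(x$ct_dim, collapse = "x"), paste(x$ct_spacing, collapse = "/"),
              paste(x$mr_dim, collapse = "x"), paste(x$mr_spacing, collapse = "/")))
  cat(sprintf("  cap r = %s mm, shaft r = %g mm x %g mm, shell %g mm\n",
              paste(x$cap_radius, collapse = "/"), x$shaft_radius, x$shaft_length, x$shell))
  cat(sprintf("  phi: cortical %.3f, trabecular %.3f (sd %.3f @ %.1f mm)\n",
              x$phi_cort, x$phi_trab, x$phi_sd, x$phi_smooth))
  cat(sprintf("  BMD: rho_max %g, coupling %g | TE %g/%g ms, T2* %g/%g ms\n",
              x$rho_max, x$coupling, x$te_short, x$te_long, x$t2s_bw, x$t2s_pw))
  invisible(x)
}

ct_geometry <- function(spec) {
  voxel_grid(array(0, spec$ct_dim), spec$ct_spacing, spec$ct_origin)
}

mr_geometry <- function(spec) {
  voxel_grid(array(0, spec$mr_dim), spec$mr_spacing, spec$mr_origin)
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# world-coordinate vectors along each CT axis (axis-aligned grids only)
axis_coords <- function(spec) {
  list(
    x = spec$ct_origin[1] + (seq_len(spec$ct_dim[1]) - 1) * spec$ct_spacing[1],
    y = spec$ct_origin[2] + (seq_len(spec$ct_dim[2]) - 1) * spec$ct_spacing[2],
    z = spec$ct_origin[3] + (seq_len(spec$ct_dim[3]) - 1) * spec$ct_spacing[3]
  )
}

# bone shape: ellipsoid cap (centre bone_center, semi-axes cap_radius) union
# cylindrical shaft running from the cap centre towards +z
bone_shape_mask <- function(spec, erode = 0) {
  co <- axis_coords(spec)
  c0 <- spec$bone_center
  a <- pmax(spec$cap_radius - erode, 1e-6)
  rs <- max(spec$shaft_radius - erode, 1e-6)
  ex2 <- ((co$x - c0[1]) / a[1])^2
  ey2 <- ((co$y - c0[2]) / a[2])^2
  ez2 <- ((co$z - c0[3]) / a[3])^2
  exy <- outer(ex2, ey2, "+")
  ell <- outer(exy, ez2, "+") <= 1
  rxy <- outer((co$x - c0[1])^2, (co$y - c0[2])^2, "+") <= rs^2
  zin <- co$z >= c0[3] & co$z <= c0[3] + spec$cap_radius[3] + spec$shaft_length - erode
  cyl <- outer(rxy, zin, "&")
  ell | cyl
}

# z level of the cap/shaft junction: where the ellipsoid narrows to the shaft
condyle_junction_z <- function(spec) {
  a <- spec$cap_radius
  frac <- min(1, spec$shaft_radius / min(a[1], a[2]))
  spec$bone_center[3] + a[3] * sqrt(1 - frac^2)
}

#' Generate the spatial porosity field and geometry masks
#'
#' Builds the condyle-shaped bone (ellipsoid cap plus shaft), assigns the
#' cortical porosity level to a shell of the configured thickness and the
#' trabecular level to the interior, and adds band-limited spatial variation
#' (white noise laid down at the correlation length and linearly upsampled).
#' The field is clipped to [0, 1]; background is 0.
#'
#' @param spec A [phantom_spec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return List with `porosity` (a [voxel_grid()]), and logical-grid masks
#'   `bone`, `shell`, `core`, `condyle`.
#' @export
make_porosity_field <- function(spec, seed = spec$seed) {
  validate_phantom_spec(spec)
  bone <- bone_shape_mask(spec)
  inner <- bone_shape_mask(spec, erode = spec$shell)
  core <- bone & inner
  shellm <- bone & !inner
  phi <- array(0, spec$ct_dim)
  phi[shellm] <- spec$phi_cort
  phi[core] <- spec$phi_trab
  ctg <- ct_geometry(spec)
  if (spec$phi_sd > 0) {
    field <- with_seed(seed, {
      cdim <- pmax(4L, as.integer(ceiling(grid_extent(ctg) / spec$phi_smooth)) + 3L)
      coarse <- voxel_grid(array(rnorm(prod(cdim)), cdim),
                           spacing = rep(spec$phi_smooth, 3),
                           origin = spec$ct_origin - spec$phi_smooth)
      resample(coarse, reference = ctg)$values
    })
    s <- sd(field[bone])
    if (s > 0) phi <- phi + field * (spec$phi_sd / s)
    phi[!bone] <- 0
    phi[phi < 0] <- 0
    phi[phi > 1] <- 1
  }
  co <- axis_coords(spec)
  zj <- condyle_junction_z(spec)
  condyle <- bone
  condyle[, , co$z > zj] <- FALSE
  list(
    porosity = with_values(ctg, phi),
    bone = with_values(ctg, bone),
    shell = with_values(ctg, shellm),
    core = with_values(ctg, core),
    condyle = with_values(ctg, condyle)
  )
}

#' Generate the BMD field coupled to porosity
#'
#' `BMD = rho_max (1 - coupling * phi) + N(0, bmd_noise_sd)` inside the bone
#' mask, clipped below at 0; background 0.
#'
#' @param porosity Porosity [voxel_grid()] in [0, 1].
#' @param bone Bone mask grid.
#' @param spec A [phantom_spec()].
#' @param seed RNG seed.
#' @return A [voxel_grid()] of BMD in mg HA/cm^3.
#' @export
make_bmd_field <- function(porosity, bone, spec, seed = spec$seed) {
  stopifnot(inherits(porosity, "voxel_grid"))
  if (min(porosity$values) < 0 || max(porosity$values) > 1)
    stop("porosity must lie in [0, 1]", call. = FALSE)
  bm <- bone$values
  bmd <- array(0, dim(porosity))
  bmd[bm] <- spec$rho_max * (1 - spec$coupling * porosity$values[bm])
  if (spec$bmd_noise_sd > 0) {
    noise <- with_seed(seed, rnorm(sum(bm), sd = spec$bmd_noise_sd))
    bmd[bm] <- bmd[bm] + noise
  }
  bmd[bmd < 0] <- 0
  with_values(porosity, bmd)
}

insert_rod_masks <- function(spec) {
  co <- axis_coords(spec)
  nd <- length(spec$insert_densities)
  yext <- range(co$y)
  ys <- seq(yext[1] + 3, yext[2] - 3, length.out = nd)
  zin <- co$z >= min(co$z) + 2 & co$z <= max(co$z) - 2
  ctg <- ct_geometry(spec)
  lapply(seq_len(nd), function(q) {
    rxy <- outer((co$x - spec$insert_x)^2, (co$y - ys[q])^2, "+") <= spec$insert_radius^2
    with_values(ctg, outer(rxy, zin, "&"))
  })
}

#' Render the CT volume with calibration rods
#'
#' Grey values follow `g0 + g1 * BMD` inside bone and inside each
#' hydroxyapatite rod (at its known density); elsewhere a flat soft-tissue
#' background grey. Gaussian detector noise of SD `ct_noise_sd` is added
#' over the whole volume.
#'
#' @param bmd BMD [voxel_grid()].
#' @param bone Bone mask grid.
#' @param spec A [phantom_spec()].
#' @param seed RNG seed.
#' @return List with `ct` (grid), `insert_masks` (list of mask grids) and
#'   `insert_densities`.
#' @export
render_ct <- function(bmd, bone, spec, seed = spec$seed) {
  inserts <- insert_rod_masks(spec)
  bm <- bone$values
  for (m in inserts) {
    if (any(m$values & bm))
      stop("insert rod geometry overlaps the bone", call. = FALSE)
  }
  grey <- array(spec$background_grey, dim(bmd))
  grey[bm] <- spec$g0 + spec$g1 * bmd$values[bm]
  for (q in seq_along(inserts)) {
    grey[inserts[[q]]$values] <- spec$g0 + spec$g1 * spec$insert_densities[q]
  }
  if (spec$ct_noise_sd > 0) {
    grey <- grey + with_seed(seed, array(rnorm(length(grey), sd = spec$ct_noise_sd), dim(grey)))
  }
  list(ct = with_values(bmd, grey), insert_masks = inserts,
       insert_densities = spec$insert_densities)
}

two_pool_signal <- function(phi, te, spec) {
  spec$a_bw * (1 - phi) * exp(-te / spec$t2s_bw) +
    spec$a_pw * phi * exp(-te / spec$t2s_pw)
}

#' Closed-form noiseless porosity index of the two-pool model
#'
#' `PI(phi) = 100 * S(te_long) / S(te_short)` with
#' `S(TE) = a_bw (1-phi) exp(-TE/T2*_bw) + a_pw phi exp(-TE/T2*_pw)`.
#' Strictly increasing in `phi` whenever `t2s_pw > t2s_bw`.
#'
#' @param phi Porosity values (vector, array or [voxel_grid()]).
#' @param spec A [phantom_spec()].
#' @return PI in percent, same shape as `phi` (a `voxel_grid` in, a
#'   `voxel_grid` out).
#' @export
ideal_pi <- function(phi, spec) {
  if (inherits(phi, "voxel_grid"))
    return(with_values(phi, ideal_pi(phi$values, spec)))
  100 * two_pool_signal(phi, spec$te_long, spec) /
    two_pool_signal(phi, spec$te_short, spec)
}

#' Render the dual-echo UTE MR volumes
#'
#' Evaluates the two-pool signal at both echo times on the CT grid (zero
#' outside bone), samples it onto the MR grid through the inverse of the true
#' alignment transform (so the MR volume is misaligned by exactly
#' `spec$misalignment`), and adds noise per the configured model.
#'
#' @param porosity Porosity [voxel_grid()] on the CT grid.
#' @param bone Bone mask grid.
#' @param spec A [phantom_spec()].
#' @param seed RNG seed.
#' @return List with `echo1` and `echo2` [voxel_grid()]s on the MR geometry.
#' @export
render_mr_echoes <- function(porosity, bone, spec, seed = spec$seed) {
  validate_phantom_spec(spec)
  mrg <- mr_geometry(spec)
  to_mr <- invert_affine(spec$misalignment)
  bm <- bone$values
  render_one <- function(te) {
    s <- array(0, dim(porosity))
    s[bm] <- two_pool_signal(porosity$values[bm], te, spec)
    resample(with_values(porosity, s), transform = to_mr, reference = mrg)
  }
  e1 <- render_one(spec$te_short)
  e2 <- render_one(spec$te_long)
  if (spec$mr_noise_sd > 0) {
    noise <- with_seed(seed, {
      n <- length(e1$values)
      if (spec$noise_model == "rician") {
        list(a1 = rnorm(n, sd = spec$mr_noise_sd), b1 = rnorm(n, sd = spec$mr_noise_sd),
             a2 = rnorm(n, sd = spec$mr_noise_sd), b2 = rnorm(n, sd = spec$mr_noise_sd))
      } else {
        list(a1 = rnorm(n, sd = spec$mr_noise_sd), a2 = rnorm(n, sd = spec$mr_noise_sd))
      }
    })
    d <- dim(e1)
    if (spec$noise_model == "rician") {
      e1 <- with_values(e1, array(sqrt((e1$values + noise$a1)^2 + noise$b1^2), d))
      e2 <- with_values(e2, array(sqrt((e2$values + noise$a2)^2 + noise$b2^2), d))
    } else {
      e1 <- with_values(e1, e1$values + array(noise$a1, d))
      e2 <- with_values(e2, e2$values + array(noise$a2, d))
    }
  }
  list(echo1 = e1, echo2 = e2)
}

#' Simulate one complete specimen
#'
#' Runs the full forward model: porosity field, BMD field, CT rendering with
#' calibration rods, and misaligned dual-echo MR volumes, returning the
#' images together with the ground truth needed for parameter-recovery
#' testing (fields, masks, the true alignment transform, and the true
#' voxel-wise Pearson correlation between BMD and the ideal noiseless PI
#' inside the condyle mask).
#'
#' @param spec A [phantom_spec()].
#' @param seed RNG seed.
#' @return An object of class `bone_specimen`: list with `ct`, `echo1`,
#'   `echo2`, `spec`, and `truth` (fields, masks, `transform`, `true_r`).
#' @export
simulate_specimen <- function(spec = phantom_spec(), seed = spec$seed) {
  seeds <- derive_seeds(seed, 4)
  geom <- make_porosity_field(spec, seeds[1])
  bmd <- make_bmd_field(geom$porosity, geom$bone, spec, seeds[2])
  ctr <- render_ct(bmd, geom$bone, spec, seeds[3])
  mr <- render_mr_echoes(geom$porosity, geom$bone, spec, seeds[4])
  pi_true <- ideal_pi(geom$porosity, spec)
  cm <- geom$condyle$values
  true_r <- cor(bmd$values[cm], pi_true$values[cm])
  structure(list(
    ct = ctr$ct, echo1 = mr$echo1, echo2 = mr$echo2, spec = spec,
    truth = list(
      porosity = geom$porosity, bmd = bmd, ideal_pi = pi_true,
      bone = geom$bone, shell = geom$shell, core = geom$core,
      condyle = geom$condyle,
      insert_masks = ctr$insert_masks,
      insert_densities = ctr$insert_densities,
      transform = spec$misalignment, true_r = true_r
    )
  ), class = "bone_specimen")
}

derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Lay out a synthetic study
#'
#' Builds the study design: horses x limbs, per-limb RNG seeds, per-limb
#' phantom variation (porosity-BMD coupling and MR noise drawn uniformly
#' from the given ranges) and exclusion flags. The default mirrors the study
#' shape of six horses with limbs LF, RF, LH, RH and one excluded right
#' forelimb, leaving 23 analyzable specimens.
#'
#' @param n_horses Number of horses.
#' @param limbs Limb labels per horse.
#' @param seed Study-level RNG seed.
#' @param base_spec A [phantom_spec()] supplying every non-varied parameter.
#' @param excluded Character vector of `"<horse>_<limb>"` ids to exclude.
#' @param coupling_range,mr_noise_range,bmd_noise_range Ranges for the
#'   per-limb uniform draws. The wide BMD-noise range models specimen-level
#'   heterogeneity in how tightly mineral density couples to porosity, which
#'   is what spreads the per-limb ground-truth correlations.
#' @param overrides Optional named list (by specimen id) of phantom_spec
#'   field overrides.
#' @return A tibble with one row per specimen: `specimen`, `horse`, `limb`,
#'   `excluded`, `coupling`, `mr_noise_sd`, `seed`, `spec` (list column).
#' @export
study_plan <- function(n_horses = 6,
                       limbs = c("LF", "RF", "LH", "RH"),
                       seed = 42,
                       base_spec = phantom_spec(),
                       excluded = "1_RF",
                       coupling_range = c(0.3, 0.45),
                       mr_noise_range = c(0.005, 0.01),
                       bmd_noise_range = c(60, 150),
                       overrides = NULL) {
  if (n_horses < 1) stop("`n_horses` must be at least 1", call. = FALSE)
  if (anyDuplicated(limbs)) stop("duplicate limb labels", call. = FALSE)
  plan <- tidyr::expand_grid(horse = seq_len(n_horses), limb = limbs)
  plan <- dplyr::mutate(plan, specimen = paste0(.data$horse, "_", .data$limb))
  n <- nrow(plan)
  draws <- with_seed(seed, list(
    coupling = runif(n, coupling_range[1], coupling_range[2]),
    mr_noise = runif(n, mr_noise_range[1], mr_noise_range[2]),
    bmd_noise = runif(n, bmd_noise_range[1], bmd_noise_range[2]),
    seeds = sample.int(.Machine$integer.max - 1L, n)
  ))
  plan$excluded <- plan$specimen %in% excluded
  plan$coupling <- draws$coupling
  plan$mr_noise_sd <- draws$mr_noise
  plan$bmd_noise_sd <- draws$bmd_noise
  plan$seed <- draws$seeds
  plan$spec <- purrr::pmap(
    list(plan$specimen, plan$coupling, plan$mr_noise_sd, plan$bmd_noise_sd),
    function(id, cpl, mrn, bmn) {
      sp <- base_spec
      sp$coupling <- cpl
      sp$mr_noise_sd <- mrn
      sp$bmd_noise_sd <- bmn
      for (nm in names(overrides[[id]])) sp[[nm]] <- overrides[[id]][[nm]]
      validate_phantom_spec(sp)
      sp
    }
  )
  dplyr::select(plan, "specimen", "horse", "limb", "excluded",
                "coupling", "mr_noise_sd", "bmd_noise_sd", "seed", "spec")
}

#' Generate and write a synthetic study to disk
#'
#' Simulates every non-excluded specimen of `plan` and writes a study
#' directory: one subdirectory per specimen holding `ct.nii.gz`,
#' `echo1.nii.gz`, `echo2.nii.gz`, the ground-truth fields and masks,
#' `truth_transform.txt`, `inserts.csv` and `spec.yaml`, plus a top-level
#' `manifest.csv`. Fully reproducible from the plan's seeds.
#'
#' @param plan A [study_plan()].
#' @param dir Study directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
generate_study <- function(plan = study_plan(), dir) {
  stopifnot(is.data.frame(plan), !missing(dir))
  if (anyDuplicated(plan$specimen)) stop("duplicate specimen ids in plan", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (row in seq_len(nrow(plan))) {
    if (plan$excluded[row]) next
    sdir <- file.path(dir, plan$specimen[row])
    dir.create(sdir, showWarnings = FALSE)
    b <- simulate_specimen(plan$spec[[row]], seed = plan$seed[row])
    write_volume(b$ct, file.path(sdir, "ct.nii.gz"), "float")
    write_volume(b$echo1, file.path(sdir, "echo1.nii.gz"), "float")
    write_volume(b$echo2, file.path(sdir, "echo2.nii.gz"), "float")
    write_volume(b$truth$porosity, file.path(sdir, "truth_porosity.nii.gz"), "float")
    write_volume(b$truth$bmd, file.path(sdir, "truth_bmd.nii.gz"), "float")
    write_volume(b$truth$bone, file.path(sdir, "truth_bone.nii.gz"), "uint8")
    write_volume(b$truth$condyle, file.path(sdir, "truth_condyle.nii.gz"), "uint8")
    labels <- array(0, dim(b$ct))
    for (q in seq_along(b$truth$insert_masks))
      labels[b$truth$insert_masks[[q]]$values] <- q
    write_volume(with_values(b$ct, labels), file.path(sdir, "truth_inserts.nii.gz"), "uint8")
    write.csv(data.frame(label = seq_along(b$truth$insert_densities),
                         density = b$truth$insert_densities),
              file.path(sdir, "inserts.csv"), row.names = FALSE)
    write_affine(b$truth$transform, file.path(sdir, "truth_transform.txt"))
    spec_to_yaml(b$spec, file.path(sdir, "spec.yaml"))
  }
  manifest <- dplyr::select(plan, "specimen", "horse", "limb", "excluded",
                            "coupling", "mr_noise_sd", "bmd_noise_sd", "seed")
  manifest$true_r <- NA_real_
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(tibble::as_tibble(manifest))
}

#' Load a specimen written by [generate_study()]
#'
#' @param sdir Specimen subdirectory.
#' @return A `bone_specimen` (without the ideal-PI convenience fields,
#'   which are recomputed from the porosity and spec).
#' @export
load_specimen <- function(sdir) {
  need <- file.path(sdir, c("ct.nii.gz", "echo1.nii.gz", "echo2.nii.gz"))
  if (!all(file.exists(need)))
    stop("not a specimen directory (missing volumes): ", sdir, call. = FALSE)
  spec <- spec_from_yaml(file.path(sdir, "spec.yaml"))
  porosity <- read_volume(file.path(sdir, "truth_porosity.nii.gz"))
  bmd <- read_volume(file.path(sdir, "truth_bmd.nii.gz"))
  bone <- as_mask(read_volume(file.path(sdir, "truth_bone.nii.gz")), 0.5)
  condyle <- as_mask(read_volume(file.path(sdir, "truth_condyle.nii.gz")), 0.5)
  labels <- read_volume(file.path(sdir, "truth_inserts.nii.gz"))
  ins <- read.csv(file.path(sdir, "inserts.csv"))
  insert_masks <- lapply(ins$label, function(q) as_mask(with_values(labels, labels$values == q)))
  pi_true <- ideal_pi(porosity, spec)
  cm <- condyle$values
  structure(list(
    ct = read_volume(file.path(sdir, "ct.nii.gz")),
    echo1 = read_volume(file.path(sdir, "echo1.nii.gz")),
    echo2 = read_volume(file.path(sdir, "echo2.nii.gz")),
    spec = spec,
    truth = list(
      porosity = porosity, bmd = bmd, ideal_pi = pi_true,
      bone = bone, condyle = condyle,
      insert_masks = insert_masks, insert_densities = ins$density,
      transform = read_affine(file.path(sdir, "truth_transform.txt")),
      true_r = cor(bmd$values[cm], pi_true$values[cm])
    )
  ), class = "bone_specimen")
}

spec_to_yaml <- function(spec, path) {
  out <- unclass(spec)
  out$misalignment <- list(
    matrix = as.numeric(spec$misalignment$matrix),
    translation = spec$misalignment$translation
  )
  out$seed <- if (is.null(spec$seed)) NA else spec$seed
  yaml::write_yaml(out, path)
  invisible(path)
}

spec_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  mis <- affine3d(matrix(raw$misalignment$matrix, 3, 3), raw$misalignment$translation)
  raw$misalignment <- NULL
  raw$seed <- if (is.null(raw$seed) || is.na(raw$seed)) NULL else raw$seed
  args <- raw[names(raw) %in% names(formals(phantom_spec))]
  do.call(phantom_spec, c(args, list(misalignment = mis)))
}
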