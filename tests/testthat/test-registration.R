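fast_config <- function(...) {
  registration_config(max_samples = 12000, max_sweeps = 4, ...)
}

test_that("MI of an image with itself equals its histogram entropy", {
  g <- random_grid(c(24, 24, 24), seed = 41)
  mi <- mutual_information(g, g, bins = 32)
  v <- as.numeric(g$values)
  rng <- range(v)
  bin <- pmin(32, pmax(1, floor((v - rng[1]) / diff(rng) * 32) + 1))
  p <- tabulate(bin, 32) / length(v)
  entropy <- -sum(p[p > 0] * log2(p[p > 0]))
  expect_equal(mi, entropy, tolerance = 1e-10)
})

test_that("MI of independent images is near zero and of constants is zero", {
  a <- random_grid(c(48, 48, 48), seed = 42)
  b <- random_grid(c(48, 48, 48), seed = 43)
  expect_lt(mutual_information(a, b, bins = 32), 0.05)
  const <- voxel_grid(array(1, c(48, 48, 48)))
  expect_equal(mutual_information(a, const), 0)
})

test_that("MI is symmetric on identical grids", {
  a <- random_grid(c(16, 16, 16), seed = 44)
  b <- with_values(a, a$values^2 + 0.5 * random_grid(c(16, 16, 16), 45)$values)
  expect_equal(mutual_information(a, b), mutual_information(b, a),
               tolerance = 1e-10)
})

test_that("MI peaks at the true offset along a translation sweep", {
  sp <- small_spec(mr_noise_sd = 0.002)
  b <- simulate_specimen(sp, seed = 46)
  pim <- compute_pi(b$echo1, b$echo2)
  v <- pim$values$values; v[!pim$valid$values] <- 0
  mv <- with_values(pim$values, v)
  truth <- b$truth$transform
  offsets <- seq(-2, 2, by = 0.25)
  mis <- vapply(offsets, function(dx) {
    probe <- truth
    probe$translation <- truth$translation + c(dx, 0, 0)
    mutual_information(b$ct, mv, probe, max_samples = 20000)
  }, numeric(1))
  best <- offsets[which.max(mis)]
  expect_lte(abs(best), 0.5 * sp$ct_spacing[1] + 0.25) # grid resolution of the sweep
})

test_that("self-registration stays at the identity", {
  b <- simulate_specimen(small_spec(), seed = 47)
  reg <- register_affine(b$ct, b$ct, config = fast_config())
  ctr <- grid_center(b$ct)
  shift <- drop(apply_affine(reg$transform, ctr)) - ctr
  expect_lt(max(abs(shift)), 0.1 * min(b$ct$spacing))
  expect_lt(rotation_between(reg$transform, identity_affine()), 0.1)
})

test_that("registration recovers a known rigid misalignment", {
  sp <- small_spec()
  b <- simulate_specimen(sp, seed = 48)
  pim <- compute_pi(b$echo1, b$echo2)
  v <- pim$values$values; v[!pim$valid$values] <- 0
  reg <- register_affine(b$ct, with_values(pim$values, v),
                         config = fast_config())
  truth <- b$truth$transform
  ctr <- grid_center(b$ct)
  terr <- abs(drop(apply_affine(reg$transform, ctr)) -
                drop(apply_affine(truth, ctr)))
  # within half the coarser (MR) voxel per axis
  expect_true(all(terr < 0.5 * sp$mr_spacing))
  # rotation about the long axis is only weakly observable on the
  # nearly-spherical small cap; the full-size phantom pins it down
  expect_lt(rotation_between(reg$transform, truth), 4)
})

test_that("affine registration recovers rotation and anisotropic scale", {
  b <- simulate_specimen(phantom_spec(), seed = 49)
  ctr <- grid_center(b$ct)
  truth <- affine_from_params(translation = c(1.5, -0.8, 0.4),
                              rotation = c(0, 0, 5),
                              scale = c(1.02, 0.98, 1), center = ctr)
  moving <- resample(b$ct, transform = invert_affine(truth), reference = b$ct)
  reg <- register_affine(b$ct, moving)
  expect_lt(rotation_between(reg$transform, truth), 1)
  expect_true(all(abs(sort(decompose_affine(reg$transform)$scales) -
                        sort(decompose_affine(truth)$scales)) < 0.01))
})

test_that("median target-registration error stays below one CT voxel", {
  sp <- small_spec(mr_noise_sd = 0.005)
  set.seed(50)
  perturbs <- lapply(1:6, function(i) {
    list(t = runif(3, -4, 4), r = c(0, 0, runif(1, -5, 5)))
  })
  b0 <- simulate_specimen(sp, seed = 51)
  ctr <- grid_center(b0$ct)
  cond <- which(b0$truth$condyle$values)
  cond <- cond[seq(1, length(cond), by = 100)]
  d <- dim(b0$ct)
  ijk <- cbind((cond - 1) %% d[1], ((cond - 1) %/% d[1]) %% d[2],
               (cond - 1) %/% (d[1] * d[2]))
  xyz <- index_to_world(b0$ct, ijk)
  tres <- vapply(perturbs, function(pp) {
    mis <- affine_from_params(translation = pp$t, rotation = pp$r, center = ctr)
    spp <- small_spec(mr_noise_sd = 0.005, misalignment = mis)
    b <- simulate_specimen(spp, seed = 51)
    pim <- compute_pi(b$echo1, b$echo2)
    v <- pim$values$values; v[!pim$valid$values] <- 0
    reg <- register_affine(b$ct, with_values(pim$values, v),
                           config = fast_config(dof = "rigid"))
    md <- sqrt(rowSums((apply_affine(reg$transform, xyz) -
                          apply_affine(mis, xyz))^2))
    median(md)
  }, numeric(1))
  expect_lt(median(tres), max(sp$ct_spacing))
})

test_that("aligning PI maps preserves identity and propagates invalidity", {
  sp <- small_spec(misalignment = identity_affine())
  sp$mr_dim <- sp$ct_dim; sp$mr_spacing <- sp$ct_spacing; sp$mr_origin <- sp$ct_origin
  b <- simulate_specimen(sp, seed = 52)
  pim <- compute_pi(b$echo1, b$echo2)
  aligned <- align_pi_to_ct(pim, b$ct, identity_affine())
  expect_equal(aligned$values$values, pim$values$values, tolerance = 1e-9)
  expect_identical(aligned$valid$values, pim$valid$values)
  # all-invalid input stays all-invalid
  zero <- compute_pi(with_values(b$echo1, array(0, dim(b$echo1))), b$echo2,
                     floor = 0)
  out <- align_pi_to_ct(zero, b$ct, identity_affine())
  expect_equal(mask_count(out$valid), 0)
})

test_that("truth-transform alignment reproduces the ideal PI in the interior", {
  sp <- phantom_spec(mr_noise_sd = 0, ct_noise_sd = 0)
  b <- simulate_specimen(sp, seed = 53)
  pim <- compute_pi(b$echo1, b$echo2, floor = 0.05)
  aligned <- align_pi_to_ct(pim, b$ct, b$truth$transform)
  # interior: the condylar core eroded by the MR voxel footprint, so the
  # comparison is not dominated by partial-volume voxels at the shell edge
  core <- array(as.numeric(b$truth$core$values & b$truth$condyle$values),
                dim(b$ct))
  interior <- porindex:::cpp_local_minmax(core, dim(b$ct), 5L, FALSE)$lo > 0.5
  interior <- interior & aligned$valid$values
  err <- abs(aligned$values$values[interior] - b$truth$ideal_pi$values[interior])
  expect_lt(mean(err), 1)
})
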