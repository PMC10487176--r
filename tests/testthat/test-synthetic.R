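test_that("phantom_spec rejects degenerate physics", {
  expect_error(small_spec(te_short = 2.52, te_long = 2.52), "strictly below")
  expect_error(small_spec(t2s_bw = 10, t2s_pw = 0.39), "below pore-water")
  expect_error(small_spec(t2s_pw = -1), "positive")
  expect_error(small_spec(insert_densities = c(100, 100)), "distinct")
  expect_error(small_spec(shell = 10), "shell thickness")
  expect_error(small_spec(phi_trab = 1.2), "\\[0, 1\\]")
})

test_that("porosity field hits the configured levels without spatial noise", {
  sp <- small_spec(phi_sd = 0)
  geom <- make_porosity_field(sp, seed = 1)
  expect_true(all(geom$porosity$values[geom$shell$values] == sp$phi_cort))
  expect_true(all(geom$porosity$values[geom$core$values] == sp$phi_trab))
  expect_true(all(geom$porosity$values[!geom$bone$values] == 0))
  # condyle is contained in the bone
  expect_true(all(geom$bone$values[geom$condyle$values]))
  sp2 <- small_spec(phi_sd = 0, phi_cort = 0.3, phi_trab = 0.3)
  geom2 <- make_porosity_field(sp2, seed = 1)
  expect_true(all(geom2$porosity$values[geom2$bone$values] == 0.3))
})

test_that("shell porosity stays near the cortical level under spatial noise", {
  geom <- make_porosity_field(small_spec(), seed = 11)
  sp <- small_spec()
  expect_lt(abs(mean(geom$porosity$values[geom$shell$values]) - sp$phi_cort), 0.02)
  expect_gte(min(geom$porosity$values), 0)
  expect_lte(max(geom$porosity$values), 1)
})

test_that("BMD couples negatively and exactly to porosity without noise", {
  sp <- small_spec(bmd_noise_sd = 0)
  geom <- make_porosity_field(sp, seed = 2)
  zero_phi <- with_values(geom$porosity, array(0, dim(geom$porosity)))
  bmd0 <- make_bmd_field(zero_phi, geom$bone, sp, seed = 2)
  expect_true(all(bmd0$values[geom$bone$values] == sp$rho_max))
  bmd <- make_bmd_field(geom$porosity, geom$bone, sp, seed = 2)
  bm <- geom$bone$values
  expect_equal(cor(bmd$values[bm], geom$porosity$values[bm]), -1)
})

test_that("noisy BMD-porosity correlation matches the analytic attenuation", {
  sp <- small_spec()
  geom <- make_porosity_field(sp, seed = 3)
  bmd <- make_bmd_field(geom$porosity, geom$bone, sp, seed = 3)
  bm <- geom$bone$values
  r_obs <- cor(bmd$values[bm], geom$porosity$values[bm])
  signal <- sp$rho_max * sp$coupling * sd(geom$porosity$values[bm])
  r_ana <- -1 / sqrt(1 + (sp$bmd_noise_sd / signal)^2)
  expect_lt(abs(r_obs - r_ana), 0.05)
})

test_that("CT rendering follows the grey model and supports calibration", {
  sp <- small_spec(ct_noise_sd = 0, bmd_noise_sd = 0, g0 = 0, g1 = 1)
  geom <- make_porosity_field(sp, seed = 4)
  bmd <- make_bmd_field(geom$porosity, geom$bone, sp, seed = 4)
  ctr <- render_ct(bmd, geom$bone, sp, seed = 4)
  bm <- geom$bone$values
  expect_equal(ctr$ct$values[bm], bmd$values[bm])
  # water insert renders at g0
  sp2 <- small_spec(ct_noise_sd = 0, g0 = 40, g1 = 1.8,
                    insert_densities = c(0, 200))
  geom2 <- make_porosity_field(sp2, seed = 4)
  bmd2 <- make_bmd_field(geom2$porosity, geom2$bone, sp2, seed = 4)
  ct2 <- render_ct(bmd2, geom2$bone, sp2, seed = 4)
  m_water <- mean(ct2$ct$values[ct2$insert_masks[[1]]$values])
  m_200 <- mean(ct2$ct$values[ct2$insert_masks[[2]]$values])
  expect_equal(m_water, 40)
  expect_equal(m_200, 40 + 200 * 1.8)
  # two-point line through the noiseless means recovers (g0, g1)
  g1_hat <- (m_200 - m_water) / 200
  g0_hat <- m_water
  expect_equal(c(g0_hat, g1_hat), c(40, 1.8))
})

test_that("two-pool echo ratio matches the closed form", {
  sp <- small_spec()
  expect_equal(ideal_pi(0, sp), 100 * exp(-2.48 / 0.39), tolerance = 1e-12)
  expect_equal(ideal_pi(1, sp), 100 * exp(-2.48 / 10), tolerance = 1e-12)
  expect_equal(round(ideal_pi(1, sp), 1), 78.0)
  # rendered echoes reproduce the ratio on an aligned, noiseless phantom
  sp0 <- small_spec(mr_noise_sd = 0, phi_sd = 0,
                    misalignment = identity_affine())
  sp0$mr_dim <- sp0$ct_dim
  sp0$mr_spacing <- sp0$ct_spacing
  sp0$mr_origin <- sp0$ct_origin
  geom <- make_porosity_field(sp0, seed = 5)
  mr <- render_mr_echoes(geom$porosity, geom$bone, sp0, seed = 5)
  core <- geom$core$values
  ratio <- mr$echo2$values[core] / mr$echo1$values[core]
  expect_equal(unique(round(ratio, 10)),
               round(ideal_pi(sp0$phi_trab, sp0) / 100, 10))
})

test_that("ideal PI increases strictly with porosity", {
  sp <- small_spec()
  phi <- seq(0, 1, by = 0.01)
  expect_true(all(diff(ideal_pi(phi, sp)) > 0))
})

test_that("specimen simulation is deterministic and self-consistent", {
  sp <- small_spec()
  b1 <- simulate_specimen(sp, seed = 10)
  b2 <- simulate_specimen(sp, seed = 10)
  expect_identical(b1$ct$values, b2$ct$values)
  expect_identical(b1$echo1$values, b2$echo1$values)
  expect_lt(b1$truth$true_r, 0) # negative BMD-PI coupling by construction
  expect_true(all(b1$truth$bone$values[b1$truth$condyle$values]))
  # inserts disjoint from bone
  for (m in b1$truth$insert_masks)
    expect_false(any(m$values & b1$truth$bone$values))
})

test_that("study plans have the study shape and exclusions", {
  plan <- study_plan(n_horses = 6, seed = 1, base_spec = small_spec())
  expect_equal(nrow(plan), 24)
  expect_equal(sum(plan$excluded), 1)
  expect_equal(plan$specimen[plan$excluded], "1_RF")
  expect_equal(sum(!plan$excluded), 23)
  expect_error(study_plan(limbs = c("LF", "LF")), "duplicate")
  expect_error(study_plan(n_horses = 0), "at least 1")
  # per-limb draws are reproducible
  plan2 <- study_plan(n_horses = 6, seed = 1, base_spec = small_spec())
  expect_identical(plan$coupling, plan2$coupling)
  expect_identical(plan$seed, plan2$seed)
})

test_that("a generated study round-trips through its directory layout", {
  plan <- study_plan(n_horses = 1, limbs = c("LF", "RF"), seed = 3,
                     base_spec = small_spec(), excluded = character())
  dir1 <- file.path(tempdir(), "study_a")
  dir2 <- file.path(tempdir(), "study_b")
  man <- generate_study(plan, dir1)
  generate_study(plan, dir2)
  expect_equal(nrow(man), 2)
  expect_true(file.exists(file.path(dir1, "manifest.csv")))
  f1 <- file.path(dir1, "1_LF", "ct.nii.gz")
  f2 <- file.path(dir2, "1_LF", "ct.nii.gz")
  expect_identical(read_volume(f1)$values, read_volume(f2)$values)
  b <- load_specimen(file.path(dir1, "1_LF"))
  direct <- simulate_specimen(plan$spec[[1]], seed = plan$seed[1])
  expect_equal(b$ct$values, direct$ct$values, tolerance = 1e-6)
  expect_equal(b$truth$transform$matrix, direct$truth$transform$matrix,
               tolerance = 1e-12)
  expect_equal(b$truth$true_r, direct$truth$true_r, tolerance = 1e-4)
  unlink(c(dir1, dir2), recursive = TRUE)
})
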