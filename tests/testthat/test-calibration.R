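two_insert_ct <- function(grey_a, grey_b) {
  vals <- array(0, c(6, 6, 6))
  vals[1:2, , ] <- grey_a
  vals[5:6, , ] <- grey_b
  ct <- voxel_grid(vals)
  mask_a <- with_values(ct, array(slice.index(vals, 1) <= 2, dim(vals)))
  mask_b <- with_values(ct, array(slice.index(vals, 1) >= 5, dim(vals)))
  list(ct = ct, a = mask_a, b = mask_b)
}

test_that("two inserts give the exact line through their mean greys", {
  f <- two_insert_ct(100, 300)
  model <- fit_calibration(f$ct, list(list(mask = f$a, density = 0),
                                      list(mask = f$b, density = 200)))
  expect_equal(model$a, 1)
  expect_equal(model$b, -100)
  expect_equal(model$r_squared, 1)
  f2 <- two_insert_ct(0, 1)
  m2 <- fit_calibration(f2$ct, list(list(mask = f2$a, density = 0),
                                    list(mask = f2$b, density = 1)))
  expect_equal(c(m2$a, m2$b), c(1, 0))
})

test_that("degenerate insert configurations are rejected", {
  f <- two_insert_ct(100, 100)
  expect_error(fit_calibration(f$ct, list(list(mask = f$a, density = 0),
                                          list(mask = f$b, density = 200))),
               "degenerate")
  expect_error(fit_calibration(f$ct, list(list(mask = f$a, density = 50),
                                          list(mask = f$b, density = 50))),
               "all equal")
  empty <- with_values(f$ct, array(FALSE, dim(f$ct)))
  expect_error(fit_calibration(f$ct, list(list(mask = empty, density = 0),
                                          list(mask = f$b, density = 200))),
               "empty")
  expect_error(fit_calibration(f$ct, list(list(mask = f$a, density = 0))),
               "at least 2")
})

test_that("calibration inverts the synthetic grey model within 1%", {
  sp <- small_spec(g0 = 40, g1 = 1.8)
  b <- simulate_specimen(sp, seed = 21)
  inserts <- purrr::map2(b$truth$insert_masks, b$truth$insert_densities,
                         function(m, d) list(mask = m, density = d))
  model <- fit_calibration(b$ct, inserts)
  expect_lt(abs(model$a - 1 / sp$g1) / (1 / sp$g1), 0.01)
  expect_lt(abs(model$b - (-sp$g0 / sp$g1)) / abs(sp$g0 / sp$g1), 0.01)
})

test_that("calibration is invariant to a common grey offset", {
  f <- two_insert_ct(100, 300)
  m1 <- fit_calibration(f$ct, list(list(mask = f$a, density = 0),
                                   list(mask = f$b, density = 200)))
  shifted <- with_values(f$ct, f$ct$values + 500)
  m2 <- fit_calibration(shifted, list(list(mask = f$a, density = 0),
                                      list(mask = f$b, density = 200)))
  expect_equal(m2$a, m1$a)
  expect_equal(m2$b, m1$b - m1$a * 500)
})

test_that("applying a calibration maps grey to BMD voxel-wise", {
  f <- two_insert_ct(100, 300)
  model <- fit_calibration(f$ct, list(list(mask = f$a, density = 0),
                                      list(mask = f$b, density = 200)))
  out <- apply_calibration(f$ct, model)
  expect_equal(out$values, f$ct$values * model$a + model$b)
  ident <- model; ident$a <- 1; ident$b <- 0
  expect_identical(apply_calibration(f$ct, ident)$values, f$ct$values)
  clamped <- apply_calibration(f$ct, model, clamp = TRUE)
  expect_gte(min(clamped$values), 0)
})

test_that("noiseless fit-then-apply recovers ground-truth BMD exactly", {
  sp <- small_spec(ct_noise_sd = 0)
  b <- simulate_specimen(sp, seed = 22)
  inserts <- purrr::map2(b$truth$insert_masks, b$truth$insert_densities,
                         function(m, d) list(mask = m, density = d))
  bmd <- apply_calibration(b$ct, fit_calibration(b$ct, inserts))
  bm <- b$truth$bone$values
  expect_equal(bmd$values[bm], b$truth$bmd$values[bm], tolerance = 1e-9)
})

test_that("calibrated BMD error stays within the propagated noise level", {
  sp <- small_spec()
  b <- simulate_specimen(sp, seed = 23)
  inserts <- purrr::map2(b$truth$insert_masks, b$truth$insert_densities,
                         function(m, d) list(mask = m, density = d))
  bmd <- apply_calibration(b$ct, fit_calibration(b$ct, inserts))
  bm <- b$truth$bone$values
  mae <- mean(abs(bmd$values[bm] - b$truth$bmd$values[bm]))
  expect_lt(mae, 1.5 * sp$ct_noise_sd / sp$g1)
})
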