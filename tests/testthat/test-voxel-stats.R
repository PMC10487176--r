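pairs_to_grids <- function(x, y) {
  n <- length(x)
  d <- c(n, 1, 1)
  bmd <- voxel_grid(array(x, d))
  pim <- structure(list(
    values = voxel_grid(array(y, d)),
    valid = voxel_grid(array(TRUE, d)),
    floor = 0, n_above_100 = 0
  ), class = "pi_map")
  roi <- voxel_grid(array(TRUE, d))
  list(bmd = bmd, pi = pim, roi = roi)
}

test_that("a perfect line gives exact slope and r = -1", {
  f <- pairs_to_grids(c(0, 1, 2), c(10, 8, 6))
  reg <- regress_specimen(f$bmd, f$pi, f$roi)
  expect_equal(reg$slope, -2)
  expect_equal(reg$r, -1)
  expect_equal(reg$p, 0)
})

test_that("the three-point hand-worked example reproduces to 5 decimals", {
  f <- pairs_to_grids(c(0, 1, 2), c(10, 8, 7))
  reg <- regress_specimen(f$bmd, f$pi, f$roi)
  expect_equal(reg$slope, -1.5)
  expect_equal(round(reg$r, 5), -0.98198)
})

test_that("regression matches the independent lm/cor.test oracle to 1e-10", {
  set.seed(61)
  x <- rnorm(1e4, 800, 200)
  y <- -0.01 * x + 20 + rnorm(1e4, 0, 5)
  f <- pairs_to_grids(x, y)
  reg <- regress_specimen(f$bmd, f$pi, f$roi)
  fit <- lm(y ~ x)
  ct <- cor.test(x, y)
  expect_equal(reg$slope, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(reg$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
  expect_equal(reg$slope_se, summary(fit)$coefficients[2, 2], tolerance = 1e-10)
  expect_equal(reg$r, unname(ct$estimate), tolerance = 1e-10)
  expect_equal(reg$p, ct$p.value, tolerance = 1e-10)
  expect_equal(reg$n, 1e4)
})

test_that("degenerate regressions are rejected", {
  f <- pairs_to_grids(c(0, 1), c(1, 2))
  expect_error(regress_specimen(f$bmd, f$pi, f$roi), "at least 3")
  g <- pairs_to_grids(c(1, 1, 1), c(1, 2, 3))
  expect_error(regress_specimen(g$bmd, g$pi, g$roi), "predictor variance")
})

test_that("r is scale-invariant while the slope rescales exactly", {
  set.seed(62)
  x <- rnorm(500); y <- -x + rnorm(500)
  a <- regress_specimen(pairs_to_grids(x, y)$bmd, pairs_to_grids(x, y)$pi,
                        pairs_to_grids(x, y)$roi)
  f2 <- pairs_to_grids(10 * x, y)
  b <- regress_specimen(f2$bmd, f2$pi, f2$roi)
  expect_equal(b$r, a$r, tolerance = 1e-12)
  expect_equal(b$slope, a$slope / 10, tolerance = 1e-12)
})

test_that("correlation labels follow the conventional bands on rounded |r|", {
  expect_equal(correlation_label(-0.16), "very weak")
  expect_equal(correlation_label(-0.43), "moderate")
  expect_equal(correlation_label(0), "very weak")
  expect_equal(correlation_label(c(0.195, 0.2, 0.399, 0.6, 0.81)),
               c("weak", "weak", "moderate", "strong", "very strong"))
  expect_error(correlation_label(1.2), "\\[-1, 1\\]")
})

test_that("group summaries report sample statistics with n-1 denominator", {
  s <- group_summary(c(1, 2, 3), "demo")
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(round(s$se, 5), 0.57735)
  expect_equal(c(s$min, s$max), c(1, 3))
  expect_error(group_summary(1), "at least 2")
})

test_that("Jarque-Bera follows its moment definition", {
  jb <- jarque_bera(c(-1, 0, 1))
  expect_equal(jb$statistic, 0.28125)
  expect_equal(jb$p, pchisq(0.28125, 2, lower.tail = FALSE))
  set.seed(63)
  big <- jarque_bera(rnorm(1e5))
  expect_gt(big$p, 0.01)
  expect_error(jarque_bera(rep(2, 10)), "zero variance")
  expect_error(jarque_bera(c(1, 2)), "at least 3")
})

test_that("two-sample comparisons cover Student, Welch and the null case", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  st <- compare_groups(c(1, 2, 3), c(4, 5, 6), "student")
  expect_equal(round(st$t, 3), -3.674)
  expect_equal(st$df, 4)
  expect_equal(st$t, unname(t.test(c(1, 2, 3), c(4, 5, 6),
                                   var.equal = TRUE)$statistic))
  we <- compare_groups(c(1, 2, 3), c(4, 5, 600), "welch")
  expect_lt(we$df, 4)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("the study table enforces keys and handles degenerate studies", {
  dup <- tibble::tibble(horse = c(1, 1), limb = c("LF", "LF"),
                        slope = c(-1, -1), r = c(-0.2, -0.3))
  expect_error(build_study_table(dup), "duplicate")
  single <- tibble::tibble(horse = 1:2, limb = c("LF", "LF")[1:2],
                           slope = c(-1, -2), r = c(-0.2, -0.3))
  single$limb <- c("LF", "LF"); single$horse <- 1:2
  st <- build_study_table(single)
  expect_gt(length(st$skipped), 0)
  expect_equal(nrow(st$table), 2)
})

test_that("the packaged study table reproduces its published structure", {
  st <- reproduce_table1()
  expect_equal(nrow(st$table), 24)
  expect_equal(sum(!st$table$excluded), 23)
  expect_equal(st$table$label[st$table$horse == 3 & st$table$limb == "RH"],
               "moderate")
  expect_equal(st$table$label[st$table$horse == 1 & st$table$limb == "LF"],
               "very weak")
  g <- glance(st)
  expect_equal(round(g$mean_r, 2), -0.29)
  expect_equal(nrow(st$comparisons), 4)
})
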