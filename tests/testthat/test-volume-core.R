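test_that("voxel_grid validates its geometry", {
  expect_error(voxel_grid(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)), "positive")
  expect_error(voxel_grid(array(0, c(2, 2))), "3D")
  expect_error(voxel_grid(array(0, c(2, 2, 2)), direction = matrix(1, 3, 3)),
               "orthonormal")
  g <- voxel_grid(array(1, c(3, 4, 5)), spacing = c(0.273, 0.273, 0.4))
  expect_equal(dim(g), c(3L, 4L, 5L))
  expect_equal(grid_extent(g), c(2 * 0.273, 3 * 0.273, 4 * 0.4))
})

test_that("index/world maps are mutually inverse", {
  g <- voxel_grid(array(0, c(5, 6, 7)), spacing = c(0.5, 1, 2),
                  origin = c(-3, 2, 1))
  ijk <- cbind(c(0, 1.5, 4), c(0, 2.25, 5), c(0, 3, 6))
  expect_equal(world_to_index(g, index_to_world(g, ijk)), ijk)
  expect_equal(drop(index_to_world(g, c(0, 0, 0))), g$origin)
})

test_that("NIfTI round trip is lossless for doubles and preserves geometry", {
  g <- random_grid(c(32, 32, 32), seed = 5, spacing = c(0.273, 0.273, 0.4))
  g$origin <- c(1.5, -2, 3)
  path <- tempfile(fileext = ".nii.gz")
  write_volume(g, path)
  h <- read_volume(path)
  expect_identical(h$values, g$values)
  # the NIfTI header stores pixdim in single precision
  expect_equal(h$spacing, c(0.273, 0.273, 0.4), tolerance = 1e-7)
  expect_equal(h$origin, g$origin)
  expect_equal(h$direction, diag(3))
})

test_that("mask volumes round trip with values in {0,1}", {
  m <- voxel_grid(array(c(TRUE, FALSE), c(8, 8, 8)))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(m, path, "uint8")
  h <- read_volume(path)
  expect_true(all(h$values %in% c(0, 1)))
  expect_equal(h$values > 0.5, m$values == TRUE, ignore_attr = TRUE)
})

test_that("reading fails cleanly for missing or unsupported files", {
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
  bad <- tempfile(fileext = ".txt")
  writeLines("x", bad)
  expect_error(read_volume(bad), "unsupported")
})

test_that("affine transforms compose, invert and round trip through text", {
  t1 <- affine_from_params(translation = c(1, -2, 0.5), rotation = c(10, -5, 3),
                           scale = c(1.1, 0.9, 1), shear = c(0.05, 0, -0.02))
  comp <- compose_affine(t1, invert_affine(t1))
  expect_lt(max(abs(comp$matrix - diag(3))), 1e-9)
  expect_lt(max(abs(comp$translation)), 1e-9)
  expect_error(affine3d(matrix(0, 3, 3)), "invertible")
  path <- tempfile(fileext = ".txt")
  write_affine(t1, path)
  t2 <- read_affine(path)
  expect_equal(t2$matrix, t1$matrix)
  expect_equal(t2$translation, t1$translation)
})

test_that("resampling with the identity transform reproduces the input", {
  g <- random_grid(c(12, 12, 12), seed = 2)
  expect_identical(resample(g, interpolation = "nearest")$values, g$values)
  expect_equal(resample(g, interpolation = "linear")$values, g$values,
               tolerance = 1e-12)
})

test_that("translating by one voxel spacing shifts the array by one index", {
  g <- random_grid(c(10, 10, 10), seed = 3, spacing = c(0.5, 1, 2))
  for (axis in 1:3) {
    tr <- c(0, 0, 0)
    tr[axis] <- g$spacing[axis]
    out <- resample(g, affine3d(translation = tr), g, "linear")
    # output voxel i samples moving at index i+1 along `axis`
    idx_in <- list(1:10, 1:10, 1:10)
    idx_out <- idx_in
    idx_in[[axis]] <- 2:10
    idx_out[[axis]] <- 1:9
    expect_equal(do.call(`[`, c(list(out$values), idx_out)),
                 do.call(`[`, c(list(g$values), idx_in)),
                 tolerance = 1e-12)
  }
})

test_that("resampling preserves constants and respects the value range", {
  const <- voxel_grid(array(7, c(16, 16, 16)))
  tr <- affine_from_params(translation = c(0.3, -0.2, 0.1), rotation = c(0, 0, 4),
                           center = c(7.5, 7.5, 7.5))
  out <- resample(const, tr, const, "linear", fill = NA)
  inner <- out$values[4:13, 4:13, 4:13]
  expect_true(all(inner[!is.na(inner)] == 7))
  g <- random_grid(c(16, 16, 16), seed = 9)
  res <- resample(g, tr, g, "linear")
  expect_gte(min(res$values), min(g$values))
  expect_lte(max(res$values), max(g$values))
})

test_that("downsampling by block mean halves the grid and preserves means", {
  g <- random_grid(c(8, 8, 8), seed = 4)
  d2 <- downsample_grid(g, 2)
  expect_equal(dim(d2), c(4L, 4L, 4L))
  expect_equal(d2$values[1, 1, 1], mean(g$values[1:2, 1:2, 1:2]))
  expect_equal(mean(d2$values), mean(g$values))
  expect_equal(d2$spacing, g$spacing * 2)
})
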