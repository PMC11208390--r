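test_that("voxel_grid enforces geometry and role invariants", {
  expect_error(voxel_grid(matrix(0, 2, 2)), "3-D")
  expect_error(voxel_grid(array(0, c(2, 2, 2)), spacing = c(1, -1, 1)),
               "positive")
  expect_error(voxel_grid(array(-1, c(2, 2, 2)), role = "density"),
               "non-negative")
  g <- voxel_grid(array(1, c(2, 3, 4)), c(1, 2, 3), c(0, 0, 10), "dose")
  h <- grid_like(g, g$values * 2)
  expect_true(grids_aligned(g, h))
  expect_false(grids_aligned(g, voxel_grid(array(1, c(2, 3, 4)),
                                           c(1, 2, 3), c(0, 0, 11), "dose")))
})

test_that("HU-to-density interpolates the anchors and stays monotone", {
  tab <- material_table()
  ct <- function(hu) voxel_grid(array(hu, c(1, 1, 1)), 1, role = "HU")
  rho <- function(hu) hu_to_density(ct(hu), tab)$values[1]
  expect_equal(rho(-1000), 0.00121)
  expect_equal(rho(0), 1.000)
  # halfway between two anchors -> mean of their densities
  expect_equal(rho(30), (1.000 + 1.06) / 2)
  expect_equal(rho((-1000 - 740) / 2), (0.00121 + 0.26) / 2)
  # clamped at the extreme anchors
  expect_equal(rho(-2000), 0.00121)
  expect_equal(rho(5000), 1.90)
  # monotone non-decreasing over a sweep
  hu <- seq(-1200, 2000, by = 7)
  grid <- voxel_grid(array(hu, c(length(hu), 1, 1)), 1, role = "HU")
  d <- hu_to_density(grid, tab)$values
  expect_true(all(diff(as.vector(d)) >= 0))
  expect_error(material_table(hu = c(0, 0), density = c(1, 1)), "increasing")
  expect_error(material_table(hu = c(0, 10), density = c(1, 0.5)),
               "non-decreasing")
})

test_that("material binning assigns air / lung / soft tissue / bone", {
  hu <- c(-1000, -740, 0, 60, 500)
  ct <- voxel_grid(array(hu, c(5, 1, 1)), 1, role = "HU")
  m <- hu_to_material(ct)
  mats <- attr(m, "materials")[as.vector(m$values)]
  expect_equal(mats, c("air", "lung", "soft_tissue", "soft_tissue", "bone"))
})

test_that("zero-padding reaches the next stride multiple plus the halo", {
  g <- voxel_grid(array(runif(64 * 64 * 42), c(64, 64, 42)), 9.59)
  expect_equal(dim(zero_pad(g, 32, 0)$grid$values), c(64, 64, 64))
  expect_equal(dim(zero_pad(g, 32, 4)$grid$values), c(72, 72, 72))
  expect_equal(dim(zero_pad(g, 24, 0)$grid$values), c(72, 72, 48))
})

test_that("crop_back inverts zero_pad exactly for arbitrary shapes", {
  set.seed(42)
  for (i in 1:8) {
    d <- sample(3:17, 3, replace = TRUE)
    g <- voxel_grid(array(rnorm(prod(d)), d), runif(1, 0.5, 5),
                    rnorm(3), "other")
    stride <- sample(1:9, 1)
    extra <- sample(0:3, 1)
    p <- zero_pad(g, stride, extra)
    back <- crop_back(p$grid, p$record)
    expect_identical(back$values, g$values)
    expect_equal(back$origin, g$origin)
    # pads are consistent with the record
    expect_equal(p$record$original_dim + p$record$low + p$record$high,
                 dim(p$grid$values))
  }
})

test_that("resampling onto the identical geometry is the identity", {
  g <- voxel_grid(array(rnorm(5 * 6 * 7), c(5, 6, 7)), c(2, 3, 1),
                  c(1, 2, 3), "other")
  for (mode in c("linear", "nearest")) {
    r <- resample_to(g, dim(g$values), g$spacing, g$origin, mode)
    expect_equal(r$values, g$values, tolerance = 1e-12)
  }
})

test_that("resampling a linear ramp reproduces the closed form", {
  # values equal to the physical x-coordinate of each voxel centre
  d <- c(17, 5, 5)
  xc <- (seq_len(d[1]) - 1) * 2  # spacing 2 mm, origin 0
  g <- voxel_grid(array(rep(xc, times = d[2] * d[3]), d), c(2, 2, 2),
                  c(0, 0, 0), "other")
  # 2x coarser grid strictly inside the support
  r <- resample_to(g, c(7, 2, 2), c(4, 4, 4), c(2, 2, 2), "linear")
  expect_equal(r$values[, 1, 1], 2 + (0:6) * 4, tolerance = 1e-12)
  # constant volume resamples to the same constant inside the support
  cg <- voxel_grid(array(7, d), c(2, 2, 2), c(0, 0, 0), "other")
  rc <- resample_to(cg, c(5, 2, 2), c(3, 3, 3), c(1, 1, 1), "linear")
  expect_true(all(rc$values == 7))
  # out-of-support HU fill is air
  hu <- voxel_grid(array(0, c(4, 4, 4)), 1, role = "HU")
  rr <- resample_to(hu, c(4, 4, 4), 1, origin = c(10, 0, 0))
  expect_true(all(rr$values[3:4, , ] == -1000))
  expect_error(resample_to(g, c(0, 5, 5), 1), "degenerate")
})

test_that("volumes round-trip through NIfTI with geometry and role", {
  g <- voxel_grid(array(runif(4 * 5 * 6), c(4, 5, 6)), c(2, 2, 2.5),
                  c(-10, 0, 5), "activity")
  path <- tempfile(fileext = ".nii.gz")
  write_volume(g, path)
  h <- read_volume(path)
  expect_equal(h$values, g$values, tolerance = 1e-6)
  expect_equal(h$spacing, g$spacing, tolerance = 1e-6)
  expect_equal(h$origin, g$origin)
  expect_equal(h$role, "activity")
  unlink(c(path, sub("\\.nii\\.gz$", ".json", path)))
})
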