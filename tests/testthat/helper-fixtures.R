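# Fixtures are built in code; nothing is read from disk.

# homogeneous water block with uniform source in the interior
water_block <- function(n = 8, voxel_mm = 9.59, rho = 1.0) {
  dens <- voxel_grid(array(rho, c(n, n, n)), voxel_mm, role = "density")
  tia <- array(0, c(n, n, n))
  core <- 2:(n - 1)
  tia[core, core, core] <- 1
  list(density = dens, tia = voxel_grid(tia, voxel_mm, role = "tia"))
}

# uniform-TIA / zero-density-agnostic pair on the study grid for layout tests
uniform_study_pair <- function(dims = c(64, 64, 42), voxel_mm = 9.59) {
  tia <- voxel_grid(array(1, dims), voxel_mm, role = "tia")
  geom <- voxel_grid(array(1, dims), voxel_mm, role = "density")
  list(tia = tia, geometry = geom)
}

expect_grid_equal <- function(a, b, tol = 0) {
  expect_true(grids_aligned(a, b))
  if (tol == 0) expect_identical(a$values, b$values)
  else expect_lt(max(abs(a$values - b$values)), tol)
}
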