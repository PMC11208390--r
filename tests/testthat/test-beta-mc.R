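test_that("the bundled beta spectrum is a normalised density with the right support", {
  sp <- beta_spectrum()
  binw <- sp$e_max / length(sp$e)
  expect_lt(abs(sum(sp$pdf * binw) - 1), 1e-6)
  expect_true(all(sp$pdf >= 0))
  expect_equal(sp$e_max, 2.28)
  expect_gt(sp$mean_mev, 0.90)
  expect_lt(sp$mean_mev, 0.96)
})

test_that("energy sampling matches the tabulated spectrum", {
  sp <- beta_spectrum()
  set.seed(7)
  e <- sample_beta_energy(sp, 1e5)
  expect_true(all(e > 0 & e <= sp$e_max))
  # 4-sigma band around the quadrature mean of the fine table
  w <- sp$cdf; de <- diff(sp$cdf_e)
  dens <- diff(w) / de
  mids <- (sp$cdf_e[-1] + head(sp$cdf_e, -1)) / 2
  mu <- sum(mids * dens * de)
  sdv <- sqrt(sum((mids - mu)^2 * dens * de))
  expect_lt(abs(mean(e) - mu), 4 * sdv / sqrt(length(e)))
  # degenerate one-line spectrum
  expect_equal(unique(sample_beta_energy(mono_spectrum(0.5), 100)), 0.5)
})

test_that("decay positions follow the TIA distribution", {
  # single nonzero voxel: every sample lies inside it
  tia <- voxel_grid(array(c(0, 0, 3, 0), c(4, 1, 1)), 10, role = "tia")
  set.seed(1)
  s <- sample_decay_position(tia, 200)
  expect_true(all(s$index[, 1] == 3))
  expect_true(all(s$position_mm[, 1] >= 15 & s$position_mm[, 1] <= 25))
  # 1:3 weights: empirical fraction within 4-sigma binomial band of 0.25
  tia2 <- voxel_grid(array(c(1, 3), c(2, 1, 1)), 1, role = "tia")
  set.seed(2)
  s2 <- sample_decay_position(tia2, 1e4)
  frac <- mean(s2$index[, 1] == 1)
  expect_lt(abs(frac - 0.25), 4 * sqrt(0.25 * 0.75 / 1e4))
  # uniform TIA: chi-square over voxel counts not rejected at alpha=0.001
  tia3 <- voxel_grid(array(1, c(4, 4, 4)), 1, role = "tia")
  set.seed(3)
  s3 <- sample_decay_position(tia3, 6400)
  lin <- (s3$index[, 3] - 1) * 16 + (s3$index[, 2] - 1) * 4 + s3$index[, 1]
  counts <- tabulate(lin, 64)
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
  expect_error(sample_decay_position(grid_like(tia, 0 * tia$values), 1),
               "all-zero")
})

test_that("single histories conserve energy and respect the CSDA range", {
  n <- 31
  water <- voxel_grid(array(1.0, c(n, n, n)), 2, role = "density")
  ctr <- rep(n / 2 * 2, 3)
  cfg_straight <- transport_config(multiple_scattering = FALSE)
  for (e0 in c(0.2, 0.9337, 2.28)) {
    h <- transport_history(ctr, c(1, 0.3, -0.2), e0, water,
                           cfg_straight, seed = 5)
    expect_lt(abs(sum(h$edep) + h$escaped - e0) / e0, 1e-9)
    # straight track cannot exceed the CSDA range (g/cm2 -> mm in water)
    # beyond the finite-step integration error of the stepping scheme
    expect_lte(h$path_mm, csda_range(e0) * 10 * 1.005 + 1e-3)
  }
  # birth below the cutoff: everything deposits in the birth voxel
  hb <- transport_history(ctr, c(0, 0, 1), 0.010, water,
                          transport_config(cutoff_kev = 15), seed = 1)
  expect_equal(hb$escaped, 0)
  expect_equal(sum(hb$edep > 0), 1L)
  expect_equal(sum(hb$edep), 0.010)
  # scattered tracks still conserve energy exactly
  hs <- transport_history(ctr, c(0, 0, 1), 1.5, water,
                          transport_config(), seed = 9)
  expect_lt(abs(sum(hs$edep) + hs$escaped - 1.5) / 1.5, 1e-9)
})

test_that("simulations are deterministic and conserve energy globally", {
  wb <- water_block(6)
  t1 <- run_simulation(wb$tia, wb$density, 2000, 4, seed = 31)
  t2 <- run_simulation(wb$tia, wb$density, 2000, 4, seed = 31)
  expect_identical(t1$batches, t2$batches)
  t3 <- run_simulation(wb$tia, wb$density, 2000, 4, seed = 32)
  expect_false(identical(t1$batches, t3$batches))
  # sum(dose * mass) / (J/MeV) per primary + escaped == sampled energy
  vox_kg <- wb$density$values * prod(wb$density$spacing) / 1e6
  for (b in seq_along(t1$batches)) {
    edep <- sum(t1$batches[[b]] * vox_kg) / 1.602176634e-13 *
      t1$primaries[b]
    expect_lt(abs(edep + t1$escaped_mev[b] - t1$e_init_mev[b]) /
                t1$e_init_mev[b], 1e-9)
  }
  expect_error(run_simulation(wb$tia, water_block(7)$density, 100, 2),
               "aligned")
})

test_that("batch merging reproduces the forced arithmetic and edge cases", {
  a <- array(1, c(2, 2, 2)); b <- array(3, c(2, 2, 2))
  m <- merge_batches(list(a, b))
  expect_equal(m$mean, array(2, c(2, 2, 2)))
  expect_equal(m$uncertainty_pct, array(50, c(2, 2, 2)))
  # identical batches -> zero uncertainty
  m2 <- merge_batches(list(a, a, a))
  expect_true(all(m2$uncertainty_pct == 0))
  # weighted mean honours batch primaries
  m3 <- merge_batches(list(a, b), primaries = c(3, 1))
  expect_equal(m3$mean[1], 1.5)
  # zero-dose voxels report zero uncertainty
  z <- array(0, c(2, 2, 2))
  expect_true(all(merge_batches(list(z, z))$uncertainty_pct == 0))
  expect_error(merge_batches(list()), "zero batches")
  expect_warning(merge_batches(list(a)), "single batch")
})

test_that("absolute scaling is linear in the total TIA", {
  d <- array(1e-14, c(2, 2, 2))
  expect_equal(scale_to_absolute(d, 2e8), array(2e-6, c(2, 2, 2)))
  expect_true(all(scale_to_absolute(d, 0) == 0))
  expect_error(scale_to_absolute(d, -1), "negative")
  g <- voxel_grid(d, 1, role = "dose_per_primary")
  expect_equal(scale_to_absolute(g, 1e6)$role, "dose")
})

test_that("mean voxel uncertainty follows the 1/sqrt(N) law", {
  wb <- water_block(6)
  u_of <- function(n, seed) {
    m <- merge_batches(run_simulation(wb$tia, wb$density, n, 10,
                                      seed = seed))
    mean(m$uncertainty_pct[m$mean > 0])
  }
  u1 <- u_of(4e4, 21)
  u4 <- u_of(1.6e5, 22)
  expect_lt(abs(u1 / u4 - 2), 0.4)  # halving within 20% relative
})

test_that("the water-sphere S value respects the energy-conservation bounds", {
  sp <- beta_spectrum()
  sv <- sphere_s_value(60, voxel_mm = 4, n_primaries = 2e4, seed = 17)
  bound <- sp$mean_mev * 1.602176634e-13 / (sv$mass_voxelized_g / 1000)
  expect_lt(sv$s_value, bound)
  expect_gt(sv$s_value, 0.5 * bound)  # most energy stays in a 60 g sphere
  # escape-free limit: a very large sphere absorbs everything
  sv_big <- sphere_s_value(1e6, voxel_mm = 50, n_primaries = 5e4,
                           seed = 18)
  limit <- sp$mean_mev * 1.602176634e-13 / (sv_big$mass_voxelized_g / 1000)
  expect_lt(abs(sv_big$s_value / limit - 1), 0.01)
  expect_error(make_benchmark_sphere(60, voxel_mm = 30), "under-resolved")
})
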