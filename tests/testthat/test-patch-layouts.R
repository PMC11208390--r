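test_that("overlap sizing follows ceil(2R/v) with even rounding, ties upward", {
  expect_identical(min_overlap_voxels(11.3, 9.59), 4L)   # 38.36 mm per face
  expect_identical(min_overlap_voxels(9.59, 9.59), 2L)
  expect_identical(min_overlap_voxels(5, 10), 2L)
  expect_identical(min_overlap_voxels(19.18, 9.59), 4L)
  expect_error(min_overlap_voxels(0, 1), "> 0")
  expect_error(min_overlap_voxels(1, -1), "> 0")
})

test_that("layout specs validate overlap rules and derive the geometry edge", {
  expect_equal(layout_spec("cl1", 32)$geometry_edge, 32L)
  expect_equal(layout_spec("cl2", 32, 4)$geometry_edge, 40L)
  expect_equal(layout_spec("cl3", 24, 4)$geometry_edge, 32L)
  expect_error(layout_spec("cl1", 32, 4), "overlap = 0")
  expect_error(layout_spec("cl3", 32, 3), "even")
  expect_error(layout_spec("cl3", 32, 0), "overlap > 0")
})

test_that("cropping the study grid yields the expected patch counts", {
  up <- uniform_study_pair()
  for (ly in list(layout_spec("cl1", 32), layout_spec("cl2", 32, 4),
                  layout_spec("cl3", 32, 4))) {
    ps <- crop(up$tia, up$geometry, ly)
    expect_length(ps$patches, 8L)
    g <- ly$geometry_edge
    expect_equal(dim(ps$patches[[1]]$source), c(g, g, g))
    expect_equal(dim(ps$patches[[1]]$geometry), c(g, g, g))
  }
  ps18 <- crop(up$tia, up$geometry, layout_spec("cl3", 24, 4))
  expect_length(ps18$patches, 18L)
  expect_equal(dim(ps18$patches[[1]]$geometry), c(32, 32, 32))
})

test_that("source patches partition the TIA for cl1/cl3 but not cl2", {
  up <- uniform_study_pair(c(16, 16, 10), 1)
  total <- sum(up$tia$values)
  for (lid in c("cl1", "cl3")) {
    ly <- if (lid == "cl1") layout_spec("cl1", 8) else layout_spec("cl3", 8, 2)
    ps <- crop(up$tia, up$geometry, ly)
    expect_equal(sum(vapply(ps$patches, `[[`, numeric(1), "sum_tia")), total)
  }
  # cl2 source patches double-count the bands when activity lies there
  ps2 <- crop(up$tia, up$geometry, layout_spec("cl2", 8, 2))
  expect_gt(sum(vapply(ps2$patches, `[[`, numeric(1), "sum_tia")), total)
})

test_that("primaries split homogeneously with an exact sum", {
  expect_true(all(allocate_primaries(5e8, 8) == 6.25e7))
  a18 <- allocate_primaries(5e8, 18)
  expect_equal(sum(a18), 5e8)
  expect_true(all(abs(a18 - 2.78e7) < 1e6))
  expect_true(max(a18) - min(a18) <= 1)
  expect_equal(allocate_primaries(7, 2), c(4, 3))
  expect_error(allocate_primaries(0, 2), ">= 1")
})

test_that("patch scaling is linear in the patch TIA", {
  d <- array(2, c(3, 3, 3))
  expect_true(all(scale_patch(d, 0) == 0))
  expect_equal(scale_patch(d, 5), d * 5)
  expect_equal(scale_patch(d, 6, primaries = 3), d * 2)
  # two patches with equal raw dose and TIA ratio 2:1 scale 2:1
  expect_equal(scale_patch(d, 4), 2 * scale_patch(d, 2))
})

test_that("cl1 mosaicking of the source patches reproduces the volume", {
  set.seed(5)
  tia <- voxel_grid(array(runif(16 * 16 * 10), c(16, 16, 10)), 2,
                    role = "tia")
  geom <- grid_like(tia, tia$values * 0 + 1, role = "density")
  ps <- crop(tia, geom, layout_spec("cl1", 8))
  out <- mosaic(lapply(ps$patches, `[[`, "source"), ps)
  expect_equal(out$values, tia$values, tolerance = 1e-15)
  expect_equal(out$origin, tia$origin)
})

test_that("cl2 averages and cl3 sums overlapping patches", {
  up <- uniform_study_pair(c(16, 16, 16), 1)
  ly2 <- layout_spec("cl2", 8, 2)
  ps2 <- crop(up$tia, up$geometry, ly2)
  g <- ly2$geometry_edge
  const <- lapply(ps2$patches, function(p) array(3.5, c(g, g, g)))
  m2 <- mosaic(const, ps2)
  expect_true(all(abs(m2$values - 3.5) < 1e-12))
  # cl3: a single nonzero patch contributes exactly its values
  ly3 <- layout_spec("cl3", 8, 2)
  ps3 <- crop(up$tia, up$geometry, ly3)
  doses <- lapply(ps3$patches, function(p) array(0, c(12, 12, 12)))
  doses[[1]] <- array(seq_len(12^3) * 1.0, c(12, 12, 12))
  m3 <- mosaic(doses, ps3)
  # patch 1 spans canvas 1..12 = core -2..10; core cell voxels 1..8 plus
  # the band 9..10 land in the output
  expect_equal(m3$values[1:10, 1:10, 1:10],
               doses[[1]][3:12, 3:12, 3:12])
  expect_true(all(m3$values[11:16, , ] == 0))
  expect_error(mosaic(doses[-1], ps3), "missing patch")
})

test_that("the overlap mask marks the 2*OV bands around interior boundaries", {
  ly <- layout_spec("cl2", 32, 4)
  m <- overlap_region_mask(ly, c(64, 64, 64))
  expect_equal(sum(m), 64^3 - 56^3)  # brute-force complement count
  expect_true(all(which(apply(m, 1, all)) == 29:36))
  # single patch -> empty mask
  expect_equal(sum(overlap_region_mask(layout_spec("cl2", 70, 4),
                                       c(64, 64, 42))), 0)
  # cl1 needs the reference overlap
  expect_error(overlap_region_mask(layout_spec("cl1", 32), c(64, 64, 42)),
               "reference")
  m1 <- overlap_region_mask(layout_spec("cl1", 32), c(64, 64, 42),
                            reference_ov = 4)
  expect_equal(m1, overlap_region_mask(ly, c(64, 64, 42)))
  # a corner voxel of three bands is covered by 8 geometry patches
  ps <- crop(voxel_grid(array(1, c(64, 64, 64)), 1, role = "tia"),
             voxel_grid(array(1, c(64, 64, 64)), 1, role = "density"), ly)
  cover <- array(0L, ps$canvas_dim)
  for (p in ps$patches) {
    o <- p$origin
    idx <- lapply(1:3, function(a) o[a] + seq_len(40))
    cover[idx[[1]], idx[[2]], idx[[3]]] <-
      cover[idx[[1]], idx[[2]], idx[[3]]] + 1L
  }
  expect_equal(cover[36 + 4, 36 + 4, 36 + 4], 8L)  # canvas index of core 36
  expect_true(all(cover[!is.na(cover)] %in% c(1L, 2L, 4L, 8L)))
})

test_that("with a compact kernel the sum-mosaic equals whole-volume convolution", {
  ph <- make_synthetic_patient()
  tia <- tia_map(ph$activity, 24)
  k <- make_toy_kernel(2, 9.59, "tent")
  ref <- convolve_tia(tia, k)
  d3 <- patch_kernel_dose(tia, layout_spec("cl3", 32, 4), k)
  expect_lt(max(abs(d3$values - ref$values)),
            1e-12 * max(ref$values))
  rel <- abs(d3$values - ref$values) / ref$values
  expect_lt(max(rel[ref$values > 0]), 1e-12)
})

test_that("cl1 and cl2 lose dose at their characteristic border voxels", {
  # uniform source: every border effect is exercised deterministically
  dims <- c(64, 64, 42)
  tia <- voxel_grid(array(1, dims), 9.59, role = "tia")
  hw <- 2L
  k <- make_toy_kernel(hw, 9.59, "uniform")
  ref <- convolve_tia(tia, k)
  d1 <- patch_kernel_dose(tia, layout_spec("cl1", 32), k)
  d2 <- patch_kernel_dose(tia, layout_spec("cl2", 32, 4), k)
  eps <- 1e-12 * max(ref$values)
  expect_true(all(d1$values <= ref$values + eps))
  expect_true(all(d2$values <= ref$values + eps))
  # along x at mid y/z: cl1 under-doses exactly the voxels within the
  # kernel half-width of the interior patch boundary (x = 31..34)
  p_ref <- line_profile(ref, 1, c(20, 20))
  p1 <- line_profile(d1, 1, c(20, 20))
  p2 <- line_profile(d2, 1, c(20, 20))
  strict1 <- which(p1 < p_ref - eps)
  expect_equal(strict1, 31:34)
  # cl2 under-doses the band-edge voxels whose footprint exits a patch
  # (band 29..36, kernel reach 2 -> 29,30 and 35,36), and is exact at the
  # band centre
  strict2 <- which(p2 < p_ref - eps)
  expect_equal(strict2, c(29, 30, 35, 36))
  expect_true(all(abs(p2[31:34] - p_ref[31:34]) <= eps))
})

test_that("patch Monte Carlo runs are deterministic and mosaic to the parent grid", {
  wb <- water_block(12, voxel_mm = 9.59)
  ly <- layout_spec("cl3", 6, 2)
  r1 <- patch_mc_dose(wb$tia, wb$density, ly, 4000, 4, seed = 8)
  r2 <- patch_mc_dose(wb$tia, wb$density, ly, 4000, 4, seed = 8)
  expect_identical(r1$dose$values, r2$dose$values)
  expect_true(grids_aligned(r1$dose, wb$tia))
  expect_length(r1$patchset$patches, 8L)
  expect_equal(sum(r1$primaries_per_patch), 4000)
  expect_true(all(r1$dose$values >= 0))
  expect_gt(sum(r1$dose$values), 0)
})
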