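test_that("extract_vasculature multiplies image and mask voxelwise", {
  ph <- generate_phantom(small_test_spec(seed = 2))
  d <- dim(ph$volume$voxels)
  ones <- binary_mask(array(1L, d), ph$volume$spacing)
  zeros <- binary_mask(array(0L, d), ph$volume$spacing)
  expect_identical(extract_vasculature(ph$volume, ones)$voxels, ph$volume$voxels)
  expect_true(all(extract_vasculature(ph$volume, zeros)$voxels == 0L))
  ext <- extract_vasculature(ph$volume, ph$truth$vessel_mask)
  expect_true(all(ext$voxels[ph$truth$vessel_mask$voxels == 0L] == 0L))
  expect_error(extract_vasculature(ph$volume, binary_mask(array(0L, c(2, 2, 2)))),
               "shape")
  hu <- ct_volume(ph$volume$voxels, intensity_scale = "HU")
  expect_error(extract_vasculature(hu, ones), "8-bit")
})

test_that("thresholding is strict by default and matches the double-loop oracle", {
  at145 <- ct_volume(array(145L, c(6, 6, 2)))
  expect_identical(count_calcified(at145), c(0L, 0L))
  expect_identical(count_calcified(at145, score_config(inclusive = TRUE)),
                   c(36L, 36L))
  at146 <- ct_volume(array(146L, c(6, 6, 2)))
  expect_identical(count_calcified(at146), c(36L, 36L))

  set.seed(8)
  for (i in 1:10) {
    vox <- array(sample(130:160, 8 * 8 * 3, replace = TRUE), c(8, 8, 3))
    v <- ct_volume(vox)
    counts <- count_calcified(v)
    for (s in 1:3)
      expect_identical(counts[s], oracle_count_above(vox[, , s], 145))
  }
})

test_that("minimum-area filter drops small 8-connected components", {
  sl <- matrix(0L, 8, 8)
  sl[2, 2] <- sl[3, 3] <- 200L            # diagonal pair: one 8-conn component, size 2
  sl[6, 2:6] <- 200L                      # line of 5
  v <- ct_volume(array(sl, c(8, 8, 1)), spacing = c(1, 1, 1))
  expect_identical(count_calcified(v), 7L)
  expect_identical(count_calcified(v, score_config(min_component_area_mm2 = 3)), 5L)
  expect_identical(count_calcified(v, score_config(min_component_area_mm2 = 2)), 7L)
  expect_identical(count_calcified(v, score_config(min_component_area_mm2 = 6)), 0L)
  # anisotropic pixels change the area of the same voxel count
  v2 <- ct_volume(array(sl, c(8, 8, 1)), spacing = c(2, 2, 1))
  expect_identical(count_calcified(v2, score_config(min_component_area_mm2 = 12)), 5L)
})

test_that("calcium_score recovers phantom truth exactly with ground-truth masks", {
  ph <- generate_phantom(small_test_spec(seed = 10))
  rep <- calcium_score(ph$volume, ph$truth$vessel_mask)
  expect_identical(rep$total_count, ph$truth$true_calcium_voxels)
  expect_identical(rep$total_volume_mm3, ph$truth$true_calcium_volume)
  expect_identical(sum(rep$per_slice$calcified_voxels), rep$total_count)
  expect_equal(rep$total_volume_mm3, rep$total_count * rep$voxel_volume_mm3)
})

test_that("slice range and spacing enter the score the way geometry dictates", {
  spec <- phantom_spec(image_size = 48, n_slices = 10,
                       vessel_path = matrix(24, 10, 2),
                       vessel_radius_profile = rep(8, 10),
                       calcifications = list(list(
                         slice_range = c(4, 6), angular_arc = c(0, pi),
                         radial_thickness = 2, intensity = 210)))
  ph <- generate_phantom(spec)
  # a range that excludes all calcified slices scores zero
  none <- calcium_score(ph$volume, ph$truth$vessel_mask,
                        score_config(slice_range = c(7, 10)))
  expect_identical(none$total_count, 0L)
  full <- calcium_score(ph$volume, ph$truth$vessel_mask)
  # doubling dz doubles volume but not counts
  thick <- calcium_score(ph$volume, ph$truth$vessel_mask, spacing = c(1, 1, 2))
  expect_identical(thick$total_count, full$total_count)
  expect_equal(thick$total_volume_mm3, 2 * full$total_volume_mm3)
  expect_error(calcium_score(ph$volume, ph$truth$vessel_mask,
                             score_config(slice_range = c(9, 3))),
               "slice_range")
})

test_that("counts are monotone in threshold and in mask inclusion", {
  set.seed(77)
  for (i in 1:15) {
    ph <- generate_phantom(small_test_spec(seed = i, noise_sigma = 5))
    th <- sort(sample(100:220, 2))
    lo <- calcium_score(ph$volume, ph$truth$vessel_mask, score_config(threshold = th[1]))
    hi <- calcium_score(ph$volume, ph$truth$vessel_mask, score_config(threshold = th[2]))
    expect_true(all(hi$per_slice$calcified_voxels <= lo$per_slice$calcified_voxels))
    # superset mask: full-volume mask upper-bounds the vessel mask score
    allmask <- binary_mask(array(1L, dim(ph$volume$voxels)), ph$volume$spacing)
    sup <- calcium_score(ph$volume, allmask, score_config(threshold = th[1]))
    expect_true(all(lo$per_slice$calcified_voxels <= sup$per_slice$calcified_voxels))
  }
})

test_that("reports round-trip through JSON and CSV", {
  ph <- generate_phantom(small_test_spec(seed = 10))
  rep <- calcium_score(ph$volume, ph$truth$vessel_mask)
  stem <- file.path(withr::local_tempdir(), "report")
  write_report(rep, stem)
  j <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  expect_equal(j$total_count, rep$total_count)
  expect_equal(j$total_volume_mm3, rep$total_volume_mm3)
  csv <- read.csv(paste0(stem, ".csv"))
  expect_equal(sum(csv$calcified_voxels), rep$total_count)
})
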