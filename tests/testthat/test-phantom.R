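test_that("a phantom without calcifications has zero true calcium volume", {
  spec <- phantom_spec(image_size = 32, n_slices = 4)
  ph <- generate_phantom(spec)
  expect_identical(ph$truth$true_calcium_voxels, 0L)
  expect_equal(ph$truth$true_calcium_volume, 0)
  expect_equal(sum(ph$truth$calcium_mask$voxels), 0L)
})

test_that("generation is bit-identical for a fixed spec and seed", {
  spec <- small_test_spec(seed = 13, noise_sigma = 6)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$truth$vessel_mask$voxels, b$truth$vessel_mask$voxels)
})

test_that("closed-form calcium volume equals brute-force point-in-region rasterization", {
  for (seed in c(3, 17, 29)) {
    spec <- small_test_spec(seed = seed)
    ph <- generate_phantom(spec)
    brute <- oracle_calcium_voxels(spec)
    expect_identical(ph$truth$true_calcium_voxels, brute)
    expect_equal(ph$truth$true_calcium_volume,
                 brute * prod(spec$voxel_spacing))
  }
})

test_that("an arc with a constant per-slice footprint scales volume by slice count", {
  # constant radius and a fixed arc: every covered slice rasterizes the
  # same voxel set, so volume = per-slice count x slices x voxel volume
  spec <- phantom_spec(image_size = 48, n_slices = 12,
                       vessel_path = matrix(24, 12, 2),
                       vessel_radius_profile = rep(8, 12),
                       wall_thickness = 3,
                       calcifications = list(list(
                         slice_range = c(2, 11), angular_arc = c(0, pi / 2),
                         radial_thickness = 3, intensity = 200)))
  ph <- generate_phantom(spec)
  per_slice <- sum(ph$truth$calcium_mask$voxels[, , 2])
  expect_gt(per_slice, 0L)
  expect_identical(ph$truth$true_calcium_voxels, per_slice * 10L)
  expect_equal(ph$truth$true_calcium_volume, per_slice * 10)
})

test_that("with zero noise every region renders at its specified intensity", {
  spec <- small_test_spec(seed = 21)
  ph <- generate_phantom(spec)
  vox <- ph$volume$voxels
  calc <- ph$truth$calcium_mask$voxels == 1L
  expect_true(all(vox[calc] > 145L))
  lumen_wall <- ph$truth$vessel_mask$voxels == 1L & !calc
  expect_true(all(vox[lumen_wall] < 145L))
})

test_that("calcium lies inside the vessel and vessel slices are single components", {
  label8 <- getFromNamespace("label_components_8", "vasccalc")
  for (seed in c(1, 8)) {
    ph <- generate_phantom(small_test_spec(seed = seed))
    expect_true(all(ph$truth$calcium_mask$voxels <= ph$truth$vessel_mask$voxels))
    for (s in seq_len(dim(ph$truth$vessel_mask$voxels)[3])) {
      lab <- label8(ph$truth$vessel_mask$voxels[, , s] == 1L)
      expect_identical(max(lab), 1L)
    }
  }
})

test_that("noise never changes the truth", {
  clean <- generate_phantom(small_test_spec(seed = 4, noise_sigma = 0))
  noisy <- generate_phantom(small_test_spec(seed = 4, noise_sigma = 10))
  expect_identical(clean$truth$vessel_mask$voxels, noisy$truth$vessel_mask$voxels)
  expect_identical(clean$truth$true_calcium_voxels, noisy$truth$true_calcium_voxels)
  expect_false(identical(clean$volume$voxels, noisy$volume$voxels))
  expect_true(min(noisy$volume$voxels) >= 0L && max(noisy$volume$voxels) <= 255L)
})

test_that("invalid geometry is rejected", {
  expect_error(phantom_spec(image_size = 32, n_slices = 4,
                            vessel_path = matrix(c(2, 2), 4, 2, byrow = TRUE),
                            vessel_radius_profile = rep(6, 4)),
               "exits the image frame")
  expect_error(phantom_spec(image_size = 32, n_slices = 4,
                            wall_thickness = 2,
                            calcifications = list(list(
                              slice_range = c(1, 2), angular_arc = c(0, 1),
                              radial_thickness = 5, intensity = 200))),
               "thicker than the vessel wall")
  expect_error(phantom_spec(image_size = 32, n_slices = 4,
                            calcifications = list(list(
                              slice_range = c(1, 2), angular_arc = c(0, 1),
                              radial_thickness = 1, intensity = 120))),
               "above 145")
  expect_error(phantom_spec(image_size = 64, n_slices = 4,
                            bones = list(list(center = c(32, 32), radius = 5,
                                              intensity = 200))),
               "bone disk intersects")
})

test_that("artifacts corrupt the image but never the truth", {
  spec <- small_test_spec(seed = 6)
  ph <- generate_phantom(spec)
  vox <- ph$volume$voxels

  expect_identical(apply_artifact(ph$volume, ph$truth, "none")$voxels, vox)

  nc <- apply_artifact(ph$volume, ph$truth, "no_contrast")
  lumen <- ph$truth$vessel_mask$voxels == 1L & ph$truth$calcium_mask$voxels == 0L
  expect_lt(mean(nc$voxels[lumen]), mean(vox[lumen]))

  st <- apply_artifact(ph$volume, ph$truth, "stent")
  outside_calc <- st$voxels > 145L & ph$truth$calcium_mask$voxels == 0L
  expect_gt(sum(outside_calc), 0L)

  ms <- apply_artifact(ph$volume, ph$truth, "metal_streak", seed = 2)
  expect_gt(sum(ms$voxels == 255L), sum(vox == 255L))

  expect_error(apply_artifact(ph$volume, ph$truth, "fog"), "arg")
})

test_that("randomized specs are reproducible and leave the caller's RNG alone", {
  set.seed(99); before <- runif(1)
  set.seed(99)
  s1 <- random_phantom_spec(seed = 12, image_size = 32, n_slices = 4)
  after <- runif(1)
  expect_identical(before, after)
  s2 <- random_phantom_spec(seed = 12, image_size = 32, n_slices = 4)
  expect_identical(s1$vessel_path, s2$vessel_path)
  expect_identical(s1$calcifications, s2$calcifications)
})
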