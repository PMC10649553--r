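no_op_config <- function() {
  augment_config(hflip_prob = 0, grid_distort_prob = 0, downscale_prob = 0,
                 photometric_prob = 0, hist_eq = FALSE)
}

test_pair <- function(n = 32L, seed = 5L) {
  set.seed(seed)
  img <- matrix(round(runif(n * n) * 255), n, n)
  msk <- matrix(0L, n, n)
  msk[3:(n %/% 2), 4:(n %/% 2 + 2)] <- 1L
  list(image = img, mask = msk)
}

test_that("with all transforms disabled augmentation is the identity", {
  tp <- test_pair()
  out <- augment_pair(tp$image, tp$mask, no_op_config(), seed = 1)
  expect_equal(out$image, tp$image, ignore_attr = TRUE)
  expect_identical(out$mask, tp$mask)
})

test_that("horizontal flip mirrors image and mask jointly and is an involution", {
  tp <- test_pair()
  cfg <- no_op_config(); cfg$hflip_prob <- 1
  once <- augment_pair(tp$image, tp$mask, cfg, seed = 3)
  expect_equal(once$image, tp$image[, ncol(tp$image):1], ignore_attr = TRUE)
  expect_identical(once$mask, tp$mask[, ncol(tp$mask):1])
  expect_identical(sum(once$mask), sum(tp$mask))  # foreground count invariant
  twice <- augment_pair(once$image, once$mask, cfg, seed = 4)
  expect_equal(twice$image, tp$image, ignore_attr = TRUE)
  expect_identical(twice$mask, tp$mask)
})

test_that("augmentation is deterministic for a fixed seed and mask stays binary", {
  tp <- test_pair()
  cfg <- augment_config()
  a <- augment_pair(tp$image, tp$mask, cfg, seed = 11)
  b <- augment_pair(tp$image, tp$mask, cfg, seed = 11)
  expect_identical(a, b)
  for (s in 1:25) {
    out <- augment_pair(tp$image, tp$mask, cfg, seed = s)
    expect_true(all(out$mask %in% c(0L, 1L)))
    expect_identical(dim(out$image), dim(tp$image))
    expect_true(all(out$image >= 0 & out$image <= 255))
  }
  expect_error(augment_pair(tp$image, tp$mask * 2L, cfg), "binary")
})

test_that("transform firing frequencies match their configured probabilities", {
  # detect geometric transforms by their effect on an asymmetric mask
  tp <- test_pair(16)
  n <- 10000L
  flip_cfg <- no_op_config(); flip_cfg$hflip_prob <- 0.25
  grid_cfg <- no_op_config(); grid_cfg$grid_distort_prob <- 0.70
  down_cfg <- no_op_config(); down_cfg$downscale_prob <- 0.30
  flipped <- mirror <- tp$mask[, ncol(tp$mask):1]
  hits <- c(flip = 0L, grid = 0L, down = 0L)
  for (s in seq_len(n)) {
    f <- augment_pair(tp$image, tp$mask, flip_cfg, seed = s)
    if (identical(f$mask, mirror)) hits["flip"] <- hits["flip"] + 1L
    g <- augment_pair(tp$image, tp$mask, grid_cfg, seed = s)
    if (!isTRUE(all.equal(g$image, tp$image, check.attributes = FALSE)))
      hits["grid"] <- hits["grid"] + 1L
    d <- augment_pair(tp$image, tp$mask, down_cfg, seed = s)
    if (!isTRUE(all.equal(d$image, tp$image, check.attributes = FALSE)))
      hits["down"] <- hits["down"] + 1L
  }
  p <- c(0.25, 0.70, 0.30)
  for (k in 1:3) {
    band <- 3 * sqrt(p[k] * (1 - p[k]) / n)
    expect_lt(abs(hits[k] / n - p[k]), band)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(augment_config(hflip_prob = 1.5), "probabilities")
  expect_error(augment_config(downscale_range = c(0.9, 0.6)), "downscale_range")
  expect_error(augment_config(downscale_range = c(0, 0.9)), "downscale_range")
})

test_that("dataset expansion appends multiplicity copies deterministically", {
  tp <- test_pair()
  slices <- list(tp, tp)
  cfg <- augment_config(multiplicity = 3L)
  out1 <- augment_dataset(slices, cfg, seed = 9)
  out2 <- augment_dataset(slices, cfg, seed = 9)
  expect_length(out1, 2L * 4L)
  expect_identical(out1[[5]]$image, out2[[5]]$image)
  # originals are preserved in place
  expect_identical(out1[[1]]$image, tp$image)
})
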