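test_that("confusion counts match hand-enumerated voxels", {
  # 4x4 masks: 2 overlapping, 1 pred-only, 1 truth-only foreground voxel
  pred <- matrix(0L, 4, 4); truth <- matrix(0L, 4, 4)
  pred[1, 1] <- pred[2, 2] <- 1L; truth[1, 1] <- truth[2, 2] <- 1L  # overlap
  pred[3, 3] <- 1L   # pred-only
  truth[4, 4] <- 1L  # truth-only
  cc <- confusion(pred, truth)
  expect_identical(c(cc$TP, cc$FP, cc$FN, cc$TN), c(2L, 1L, 1L, 12L))

  ident <- confusion(truth, truth)
  expect_identical(c(ident$TP, ident$FP, ident$FN), c(3L, 0L, 0L))

  comp <- confusion(1L - truth, truth)
  expect_identical(comp$TP, 0L)

  expect_error(confusion(matrix(0L, 2, 2), matrix(0L, 3, 3)), "shape")
  expect_error(confusion(matrix(2L, 2, 2), matrix(0L, 2, 2)), "0/1")
})

test_that("iou and dice follow their closed forms and conventions", {
  cc <- list(TP = 2L, FP = 1L, FN = 1L, TN = 12L)
  expect_equal(iou(cc), 0.5)
  expect_equal(dice(cc), 2 / 3)

  empty <- confusion(matrix(0L, 3, 3), matrix(0L, 3, 3))
  expect_equal(iou(empty), 1)
  expect_equal(dice(empty), 1)

  disjoint <- confusion(diag(1L, 4), 1L - diag(1L, 4))
  expect_equal(iou(disjoint), 0)
  expect_equal(dice(disjoint), 0)
})

test_that("iou/dice agree with the brute-force oracle and each other on random masks", {
  set.seed(11)
  for (rep in 1:50) {
    mp <- random_mask_pair()
    cc <- confusion(mp$pred, mp$truth)
    oc <- oracle_confusion(mp$pred, mp$truth)
    expect_identical(cc$TP, oc$TP)
    expect_identical(cc$FP, oc$FP)
    expect_identical(cc$FN, oc$FN)
    expect_identical(cc$TN, oc$TN)
    expect_equal(iou(cc), oracle_iou(oc))
    expect_equal(dice(cc), oracle_dice(oc))
    # algebraic identity and symmetry
    expect_equal(dice(cc), 2 * iou(cc) / (1 + iou(cc)), tolerance = 1e-14)
    cc_sw <- confusion(mp$truth, mp$pred)
    expect_equal(iou(cc_sw), iou(cc))
    expect_equal(dice(cc_sw), dice(cc))
  }
})

test_that("mape and ape compute absolute percentage errors", {
  expect_equal(mape(c(100, 200), c(90, 220)), 10)
  expect_equal(mape(c(5, 5), c(5, 5)), 0)
  expect_equal(ape(100, 50), 50)
  expect_equal(ape(100, 150), 50)
  expect_equal(ape(7892, 7707), 185 / 7892 * 100)
  expect_error(mape(c(0, 1), c(1, 1)), "zero")
  expect_error(ape(0, 1), "undefined")
  set.seed(4)
  yt <- runif(10, 50, 150); yp <- runif(10, 50, 150)
  expect_equal(mape(yt, yp), mean(ape(yt, yp)))
})

test_that("r_squared and fit_line summarize agreement", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(r_squared(x, x), 1)
  expect_equal(r_squared(x, rep(mean(x), 5)), 0)
  expect_error(r_squared(rep(2, 5), x), "constant")
  fit <- fit_line(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
})

test_that("binary cross-entropy matches its closed form and stays finite", {
  expect_equal(bce(c(0, 1, 0), c(0.5, 0.5, 0.5)), log(2))
  expect_lt(bce(1, 1 - 1e-7), 1e-6)
  expect_true(is.finite(bce(c(1, 0), c(0, 1))))  # clamped saturation
  set.seed(2)
  for (i in 1:20) {
    y <- rbinom(30, 1, 0.5); p <- runif(30)
    expect_gte(bce(y, p), 0)
  }
})

test_that("per-slice overlap table averages slices, not pooled voxels", {
  # half of slices perfect, half fully wrong: per-slice mean is 0.5 even
  # though pooled-voxel dice would differ
  truth <- array(0L, c(4, 4, 4)); truth[1:2, 1:2, ] <- 1L
  pred <- truth
  pred[, , 3] <- 1L - truth[, , 3]
  pred[, , 4] <- 1L - truth[, , 4]
  tab <- slice_overlap_table(binary_mask(pred), binary_mask(truth))
  expect_equal(tab$dice, c(1, 1, 0, 0))
  expect_equal(mean(tab$dice), 0.5)
  expect_false(any(tab$both_empty))
})
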