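test_that("make_folds reproduces the 3/3/3/2 patient-level partition", {
  ids <- sprintf("PT%02d", 1:11)
  plan <- make_folds(ids, k = 4, sizes = c(3, 3, 3, 2))
  expect_length(plan$folds, 4L)
  test_sets <- lapply(plan$folds, `[[`, "test")
  expect_identical(vapply(test_sets, length, integer(1)), c(3L, 3L, 3L, 2L))
  # every patient tested exactly once; no overlap with its fold's train set
  all_tested <- unlist(test_sets)
  expect_identical(sort(all_tested), sort(ids))
  expect_identical(anyDuplicated(all_tested), 0L)
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$test), 0L)
    expect_setequal(c(f$train, f$test), ids)
  }
})

test_that("fold plan invariants hold over random patient lists", {
  set.seed(15)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    k <- sample(2:min(4, n - 1), 1)
    ids <- paste0("p", sample.int(1000, n))
    plan <- make_folds(ids, k = k, seed = i)
    tested <- unlist(lapply(plan$folds, `[[`, "test"))
    expect_setequal(tested, ids)
    expect_identical(anyDuplicated(tested), 0L)
    for (f in plan$folds) {
      expect_gte(length(f$train), 1L)
      expect_length(intersect(f$train, f$test), 0L)
    }
  }
})

test_that("degenerate or inconsistent fold requests are rejected", {
  ids <- paste0("p", 1:8)
  expect_error(make_folds(ids, k = 1), "at least 2")
  expect_error(make_folds(ids, k = 4, sizes = c(2, 2, 2, 3)), "sum")
  expect_error(make_folds(ids, k = 2, sizes = c(8, 0)), "at least one")
  expect_error(make_folds(c("a", "a", "b"), k = 2), "unique")
})

test_that("combined loss is zero at the target and maximal at its complement", {
  set.seed(6)
  t <- array(rbinom(64, 1, 0.4), c(4, 4, 1, 4))
  eps <- 1e-7
  perfect <- pmin(pmax(t, eps), 1 - eps)
  expect_lt(combined_loss(t, perfect), 1e-5)
  worst <- pmin(pmax(1 - t, eps), 1 - eps)
  expect_gt(combined_loss(t, worst), combined_loss(t, array(0.5, dim(t))))
  # complement prediction drives the Jaccard term to (almost) 1
  jacc_term <- combined_loss(t, worst, weights = c(0, 1))
  expect_gt(jacc_term, 1 - 1e-5)
})

test_that("on hard predictions the Jaccard term equals 1 - confusion-count IOU", {
  set.seed(19)
  for (i in 1:25) {
    mp <- random_mask_pair(8)
    jacc <- combined_loss(mp$truth, mp$pred, weights = c(0, 1))
    expect_equal(jacc, 1 - iou(confusion(mp$pred, mp$truth)), tolerance = 1e-12)
  }
  # both empty: perfect-agreement convention, zero loss term
  z <- matrix(0, 4, 4)
  expect_equal(combined_loss(z, z, weights = c(0, 1)), 0)
})

test_that("loss is non-negative with a bounded Jaccard term", {
  set.seed(23)
  for (i in 1:20) {
    t <- array(rbinom(64, 1, runif(1)), c(8, 8, 1, 1))
    p <- array(runif(64), c(8, 8, 1, 1))
    expect_gte(combined_loss(t, p), 0)
    j <- combined_loss(t, p, weights = c(0, 1))
    expect_gte(j, 0); expect_lte(j, 1)
  }
})

make_tiny_cohort <- function(n = 3L, seed = 50L)
  make_phantom_cohort(n, image_size = 32, n_slices = 4, noise_sigma = 3,
                      seed = seed)

test_that("train_fold records finite history and is reproducible", {
  cohort <- make_tiny_cohort()
  fold <- list(train = c("P01", "P02"), test = "P03")
  cfg <- training_config(batch_size = 4, epochs = 2, seed = 5)
  mc <- model_config(base_channels = 2, seed = 5)
  fit1 <- train_fold(fold, cohort, mc, cfg)
  expect_identical(nrow(fit1$history), 2L)
  expect_true(all(is.finite(fit1$history$loss)))
  expect_true(all(fit1$history$val_iou >= 0 & fit1$history$val_iou <= 1))
  fit2 <- train_fold(fold, cohort, mc, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_error(train_fold(list(train = character(0), test = "P03"), cohort,
                          mc, cfg),
               "empty training set")
})

test_that("the returned checkpoint is the best validation epoch", {
  cohort <- make_tiny_cohort(seed = 51)
  fold <- list(train = c("P01", "P02"), test = "P03")
  fit <- train_fold(fold, cohort, model_config(base_channels = 2, seed = 6),
                    training_config(batch_size = 4, epochs = 3, seed = 6))
  ns <- asNamespace("vasccalc")
  val_slices <- ns$patients_to_slices(cohort["P02"])
  final_iou <- ns$validate_iou(fit$model, val_slices)
  expect_equal(final_iou, max(fit$history$val_iou), tolerance = 1e-10)
})

test_that("evaluate_patient averages per-slice Dice", {
  cohort <- make_tiny_cohort(seed = 52)
  fit <- train_fold(list(train = c("P01", "P02"), test = "P03"), cohort,
                    model_config(base_channels = 2, seed = 7),
                    training_config(batch_size = 4, epochs = 1, seed = 7))
  ev <- evaluate_patient(fit$model, cohort$P03$volume, cohort$P03$mask)
  expect_equal(ev$mean_dice, mean(ev$per_slice$dice))
  expect_identical(nrow(ev$per_slice), dim(cohort$P03$volume$voxels)[3])
})
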