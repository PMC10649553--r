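#' Patient-level cross-validation plan
#'
#' Partitions patients into `k` disjoint test sets; the unit of splitting
#' is always the patient, never the slice, so no slice of a test patient
#' is ever seen in training. With 11 patients and the default sizing this
#' reproduces the 3/3/3/2 pattern: three patients held out per fold except
#' the last, which holds out two.
#'
#' @param patient_ids character vector of unique patient identifiers.
#' @param k number of folds (default 4; at least 2 — a single fold would
#'   leave no training patients).
#' @param sizes optional integer vector of test-set sizes per fold; must
#'   sum to `length(patient_ids)`. Default: as even as possible, larger
#'   folds first.
#' @param seed optional seed; when given, patients are shuffled before
#'   assignment, otherwise the input order is used. Deterministic either
#'   way.
#' @return A `fold_plan`: list with `folds`, each
#'   `list(train = ids, test = ids)`.
#' @examples
#' plan <- make_folds(sprintf("P%02d", 1:11))
#' vapply(plan$folds, function(f) length(f$test), integer(1))  # 3 3 3 2
#' @export
make_folds <- function(patient_ids, k = 4L, sizes = NULL, seed = NULL) {
  patient_ids <- as.character(patient_ids)
  n <- length(patient_ids)
  if (anyDuplicated(patient_ids)) stop("patient ids must be unique", call. = FALSE)
  k <- as.integer(k)
  if (k < 2L)
    stop("k must be at least 2: a single fold leaves no training patients",
         call. = FALSE)
  if (is.null(sizes)) {
    base <- n %/% k
    sizes <- rep(base, k)
    extra <- n - base * k
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  }
  sizes <- as.integer(sizes)
  if (length(sizes) != k || sum(sizes) != n)
    stop("sizes must have one entry per fold and sum to the patient count",
         call. = FALSE)
  if (any(sizes < 1L)) stop("every fold must test at least one patient", call. = FALSE)
  if (any(n - sizes < 1L))
    stop("degenerate plan: a fold with no training patients", call. = FALSE)
  ids <- patient_ids
  if (!is.null(seed)) {
    old <- .Random.seed_store(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    ids <- sample(ids)
  }
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  folds <- lapply(seq_len(k), function(i) {
    test <- ids[starts[i]:ends[i]]
    list(train = setdiff(ids, test), test = test)
  })
  structure(list(folds = folds, patient_ids = patient_ids, sizes = sizes),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d folds over %d patients (test sizes %s)\n",
              length(x$folds), length(x$patient_ids),
              paste(x$sizes, collapse = "/")))
  invisible(x)
}

#' Training configuration
#'
#' Hyperparameters of the segmentation training loop: Adam with learning
#' rate 1e-3, batch size 15, and the combined binary cross-entropy +
#' Jaccard loss with unit weights. `epochs = 100` matches the full
#' training recipe; desk-scale runs use far fewer (the loss plateaus on
#' phantoms within ~20).
#'
#' @param batch_size slices per gradient step.
#' @param epochs training epochs.
#' @param learning_rate Adam step size.
#' @param loss_weights `c(bce, jaccard)` term weights.
#' @param augment an [augment_config()] used to expand the training set,
#'   or `NULL` to train on the raw slices.
#' @param restart_threshold minimum acceptable best validation IOU; when
#'   a training run ends below it, training restarts from a fresh
#'   (deterministically derived) initialization, up to `max_restarts`
#'   times, and the attempt with the best validation IOU is kept. `NULL`
#'   (default) disables restarts. Selection uses validation data only.
#' @param max_restarts maximum number of re-initializations.
#' @param warm_start if `TRUE`, folds after the first continue from the
#'   previous fold's weights instead of re-initializing (the shared
#'   pretraining reading of fine-tuning per fold); default `FALSE`,
#'   independent per-fold training, the leakage-safe reading.
#' @param seed seed for shuffling and initialization.
#' @return A `training_config` object.
#' @export
training_config <- function(batch_size = 15L, epochs = 100L,
                            learning_rate = 1e-3, loss_weights = c(1, 1),
                            augment = NULL, warm_start = FALSE,
                            restart_threshold = NULL, max_restarts = 2L,
                            seed = 1L) {
  stopifnot(batch_size >= 1L, epochs >= 1L, learning_rate > 0,
            all(loss_weights >= 0), max_restarts >= 0L)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 loss_weights = as.numeric(loss_weights),
                 augment = augment, warm_start = isTRUE(warm_start),
                 restart_threshold = restart_threshold,
                 max_restarts = as.integer(max_restarts),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Combined segmentation loss
#'
#' `w_bce * BCE + w_jacc * (1 - softIOU)` on probabilities. The soft IOU
#' uses sums of elementwise products for the intersection and
#' `sum(p) + sum(t) - intersection` for the union, so for hard `{0,1}`
#' predictions the Jaccard term equals one minus the confusion-count IOU
#' exactly. Both-empty inputs give a zero Jaccard term (perfect-agreement
#' convention).
#'
#' @param y_true binary labels (any array shape).
#' @param y_prob predicted probabilities in (0, 1), same shape.
#' @param weights `c(bce, jaccard)` weights.
#' @param eps BCE clamp.
#' @return Non-negative scalar.
#' @export
combined_loss <- function(y_true, y_prob, weights = c(1, 1), eps = 1e-7) {
  stopifnot(length(y_true) == length(y_prob))
  t <- as.numeric(y_true); p <- as.numeric(y_prob)
  inter <- sum(p * t)
  union <- sum(p) + sum(t) - inter
  jacc <- if (union <= 0) 0 else 1 - inter / union
  weights[1L] * bce(t, p, eps) + weights[2L] * jacc
}

# loss + gradient w.r.t. the pre-sigmoid logits, for the training loop
loss_and_logit_grad <- function(t, p, weights, eps = 1e-7) {
  n <- length(p)
  pc <- pmin(pmax(p, eps), 1 - eps)
  inter <- sum(p * t)
  union <- sum(p) + sum(t) - inter
  jacc <- if (union <= 0) 0 else 1 - inter / union
  loss <- weights[1L] * (-mean(t * log(pc) + (1 - t) * log(1 - pc))) +
    weights[2L] * jacc
  gz_bce <- weights[1L] * (p - t) / n
  if (union <= 0) {
    gp_j <- 0
  } else {
    gp_j <- -weights[2L] * (t * union - inter * (1 - t)) / union^2
  }
  gz <- gz_bce + gp_j * p * (1 - p)
  dim(gz) <- dim(p)
  list(loss = loss, gz = gz)
}

#' Train the model on one cross-validation fold
#'
#' Trains on all slices of the fold's training patients (minus the
#' validation patient), validates after every epoch, and returns the
#' checkpoint with the best validation IOU (mean per-slice IOU of the
#' binarized prediction at 0.5). The last patient of the training set is
#' held out as validation. When an augmentation config is present, the
#' training slices are expanded with augmented copies before the first
#' epoch. Fully deterministic for a fixed config seed.
#'
#' @param fold one element of a [make_folds()] plan:
#'   `list(train = ids, test = ids)`.
#' @param data named list of patients, each
#'   `list(volume = ct_volume, mask = binary_mask)`, named by patient id.
#' @param model_config a [model_config()]; ignored when `init_model` is
#'   supplied.
#' @param train_config a [training_config()].
#' @param init_model optional `vasc_unet` to continue from (warm start).
#' @return `list(model, history)` where `history` is a data.frame with
#'   one row per epoch: `epoch`, `loss`, `val_iou`.
#' @export
train_fold <- function(fold, data, model_config = model_config(),
                       train_config = training_config(), init_model = NULL) {
  train_ids <- fold$train
  if (length(train_ids) == 0L) stop("empty training set", call. = FALSE)
  val_id <- train_ids[length(train_ids)]
  fit_ids <- if (length(train_ids) > 1L) train_ids[-length(train_ids)] else train_ids
  train_slices <- patients_to_slices(data[fit_ids])
  val_slices <- patients_to_slices(data[val_id])
  if (!is.null(train_config$augment))
    train_slices <- augment_dataset(train_slices, train_config$augment,
                                    seed = train_config$seed)
  n_attempts <- if (is.null(train_config$restart_threshold) ||
                    !is.null(init_model)) 1L
                else 1L + train_config$max_restarts
  best_fit <- NULL
  for (attempt in seq_len(n_attempts)) {
    model <- if (is.null(init_model)) {
      mc <- model_config
      mc$seed <- model_config$seed + (attempt - 1L) * 1009L
      build_model(mc)
    } else init_model
    fit <- train_on_slices(model, train_slices, val_slices, train_config)
    fit$attempt <- attempt
    if (is.null(best_fit) ||
        max(fit$history$val_iou) > max(best_fit$history$val_iou))
      best_fit <- fit
    if (max(best_fit$history$val_iou) >= (train_config$restart_threshold %||% -Inf))
      break
  }
  best_fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

patients_to_slices <- function(patients) {
  out <- list()
  for (p in patients) {
    ns <- dim(p$volume$voxels)[3L]
    for (s in seq_len(ns)) {
      out[[length(out) + 1L]] <- list(image = p$volume$voxels[, , s],
                                      mask = p$mask$voxels[, , s])
    }
  }
  out
}

train_on_slices <- function(model, train_slices, val_slices, cfg) {
  old <- .Random.seed_store(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  opt <- adam_init(model$params)
  t_step <- 0L
  best <- list(val_iou = -Inf, params = model$params, state = model$state)
  history <- data.frame(epoch = integer(), loss = numeric(), val_iou = numeric())
  n <- length(train_slices)
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    losses <- numeric()
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- perm[start:min(n, start + cfg$batch_size - 1L)]
      x <- slices_to_input(lapply(train_slices[idx], `[[`, "image"))
      d <- dim(x)
      tmask <- array(0, c(d[1], d[2], 1L, length(idx)))
      for (i in seq_along(idx)) tmask[, , 1L, i] <- train_slices[[idx[i]]]$mask
      out <- unet_forward(model, x, training = TRUE)
      model$state <- out$state
      lg <- loss_and_logit_grad(tmask, out$prob, cfg$loss_weights)
      losses <- c(losses, lg$loss)
      grads <- unet_backward(model, lg$gz, out$caches)
      t_step <- t_step + 1L
      upd <- adam_step(model$params, grads, opt, cfg$learning_rate, t_step)
      model$params <- upd$p
      opt <- upd$s
    }
    val_iou <- validate_iou(model, val_slices)
    history <- rbind(history, data.frame(epoch = epoch, loss = mean(losses),
                                         val_iou = val_iou))
    if (val_iou >= best$val_iou)
      best <- list(val_iou = val_iou, params = model$params, state = model$state)
  }
  model$params <- best$params
  model$state <- best$state
  list(model = model, history = history)
}

# mean per-slice IOU of binarized predictions on held-out slices
validate_iou <- function(model, slices, threshold = 0.5, batch_size = 8L) {
  scores <- numeric(length(slices))
  for (start in seq(1L, length(slices), by = batch_size)) {
    idx <- start:min(length(slices), start + batch_size - 1L)
    x <- slices_to_input(lapply(slices[idx], `[[`, "image"))
    out <- unet_forward(model, x, training = FALSE)
    for (i in seq_along(idx)) {
      pred <- (out$prob[, , 1L, i] > threshold) * 1L
      scores[idx[i]] <- iou(confusion(pred, slices[[idx[i]]]$mask))
    }
  }
  mean(scores)
}

#' Mean per-slice Dice of a model on one patient
#'
#' Segments the patient volume and averages the Dice score computed for
#' each slice individually — the per-patient accuracy convention used
#' throughout (never pooled-voxel Dice).
#'
#' @param model a trained `vasc_unet`.
#' @param volume the patient's [ct_volume()].
#' @param truth_mask the reference [binary_mask()].
#' @param threshold binarization threshold.
#' @return `list(mean_dice, per_slice)` with the per-slice overlap table
#'   of [slice_overlap_table()].
#' @export
evaluate_patient <- function(model, volume, truth_mask, threshold = 0.5) {
  pred <- predict_volume(model, volume, threshold = threshold)
  tab <- slice_overlap_table(pred$mask, truth_mask)
  list(mean_dice = mean(tab$dice), per_slice = tab)
}

#' Run full patient-level cross-validation
#'
#' Trains one model per fold (independently by default; sequential warm
#' start when the training config requests it) and evaluates each on its
#' held-out test patients.
#'
#' @param data named list of patients (see [train_fold()]).
#' @param plan a [make_folds()] plan over `names(data)`.
#' @param model_config,train_config configurations for every fold.
#' @return `list(models, histories, results)`; `results` is a data.frame
#'   with one row per (fold, test patient) carrying the mean per-slice
#'   Dice.
#' @export
cross_validate <- function(data, plan, model_config = model_config(),
                           train_config = training_config()) {
  stopifnot(inherits(plan, "fold_plan"))
  models <- list(); histories <- list(); rows <- list()
  prev <- NULL
  for (i in seq_along(plan$folds)) {
    fold <- plan$folds[[i]]
    fit <- train_fold(fold, data, model_config, train_config,
                      init_model = if (train_config$warm_start) prev else NULL)
    prev <- fit$model
    models[[i]] <- fit$model
    histories[[i]] <- cbind(fold = i, fit$history)
    for (pid in fold$test) {
      ev <- evaluate_patient(fit$model, data[[pid]]$volume, data[[pid]]$mask)
      rows[[length(rows) + 1L]] <- data.frame(fold = i, patient_id = pid,
                                              mean_dice = ev$mean_dice)
    }
  }
  list(models = models, histories = do.call(rbind, histories),
       results = do.call(rbind, rows))
}
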