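#' Pipeline configuration defaults
#'
#' Assembles the per-stage configuration tree for [run_pipeline()]:
#' phantom geometry, fold structure, model width, training
#' hyperparameters and scoring settings, each overridable independently.
#'
#' @param n_train_patients phantom patients used for training folds.
#' @param n_test_patients held-out phantom patients scored end to end.
#' @param image_size,n_slices,noise_sigma phantom geometry and noise.
#' @param base_channels model width.
#' @param epochs,batch_size,learning_rate training hyperparameters.
#' @param augment an [augment_config()] or `NULL`.
#' @param threshold scoring threshold on the 8-bit scale.
#' @param cross_validate if `TRUE`, run the full k-fold loop; otherwise
#'   train a single fold (the fast default for smoke runs).
#' @param k number of folds.
#' @param seed master seed; all stage seeds derive from it.
#' @return A nested list, the `config` argument of [run_pipeline()].
#' @export
pipeline_config <- function(n_train_patients = 4L, n_test_patients = 4L,
                            image_size = 64L, n_slices = 12L,
                            noise_sigma = 4, base_channels = 8L,
                            epochs = 8L, batch_size = 8L,
                            learning_rate = 1e-3, augment = NULL,
                            threshold = 145L, cross_validate = FALSE,
                            k = 4L, seed = 1L) {
  list(phantom = list(n_train_patients = as.integer(n_train_patients),
                      n_test_patients = as.integer(n_test_patients),
                      image_size = as.integer(image_size),
                      n_slices = as.integer(n_slices),
                      noise_sigma = noise_sigma),
       folds = list(k = as.integer(k), cross_validate = isTRUE(cross_validate)),
       model = list(base_channels = as.integer(base_channels)),
       train = list(epochs = as.integer(epochs),
                    batch_size = as.integer(batch_size),
                    learning_rate = learning_rate, augment = augment),
       score = list(threshold = threshold),
       seed = as.integer(seed))
}

#' Run the end-to-end calcification pipeline
#'
#' Executes phantom generation, segmentation training, prediction,
#' calcium scoring and evaluation, persisting every intermediate table so
#' each summary number is recomputable from per-slice artifacts. Outputs
#' under `out_dir`:
#' * `manifest.json` — command, config (with a fingerprint), seeds, paths,
#'   package version, timestamp;
#' * `history.csv` — per-epoch training loss and validation IOU;
#' * `dice_per_patient.csv` and `dice_per_slice.csv` — segmentation
#'   accuracy of the held-out phantoms;
#' * `scores.csv` — true vs automated calcium volume and APE per patient;
#' * `regression.json` — least-squares summary of automated vs true
#'   scores;
#' * `plots/` — Dice bars, score scatter with fitted line, APE bars.
#'
#' Any stage failure aborts with a stage-tagged error; artifacts written
#' before the failure are preserved.
#'
#' @param config a [pipeline_config()] tree.
#' @param out_dir output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "plots"), showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  seed <- config$seed
  ph <- config$phantom

  patients <- stage("phantom", {
    make_phantom_cohort(ph$n_train_patients + ph$n_test_patients,
                        image_size = ph$image_size, n_slices = ph$n_slices,
                        noise_sigma = ph$noise_sigma, seed = seed)
  })
  train_ids <- names(patients)[seq_len(ph$n_train_patients)]
  test_ids <- setdiff(names(patients), train_ids)

  mc <- model_config(base_channels = config$model$base_channels, seed = seed)
  tc <- training_config(batch_size = config$train$batch_size,
                        epochs = config$train$epochs,
                        learning_rate = config$train$learning_rate,
                        augment = config$train$augment, seed = seed)

  fit <- stage("train", {
    if (config$folds$cross_validate) {
      plan <- make_folds(train_ids, k = config$folds$k)
      cv <- cross_validate(patients[train_ids], plan, mc, tc)
      utils::write.csv(cv$results, file.path(out_dir, "cv_results.csv"),
                       row.names = FALSE)
      list(model = cv$models[[1L]], history = cv$histories)
    } else {
      fold <- list(train = train_ids, test = test_ids)
      train_fold(fold, patients, mc, tc)
    }
  })
  utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)

  eval_rows <- list(); slice_rows <- list(); score_rows <- list()
  sc <- score_config(threshold = config$score$threshold)
  stage("score", {
    for (pid in test_ids) {
      p <- patients[[pid]]
      pred <- predict_volume(fit$model, p$volume)
      tab <- slice_overlap_table(pred$mask, p$mask)
      slice_rows[[pid]] <- cbind(patient_id = pid, tab)
      eval_rows[[pid]] <- data.frame(patient_id = pid, mean_dice = mean(tab$dice))
      rep <- calcium_score(p$volume, pred$mask, sc)
      score_rows[[pid]] <- data.frame(
        patient_id = pid,
        true_volume_mm3 = p$truth$true_calcium_volume,
        predicted_volume_mm3 = rep$total_volume_mm3,
        ape = ape(p$truth$true_calcium_volume, rep$total_volume_mm3))
    }
  })
  dice_df <- do.call(rbind, eval_rows)
  slice_df <- do.call(rbind, slice_rows)
  score_df <- do.call(rbind, score_rows)

  reg <- stage("evaluate", {
    utils::write.csv(dice_df, file.path(out_dir, "dice_per_patient.csv"),
                     row.names = FALSE)
    utils::write.csv(slice_df, file.path(out_dir, "dice_per_slice.csv"),
                     row.names = FALSE)
    utils::write.csv(score_df, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
    # tiny smoke cohorts can produce a constant response (e.g. an
    # undertrained model predicting empty masks); report NA rather than fail
    reg <- tryCatch(
      fit_line(score_df$true_volume_mm3, score_df$predicted_volume_mm3),
      error = function(e) list(slope = NA_real_, intercept = NA_real_,
                               r_squared = NA_real_, n = nrow(score_df)))
    jsonlite::write_json(
      list(slope = reg$slope, intercept = reg$intercept,
           r_squared = reg$r_squared, n = reg$n,
           mape = mape(score_df$true_volume_mm3, score_df$predicted_volume_mm3)),
      file.path(out_dir, "regression.json"), auto_unbox = TRUE, digits = NA)
    ggplot2::ggsave(file.path(out_dir, "plots", "dice_per_patient.png"),
                    plot_dice_per_patient(dice_df), width = 5, height = 4, dpi = 120)
    ggplot2::ggsave(file.path(out_dir, "plots", "score_regression.png"),
                    plot_score_regression(score_df), width = 5, height = 4, dpi = 120)
    ggplot2::ggsave(file.path(out_dir, "plots", "ape_per_patient.png"),
                    plot_ape_per_patient(score_df), width = 5, height = 4, dpi = 120)
    reg
  })

  manifest <- list(
    command = "run_pipeline",
    package_version = as.character(utils::packageVersion("vasccalc")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config_jsonable(config),
    config_fingerprint = config_fingerprint(config),
    train_patients = train_ids, test_patients = test_ids,
    outputs = list(history = "history.csv",
                   dice_per_patient = "dice_per_patient.csv",
                   dice_per_slice = "dice_per_slice.csv",
                   scores = "scores.csv", regression = "regression.json"),
    summary = list(mean_test_dice = mean(dice_df$mean_dice),
                   mape = mape(score_df$true_volume_mm3,
                               score_df$predicted_volume_mm3),
                   r_squared = reg$r_squared))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Generate a cohort of randomized phantom patients
#'
#' One phantom per patient, each from an independent seed derived from
#' the master seed; ids are `P01`, `P02`, ...
#'
#' @param n number of patients.
#' @param image_size,n_slices,noise_sigma forwarded to
#'   [random_phantom_spec()].
#' @param seed master seed.
#' @return Named list of `list(volume, mask, truth, spec)` per patient.
#' @export
make_phantom_cohort <- function(n, image_size = 64L, n_slices = 12L,
                                noise_sigma = 4, seed = 1L) {
  out <- list()
  for (i in seq_len(n)) {
    spec <- random_phantom_spec(seed = (seed * 1000L + i) %% .Machine$integer.max,
                                image_size = image_size, n_slices = n_slices,
                                noise_sigma = noise_sigma)
    ph <- generate_phantom(spec)
    pid <- sprintf("P%02d", i)
    ph$volume$patient_id <- pid
    out[[pid]] <- list(volume = ph$volume, mask = ph$truth$vessel_mask,
                       truth = ph$truth, spec = spec)
  }
  out
}

config_jsonable <- function(config) {
  # augment_config serializes cleanly; strip classes recursively
  strip <- function(x) {
    if (is.list(x)) { x <- lapply(x, strip); attributes(x) <- list(names = names(x)) }
    x
  }
  strip(config)
}

# small order-sensitive string fingerprint (FNV-1a over the JSON encoding)
config_fingerprint <- function(config) {
  s <- jsonlite::toJSON(config_jsonable(config), auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2^26
  sprintf("%08x", as.integer(h))
}

#' Bar chart of per-patient Dice scores
#' @param dice_df data.frame with `patient_id`, `mean_dice`.
#' @return A ggplot object.
#' @export
plot_dice_per_patient <- function(dice_df) {
  ggplot2::ggplot(dice_df,
                  ggplot2::aes(x = .data$patient_id, y = .data$mean_dice)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = mean(dice_df$mean_dice), linetype = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "patient", y = "mean per-slice Dice",
                  title = "Segmentation accuracy per held-out patient") +
    ggplot2::theme_minimal()
}

#' Scatter of automated vs true calcium volume with fitted line
#' @param score_df data.frame with `true_volume_mm3`, `predicted_volume_mm3`.
#' @return A ggplot object.
#' @export
plot_score_regression <- function(score_df) {
  ggplot2::ggplot(score_df,
                  ggplot2::aes(x = .data$true_volume_mm3,
                               y = .data$predicted_volume_mm3)) +
    ggplot2::geom_point(color = "#d95f02") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "#1b9e77") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(x = "true calcium volume (mm^3)",
                  y = "automated calcium volume (mm^3)",
                  title = "Automated vs true calcium volume") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-patient absolute percentage error
#' @param score_df data.frame with `patient_id`, `ape`.
#' @return A ggplot object.
#' @export
plot_ape_per_patient <- function(score_df) {
  ggplot2::ggplot(score_df, ggplot2::aes(x = .data$patient_id, y = .data$ape)) +
    ggplot2::geom_col(fill = "#7570b3") +
    ggplot2::labs(x = "patient", y = "APE (%)",
                  title = "Calcium-score error per held-out patient") +
    ggplot2::theme_minimal()
}
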