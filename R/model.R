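#' Segmentation model configuration
#'
#' Describes the U-Net style encoder--decoder: a residual-block encoder
#' with five downsampling stages (each halving the spatial resolution, so
#' the input side must be divisible by 32), four skip connections passed
#' to the decoder, five decoder blocks (each upsampling by two,
#' concatenating the matching encoder feature, then applying two
#' conv--batch-norm--ReLU stages), and a final 1x1 convolution with a
#' sigmoid producing a per-pixel vessel probability. Grayscale input is
#' duplicated into three channels internally, mirroring the convention of
#' encoders born as RGB classifiers.
#'
#' The default `base_channels = 8` is a desk-scale model that is
#' architecture-isomorphic to a full-width network (same graph, fewer
#' channels) and trains on a CPU in minutes; widen it for full-size runs.
#' Pretrained encoder weights are deliberately not bundled: `pretrained`
#' is an optional hook that loads a checkpoint file when given, and random
#' (He) initialization is the default.
#'
#' @param base_channels channels of the first encoder stage; later stages
#'   use 2x/4x/8x this width.
#' @param input_channels fixed at 3 (grayscale duplicated).
#' @param pretrained optional path to a checkpoint whose weights seed the
#'   model; `NULL` (default) for random initialization.
#' @param seed integer used for weight initialization.
#' @return A `model_config` object.
#' @export
model_config <- function(base_channels = 8L, input_channels = 3L,
                         pretrained = NULL, seed = 1L) {
  stopifnot(base_channels >= 1L, input_channels == 3L)
  structure(list(base_channels = as.integer(base_channels),
                 input_channels = 3L,
                 depth = 5L, n_skips = 4L,
                 pretrained = pretrained, seed = as.integer(seed)),
            class = "model_config")
}

#' Build the segmentation network
#'
#' Instantiates the encoder--decoder of [model_config()] with
#' He-initialized weights (deterministic for a fixed `config$seed`), or
#' with weights loaded from `config$pretrained` when set.
#'
#' @param config a [model_config()].
#' @return A `vasc_unet` model handle holding the parameters, the batch
#'   normalization running statistics, and the config.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  if (!is.null(config$pretrained)) {
    mdl <- load_checkpoint(config$pretrained)
    mdl$config <- config
    return(mdl)
  }
  old <- .Random.seed_store(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  b <- config$base_channels
  params <- list(
    e1 = init_cbr(3L, config$input_channels, b),
    e2 = init_resblock(b, 2L * b),
    e3 = init_resblock(2L * b, 4L * b),
    e4 = init_resblock(4L * b, 8L * b),
    e5 = init_resblock(8L * b, 8L * b),
    d1 = list(c1 = init_cbr(3L, 16L * b, 4L * b), c2 = init_cbr(3L, 4L * b, 4L * b)),
    d2 = list(c1 = init_cbr(3L, 8L * b, 2L * b), c2 = init_cbr(3L, 2L * b, 2L * b)),
    d3 = list(c1 = init_cbr(3L, 4L * b, b), c2 = init_cbr(3L, b, b)),
    d4 = list(c1 = init_cbr(3L, 2L * b, b), c2 = init_cbr(3L, b, b)),
    d5 = list(c1 = init_cbr(3L, b, b), c2 = init_cbr(3L, b, b)),
    head = init_conv(1L, b, 1L))
  state <- list(
    e1 = init_cbr_state(b),
    e2 = init_resblock_state(2L * b), e3 = init_resblock_state(4L * b),
    e4 = init_resblock_state(8L * b), e5 = init_resblock_state(8L * b),
    d1 = list(c1 = init_cbr_state(4L * b), c2 = init_cbr_state(4L * b)),
    d2 = list(c1 = init_cbr_state(2L * b), c2 = init_cbr_state(2L * b)),
    d3 = list(c1 = init_cbr_state(b), c2 = init_cbr_state(b)),
    d4 = list(c1 = init_cbr_state(b), c2 = init_cbr_state(b)),
    d5 = list(c1 = init_cbr_state(b), c2 = init_cbr_state(b)))
  structure(list(params = params, state = state, config = config),
            class = "vasc_unet")
}

#' @export
print.vasc_unet <- function(x, ...) {
  cat(sprintf("<vasc_unet> base %d channels, %d trainable parameters\n",
              x$config$base_channels, count_params(x)))
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model a `vasc_unet`.
#' @return Integer count of weights, biases and batch-norm affines.
#' @export
count_params <- function(model) {
  n <- 0L
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk) else n <<- n + length(p)
    invisible(NULL)
  }
  walk(model$params)
  n
}

dec_fwd <- function(x, skip, p, st, training) {
  u <- upsample2_fwd(x)
  xin <- if (is.null(skip)) u else concat_ch(u, skip)
  c1 <- cbr_fwd(xin, p$c1, st$c1, training)
  c2 <- cbr_fwd(c1$y, p$c2, st$c2, training)
  list(y = c2$y, st = list(c1 = c1$st, c2 = c2$st),
       cache = list(c1 = c1$cache, c2 = c2$cache,
                    up_ch = dim(u)[3L], has_skip = !is.null(skip)))
}

dec_bwd <- function(gy, p, cache) {
  c2 <- cbr_bwd(gy, p$c2, cache$c2)
  c1 <- cbr_bwd(c2$gx, p$c1, cache$c1)
  if (cache$has_skip) {
    sp <- split_ch(c1$gx, cache$up_ch)
    gup <- sp$a; gskip <- sp$b
  } else {
    gup <- c1$gx; gskip <- NULL
  }
  list(gx = upsample2_bwd(gup), gskip = gskip,
       g = list(c1 = c1$g, c2 = c2$g))
}

# Full forward pass. x: (H, W, 3, N) in [0, 1]. Returns probabilities and,
# when training, the caches needed for the backward pass and the updated
# batch-norm running statistics.
unet_forward <- function(model, x, training = FALSE) {
  p <- model$params; st <- model$state
  d <- dim(x)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop("input side lengths must be divisible by 32", call. = FALSE)
  e1 <- cbr_fwd(x, p$e1, st$e1, training, stride = 2L)
  e2 <- resblock_fwd(e1$y, p$e2, st$e2, training)
  e3 <- resblock_fwd(e2$y, p$e3, st$e3, training)
  e4 <- resblock_fwd(e3$y, p$e4, st$e4, training)
  e5 <- resblock_fwd(e4$y, p$e5, st$e5, training)
  d1 <- dec_fwd(e5$y, e4$y, p$d1, st$d1, training)
  d2 <- dec_fwd(d1$y, e3$y, p$d2, st$d2, training)
  d3 <- dec_fwd(d2$y, e2$y, p$d3, st$d3, training)
  d4 <- dec_fwd(d3$y, e1$y, p$d4, st$d4, training)
  d5 <- dec_fwd(d4$y, NULL, p$d5, st$d5, training)
  hd <- conv_fwd(d5$y, p$head, 1L, 0L)
  prob <- sigmoid(hd$y)
  new_state <- list(e1 = e1$st, e2 = e2$st, e3 = e3$st, e4 = e4$st, e5 = e5$st,
                    d1 = d1$st, d2 = d2$st, d3 = d3$st, d4 = d4$st, d5 = d5$st)
  caches <- list(e1 = e1$cache, e2 = e2$cache, e3 = e3$cache, e4 = e4$cache,
                 e5 = e5$cache, d1 = d1$cache, d2 = d2$cache, d3 = d3$cache,
                 d4 = d4$cache, d5 = d5$cache, head = hd$cache)
  list(prob = prob, state = new_state, caches = caches)
}

# Backward pass from the gradient w.r.t. the pre-sigmoid logits.
unet_backward <- function(model, gz, caches) {
  p <- model$params
  hd <- conv_bwd(gz, p$head, caches$head)
  d5 <- dec_bwd(hd$gx, p$d5, caches$d5)
  d4 <- dec_bwd(d5$gx, p$d4, caches$d4)
  d3 <- dec_bwd(d4$gx, p$d3, caches$d3)
  d2 <- dec_bwd(d3$gx, p$d2, caches$d2)
  d1 <- dec_bwd(d2$gx, p$d1, caches$d1)
  e5 <- resblock_bwd(d1$gx, p$e5, caches$e5)
  e4 <- resblock_bwd(e5$gx + d1$gskip, p$e4, caches$e4)
  e3 <- resblock_bwd(e4$gx + d2$gskip, p$e3, caches$e3)
  e2 <- resblock_bwd(e3$gx + d3$gskip, p$e2, caches$e2)
  e1 <- cbr_bwd(e2$gx + d4$gskip, p$e1, caches$e1)
  list(e1 = e1$g, e2 = e2$g, e3 = e3$g, e4 = e4$g, e5 = e5$g,
       d1 = d1$g, d2 = d2$g, d3 = d3$g, d4 = d4$g, d5 = d5$g,
       head = hd$g)
}

# Stack grayscale slices into the (H, W, 3, N) network input, scaled to [0,1].
slices_to_input <- function(slices) {
  d <- dim(slices[[1L]])
  x <- array(0, c(d[1], d[2], 3L, length(slices)))
  for (i in seq_along(slices)) {
    g <- slices[[i]] / 255
    x[, , 1L, i] <- g; x[, , 2L, i] <- g; x[, , 3L, i] <- g
  }
  x
}

#' Segment a CT volume slice by slice
#'
#' Runs inference (batch-norm in inference mode, running statistics) on
#' every slice of an 8-bit volume and binarizes the per-pixel vessel
#' probabilities at `threshold`. The output mask is geometry-locked to the
#' input volume.
#'
#' @param model a trained `vasc_unet`.
#' @param vol a [ct_volume()] on the 8-bit scale, side lengths divisible
#'   by 32.
#' @param threshold binarization threshold in (0, 1); 0.5 by default (the
#'   conventional cut on a sigmoid output).
#' @param batch_size slices per forward pass.
#' @return `list(prob = (row, col, slice) probability array,
#'   mask = binary_mask)`.
#' @export
predict_volume <- function(model, vol, threshold = 0.5, batch_size = 8L) {
  stopifnot(inherits(model, "vasc_unet"), inherits(vol, "ct_volume"))
  if (vol$intensity_scale != "8bit")
    stop("predict_volume expects an 8-bit volume; convert with hu_to_8bit()",
         call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)", call. = FALSE)
  d <- dim(vol$voxels)
  ns <- d[3L]
  prob <- array(0, d)
  for (start in seq(1L, ns, by = batch_size)) {
    idx <- start:min(ns, start + batch_size - 1L)
    x <- slices_to_input(lapply(idx, function(s) vol$voxels[, , s]))
    out <- unet_forward(model, x, training = FALSE)
    prob[, , idx] <- out$prob[, , 1L, ]
  }
  mask <- binary_mask(array(as.integer(prob > threshold), d), vol$spacing)
  list(prob = prob, mask = mask)
}

#' Save / load a model checkpoint
#'
#' Weights and running statistics are serialized to `<path>.rds`; the
#' architecture config is written alongside as an explicit JSON sidecar
#' (`<path>.json`) so a checkpoint is never interpreted without its
#' architecture.
#'
#' @param model a `vasc_unet`.
#' @param path checkpoint stem (no extension).
#' @return `path` (save) or the restored `vasc_unet` (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "vasc_unet"))
  saveRDS(list(params = model$params, state = model$state), paste0(path, ".rds"))
  cfg <- model$config
  jsonlite::write_json(
    list(base_channels = cfg$base_channels, input_channels = cfg$input_channels,
         depth = cfg$depth, n_skips = cfg$n_skips, seed = cfg$seed,
         package_version = as.character(utils::packageVersion("vasccalc"))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  cfg_file <- paste0(path, ".json")
  if (!file.exists(cfg_file))
    stop("checkpoint config sidecar missing: ", cfg_file, call. = FALSE)
  cfg <- jsonlite::read_json(cfg_file, simplifyVector = TRUE)
  blob <- readRDS(paste0(path, ".rds"))
  structure(list(params = blob$params, state = blob$state,
                 config = model_config(base_channels = cfg$base_channels,
                                       seed = cfg$seed)),
            class = "vasc_unet")
}
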