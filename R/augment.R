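#' Training-time augmentation configuration
#'
#' Parameters of the stochastic augmentation pipeline applied to
#' image/mask pairs during training. Geometric transforms (horizontal
#' flip, grid distortion, downscale--rescale) are applied identically to
#' the image and its mask; photometric transforms (histogram
#' equalization, CLAHE, blur, brightness/contrast jitter) touch the image
#' only, since equalizing or jittering a `{0,1}` mask is meaningless.
#'
#' Defaults follow the training recipe this pipeline implements: CLAHE
#' contrast limit 0.4, blur with maximum kernel size 7 (sampled from the
#' odd sizes 3/5/7), horizontal flip with probability 0.25, grid
#' distortion (5x5 control grid, per-cell limit 0.3) with probability
#' 0.70, and downscaling to 60--90% of the original size with probability
#' 0.30. Photometric transforms fire with probability 0.5 each (the
#' default of the augmentation libraries this recipe mirrors). Jitter
#' `saturation`/`hue` entries are accepted but inert on single-channel
#' grayscale CT.
#'
#' @param clahe_clip CLAHE contrast (clip) limit.
#' @param blur_max_kernel maximum box-blur kernel size (odd).
#' @param hflip_prob horizontal-flip probability.
#' @param grid_distort_prob grid-distortion probability.
#' @param grid_steps control-grid cells per side.
#' @param grid_limit per-node displacement limit as a fraction of a cell.
#' @param downscale_range `c(lo, hi)` rescale fraction range, within (0, 1].
#' @param downscale_prob downscale probability.
#' @param jitter named list of `brightness`, `contrast`, `saturation`,
#'   `hue` half-ranges.
#' @param hist_eq enable histogram equalization.
#' @param photometric_prob firing probability of each photometric step.
#' @param multiplicity augmented copies generated per original pair when
#'   expanding a training set.
#' @return An `augment_config` object.
#' @export
augment_config <- function(clahe_clip = 0.4, blur_max_kernel = 7L,
                           hflip_prob = 0.25, grid_distort_prob = 0.70,
                           grid_steps = 5L, grid_limit = 0.3,
                           downscale_range = c(0.60, 0.90),
                           downscale_prob = 0.30,
                           jitter = list(brightness = 0.2, contrast = 0.2,
                                         saturation = 0.2, hue = 0.1),
                           hist_eq = TRUE, photometric_prob = 0.5,
                           multiplicity = 3L) {
  probs <- c(hflip_prob, grid_distort_prob, downscale_prob, photometric_prob)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (downscale_range[1] <= 0 || downscale_range[2] > 1 ||
      downscale_range[1] > downscale_range[2])
    stop("downscale_range must be an increasing interval within (0, 1]", call. = FALSE)
  structure(list(clahe_clip = clahe_clip, blur_max_kernel = as.integer(blur_max_kernel),
                 hflip_prob = hflip_prob, grid_distort_prob = grid_distort_prob,
                 grid_steps = as.integer(grid_steps), grid_limit = grid_limit,
                 downscale_range = downscale_range, downscale_prob = downscale_prob,
                 jitter = jitter, hist_eq = isTRUE(hist_eq),
                 photometric_prob = photometric_prob,
                 multiplicity = as.integer(multiplicity)),
            class = "augment_config")
}

#' Augment an image/mask pair
#'
#' Applies one stochastic pass of the augmentation pipeline. Geometric
#' transforms use bilinear resampling for the image and nearest-neighbour
#' for the mask, so the output mask is always binary. Deterministic for a
#' fixed `seed`.
#'
#' @param image numeric matrix on the 0--255 scale.
#' @param mask `{0,1}` matrix of the same shape.
#' @param config an [augment_config()].
#' @param seed optional integer; when given, the pair is a pure function
#'   of `(image, mask, config, seed)` and the caller's RNG stream is left
#'   untouched.
#' @return `list(image, mask)` with the same shapes as the inputs.
#' @export
augment_pair <- function(image, mask, config = augment_config(), seed = NULL) {
  stopifnot(is.matrix(image), is.matrix(mask),
            identical(dim(image), dim(mask)))
  if (!all(mask %in% c(0, 1)))
    stop("mask must be binary", call. = FALSE)
  if (!is.null(seed)) {
    old <- .Random.seed_store(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  img <- as.numeric(image); dim(img) <- dim(image)
  msk <- mask
  pp <- config$photometric_prob
  if (config$hist_eq && runif(1) < pp) img <- equalize_hist(img)
  if (config$clahe_clip > 0 && runif(1) < pp) img <- apply_clahe(img, config$clahe_clip)
  if (config$blur_max_kernel >= 3L && runif(1) < pp) {
    k <- sample(seq(3L, config$blur_max_kernel, by = 2L), 1L)
    img <- box_blur(img, k)
  }
  if (runif(1) < config$hflip_prob) {
    img <- img[, ncol(img):1, drop = FALSE]
    msk <- msk[, ncol(msk):1, drop = FALSE]
  }
  if (runif(1) < config$grid_distort_prob) {
    gm <- grid_distortion_maps(dim(img), config$grid_steps, config$grid_limit)
    img <- resample_bilinear(img, gm$r, gm$c)
    msk <- resample_nearest(msk, gm$r, gm$c)
  }
  if (runif(1) < config$downscale_prob) {
    f <- runif(1, config$downscale_range[1], config$downscale_range[2])
    img <- down_up(img, f, bilinear = TRUE)
    msk <- down_up(msk, f, bilinear = FALSE)
  }
  if (runif(1) < pp) {
    b <- runif(1, -config$jitter$brightness, config$jitter$brightness) * 255
    cmul <- runif(1, 1 - config$jitter$contrast, 1 + config$jitter$contrast)
    m <- mean(img)
    img <- (img - m) * cmul + m + b
  }
  d <- dim(img)
  img <- pmin(pmax(img, 0), 255)
  dim(img) <- d
  storage.mode(msk) <- "integer"
  list(image = img, mask = msk)
}

equalize_hist <- function(img) {
  x <- pmin(255L, pmax(0L, as.integer(round(img))))
  h <- tabulate(x + 1L, 256L)
  cdf <- cumsum(h) / length(x)
  y <- round(cdf[x + 1L] * 255)
  dim(y) <- dim(img)
  y
}

apply_clahe <- function(img, clip) {
  d <- dim(img)
  # CLAHE tiles need the side divisible by the grid; fall back to plain
  # equalization for tiny images
  if (any(d < 16L)) return(equalize_hist(img))
  nx <- max(2L, min(8L, d[2] %/% 8L)); ny <- max(2L, min(8L, d[1] %/% 8L))
  out <- EBImage::clahe(img / 255, nx = nx, ny = ny, limit = clip)
  pmin(255, pmax(0, as.numeric(out) * 255)) -> y
  dim(y) <- d
  y
}

box_blur <- function(img, k) {
  kern <- matrix(1 / (k * k), k, k)
  as.matrix(EBImage::filter2(img, kern, boundary = "replicate"))
}

# Backward-mapping displacement field from a jittered control grid.
grid_distortion_maps <- function(d, steps, limit) {
  nr <- d[1]; nc <- d[2]
  nodes_r <- seq(1, nr, length.out = steps + 1L)
  nodes_c <- seq(1, nc, length.out = steps + 1L)
  cell_r <- (nr - 1) / steps; cell_c <- (nc - 1) / steps
  disp_r <- matrix(0, steps + 1L, steps + 1L)
  disp_c <- matrix(0, steps + 1L, steps + 1L)
  interior <- 2:steps
  disp_r[interior, interior] <- runif(length(interior)^2, -limit, limit) * cell_r
  disp_c[interior, interior] <- runif(length(interior)^2, -limit, limit) * cell_c
  up_r <- bilinear_grid_expand(disp_r, nodes_r, nodes_c, nr, nc)
  up_c <- bilinear_grid_expand(disp_c, nodes_r, nodes_c, nr, nc)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  list(r = pmin(nr, pmax(1, rr + up_r)), c = pmin(nc, pmax(1, cc + up_c)))
}

# interpolate node values defined on (nodes_r x nodes_c) to the full pixel grid
bilinear_grid_expand <- function(nodeval, nodes_r, nodes_c, nr, nc) {
  r_idx <- findInterval(seq_len(nr), nodes_r, rightmost.closed = TRUE)
  c_idx <- findInterval(seq_len(nc), nodes_c, rightmost.closed = TRUE)
  r0 <- nodes_r[r_idx]; r1 <- nodes_r[r_idx + 1L]
  c0 <- nodes_c[c_idx]; c1 <- nodes_c[c_idx + 1L]
  wr <- (seq_len(nr) - r0) / pmax(r1 - r0, .Machine$double.eps)
  wc <- (seq_len(nc) - c0) / pmax(c1 - c0, .Machine$double.eps)
  v00 <- nodeval[cbind(rep(r_idx, nc), rep(c_idx, each = nr))]
  v10 <- nodeval[cbind(rep(r_idx + 1L, nc), rep(c_idx, each = nr))]
  v01 <- nodeval[cbind(rep(r_idx, nc), rep(c_idx + 1L, each = nr))]
  v11 <- nodeval[cbind(rep(r_idx + 1L, nc), rep(c_idx + 1L, each = nr))]
  WR <- rep(wr, nc); WC <- rep(wc, each = nr)
  out <- (1 - WR) * (1 - WC) * v00 + WR * (1 - WC) * v10 +
    (1 - WR) * WC * v01 + WR * WC * v11
  matrix(out, nr, nc)
}

resample_bilinear <- function(img, map_r, map_c) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- pmin(nr - 1L, pmax(1L, floor(map_r))); r1 <- r0 + 1L
  c0 <- pmin(nc - 1L, pmax(1L, floor(map_c))); c1 <- c0 + 1L
  wr <- map_r - r0; wc <- map_c - c0
  g <- function(ri, ci) img[cbind(as.vector(ri), as.vector(ci))]
  out <- (1 - wr) * (1 - wc) * g(r0, c0) + wr * (1 - wc) * g(r1, c0) +
    (1 - wr) * wc * g(r0, c1) + wr * wc * g(r1, c1)
  matrix(out, nr, nc)
}

resample_nearest <- function(img, map_r, map_c) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- pmin(nr, pmax(1L, round(map_r)))
  ci <- pmin(nc, pmax(1L, round(map_c)))
  matrix(img[cbind(as.vector(ri), as.vector(ci))], nr, nc)
}

down_up <- function(img, f, bilinear = TRUE) {
  nr <- nrow(img); nc <- ncol(img)
  w <- max(2L, round(nr * f)); h <- max(2L, round(nc * f))
  filt <- if (bilinear) "bilinear" else "none"
  small <- EBImage::resize(img, w = w, h = h, filter = filt)
  back <- EBImage::resize(small, w = nr, h = nc, filter = filt)
  m <- as.matrix(back)
  if (!bilinear) m <- round(m)
  m
}

#' Expand a slice set with augmented copies
#'
#' Produces `config$multiplicity` augmented copies of every (image, mask)
#' pair, appended after the originals — the dataset-expansion step that
#' precedes training.
#'
#' @param slices list of `list(image, mask)` pairs.
#' @param config an [augment_config()].
#' @param seed base seed; copy `k` of pair `i` uses a seed derived
#'   deterministically from `(seed, i, k)`.
#' @return The expanded list of pairs.
#' @export
augment_dataset <- function(slices, config = augment_config(), seed = 1L) {
  out <- slices
  for (k in seq_len(config$multiplicity)) {
    for (i in seq_along(slices)) {
      s <- slices[[i]]
      aug <- augment_pair(s$image, s$mask, config,
                          seed = (seed * 10007L + k * 1009L + i) %% .Machine$integer.max)
      s$image <- aug$image; s$mask <- aug$mask
      out[[length(out) + 1L]] <- s
    }
  }
  out
}
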