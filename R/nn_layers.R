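# Neural-network primitives on (H, W, C, N) arrays.
#
# Convolutions run through the compiled im2col+GEMM kernels; batch
# normalization, ReLU, nearest upsampling, channel concatenation and Adam
# are plain R array code. Everything here is internal to the model and
# train modules.

init_conv <- function(k, c_in, c_out) {
  # He initialization for ReLU networks
  w <- array(rnorm(k * k * c_in * c_out, 0, sqrt(2 / (k * k * c_in))),
             c(k, k, c_in, c_out))
  list(w = w, b = numeric(c_out))
}

init_bn <- function(c_out) list(gamma = rep(1, c_out), beta = rep(0, c_out))
init_bn_state <- function(c_out) list(rm = rep(0, c_out), rv = rep(1, c_out))

conv_fwd <- function(x, p, stride = 1L, pad = 1L) {
  y <- conv2d_fwd(x, p$w, p$b, as.integer(stride), as.integer(pad))
  list(y = y, cache = list(x = x, stride = stride, pad = pad))
}

conv_bwd <- function(gy, p, cache) {
  g <- conv2d_bwd(cache$x, p$w, gy, as.integer(cache$stride), as.integer(cache$pad))
  list(gx = g$gx, g = list(w = g$gw, b = g$gb))
}

bcast_ch <- function(v, d) {
  # broadcast a per-channel vector over an (H, W, C, N) array
  array(rep(rep(v, each = d[1] * d[2]), times = d[4]), d)
}

ch_mean <- function(x) apply(x, 3L, mean)
ch_sum <- function(x) apply(x, 3L, sum)

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_fwd <- function(x, p, st, training) {
  d <- dim(x)
  if (training) {
    m <- ch_mean(x)
    xc <- x - bcast_ch(m, d)
    v <- ch_mean(xc * xc)
    st$rm <- (1 - BN_MOMENTUM) * st$rm + BN_MOMENTUM * m
    st$rv <- (1 - BN_MOMENTUM) * st$rv + BN_MOMENTUM * v
  } else {
    m <- st$rm; v <- st$rv
    xc <- x - bcast_ch(m, d)
  }
  inv_sd <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * bcast_ch(inv_sd, d)
  y <- bcast_ch(p$gamma, d) * xhat + bcast_ch(p$beta, d)
  list(y = y, st = st, cache = list(xhat = xhat, inv_sd = inv_sd, d = d))
}

bn_bwd <- function(gy, p, cache) {
  d <- cache$d
  xhat <- cache$xhat
  ggamma <- ch_sum(gy * xhat)
  gbeta <- ch_sum(gy)
  n_per_ch <- d[1] * d[2] * d[4]
  gxhat <- gy * bcast_ch(p$gamma, d)
  gx <- (gxhat - bcast_ch(ch_sum(gxhat) / n_per_ch, d) -
           xhat * bcast_ch(ch_sum(gxhat * xhat) / n_per_ch, d)) *
    bcast_ch(cache$inv_sd, d)
  list(gx = gx, g = list(gamma = ggamma, beta = gbeta))
}

relu_fwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bwd <- function(gy, cache) gy * cache

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
}

upsample2_bwd <- function(gy) {
  d <- dim(gy)
  odd_r <- seq(1L, d[1], 2L); odd_c <- seq(1L, d[2], 2L)
  gy[odd_r, odd_c, , , drop = FALSE] + gy[odd_r + 1L, odd_c, , , drop = FALSE] +
    gy[odd_r, odd_c + 1L, , , drop = FALSE] + gy[odd_r + 1L, odd_c + 1L, , , drop = FALSE]
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_ch <- function(g, c_a) {
  d <- dim(g)
  list(a = g[, , seq_len(c_a), , drop = FALSE],
       b = g[, , (c_a + 1L):d[3], , drop = FALSE])
}

# conv -> BN -> ReLU, the workhorse stage of encoder stem and decoder blocks
cbr_fwd <- function(x, p, st, training, stride = 1L, pad = 1L) {
  cv <- conv_fwd(x, p$conv, stride, pad)
  bn <- bn_fwd(cv$y, p$bn, st$bn, training)
  rl <- relu_fwd(bn$y)
  list(y = rl$y, st = list(bn = bn$st),
       cache = list(cv = cv$cache, bn = bn$cache, rl = rl$cache))
}

cbr_bwd <- function(gy, p, cache) {
  gy <- relu_bwd(gy, cache$rl)
  bn <- bn_bwd(gy, p$bn, cache$bn)
  cv <- conv_bwd(bn$gx, p$conv, cache$cv)
  list(gx = cv$gx, g = list(conv = cv$g, bn = bn$g))
}

init_cbr <- function(k, c_in, c_out) list(conv = init_conv(k, c_in, c_out), bn = init_bn(c_out))
init_cbr_state <- function(c_out) list(bn = init_bn_state(c_out))

# residual block: conv(s)-BN-ReLU-conv(1)-BN plus projection shortcut, ReLU
init_resblock <- function(c_in, c_out) {
  list(conv1 = init_conv(3L, c_in, c_out), bn1 = init_bn(c_out),
       conv2 = init_conv(3L, c_out, c_out), bn2 = init_bn(c_out),
       convs = init_conv(1L, c_in, c_out), bns = init_bn(c_out))
}
init_resblock_state <- function(c_out) {
  list(bn1 = init_bn_state(c_out), bn2 = init_bn_state(c_out),
       bns = init_bn_state(c_out))
}

resblock_fwd <- function(x, p, st, training, stride = 2L) {
  c1 <- conv_fwd(x, p$conv1, stride, 1L)
  b1 <- bn_fwd(c1$y, p$bn1, st$bn1, training)
  r1 <- relu_fwd(b1$y)
  c2 <- conv_fwd(r1$y, p$conv2, 1L, 1L)
  b2 <- bn_fwd(c2$y, p$bn2, st$bn2, training)
  cs <- conv_fwd(x, p$convs, stride, 0L)
  bs <- bn_fwd(cs$y, p$bns, st$bns, training)
  s <- b2$y + bs$y
  r2 <- relu_fwd(s)
  list(y = r2$y,
       st = list(bn1 = b1$st, bn2 = b2$st, bns = bs$st),
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache,
                    cs = cs$cache, bs = bs$cache, r2 = r2$cache))
}

resblock_bwd <- function(gy, p, cache) {
  gs <- relu_bwd(gy, cache$r2)
  b2 <- bn_bwd(gs, p$bn2, cache$b2)
  c2 <- conv_bwd(b2$gx, p$conv2, cache$c2)
  g1 <- relu_bwd(c2$gx, cache$r1)
  b1 <- bn_bwd(g1, p$bn1, cache$b1)
  c1 <- conv_bwd(b1$gx, p$conv1, cache$c1)
  bs <- bn_bwd(gs, p$bns, cache$bs)
  cs <- conv_bwd(bs$gx, p$convs, cache$cs)
  list(gx = c1$gx + cs$gx,
       g = list(conv1 = c1$g, bn1 = b1$g, conv2 = c2$g, bn2 = b2$g,
                convs = cs$g, bns = bs$g))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- Adam over nested parameter lists -------------------------------------

adam_init <- function(params) {
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk)
    else list(m = p * 0, v = p * 0)
  }
  lapply(params, walk)
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  step_one <- function(p, g, s) {
    if (is.list(p) && !all(c("m", "v") %in% names(s))) {
      out_p <- p; out_s <- s
      for (nm in names(p)) {
        r <- step_one(p[[nm]], g[[nm]], s[[nm]])
        out_p[[nm]] <- r$p; out_s[[nm]] <- r$s
      }
      return(list(p = out_p, s = out_s))
    }
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g * g
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  step_one(params, grads, state)
}
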