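# Minimal neural-network primitives shared by the vision and sequence models.
# Convolution/pooling forward+backward live in src/nn_ops.cpp; parameters are
# plain named lists of arrays so checkpoints serialize with base R.

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

conv_param <- function(kh, kw, cin, cout) {
  list(W = he_init(c(kh, kw, cin, cout), kh * kw * cin),
       b = numeric(cout))
}

dense_param <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

conv_fwd <- function(x, p, pad = 1L) conv2d_fwd(x, p$W, p$b, as.integer(pad))

conv_bwd <- function(x, p, dy, pad = 1L) conv2d_bwd(x, p$W, dy, as.integer(pad))

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bwd <- function(y, dy) {
  dy[y <= 0] <- 0
  dy
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Nearest-neighbour 2x upsampling and its adjoint (gradient).
upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  h <- seq(1L, d[1], by = 2L)
  w <- seq(1L, d[2], by = 2L)
  dy[h, w, , , drop = FALSE] + dy[h + 1L, w, , , drop = FALSE] +
    dy[h, w + 1L, , , drop = FALSE] + dy[h + 1L, w + 1L, , , drop = FALSE]
}

# Softmax over the channel dimension of an (H, W, C, N) array.
softmax_channels <- function(z) {
  zmax <- apply(z, c(1, 2, 4), max)
  d <- dim(z)
  e <- exp(z - aperm(array(zmax, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3)))
  s <- apply(e, c(1, 2, 4), sum)
  e / aperm(array(s, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
}

# Adam over an arbitrarily nested list of numeric arrays.
adam_init <- function(params) {
  zero <- function(p) if (is.list(p)) lapply(p, zero) else p * 0
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      if (!is.null(names(p)) && !is.null(names(g))) g <- g[names(p)]
      out <- Map(walk, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

# Stack frames (list of H x W matrices) into an (H, W, 1, N) batch tensor.
frames_to_batch <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 4) return(frames)
  d <- dim(frames[[1]])
  array(unlist(frames, use.names = FALSE), dim = c(d[1], d[2], 1L, length(frames)))
}

# Bilinear resize of a single-channel matrix via EBImage.
resize_matrix <- function(m, h, w) {
  if (nrow(m) == h && ncol(m) == w) return(m)
  # EBImage images are (x, y); transpose in and out to keep (row, col).
  t(EBImage::resize(EBImage::Image(t(m)), w = w, h = h))[, , drop = TRUE]
}
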