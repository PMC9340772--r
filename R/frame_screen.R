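#' Covered/uncovered frame screening
#'
#' ICU patients are blanketed most of the time; CPD can only be read off
#' frames where abdomen and feet are exposed. A small convolutional network
#' classifies every 1-Hz frame as covered or uncovered, and only uncovered
#' frames feed the downstream CPD extraction.
#'
#' @name frame_screen
NULL

#' Pixel mean and standard deviation over a set of frames
#'
#' Computed on training frames only and stored with the model so training and
#' inference normalize identically.
#'
#' @param frames List of numeric matrices.
#' @return List with `mean` and `sd` over all pixels of all frames.
#' @export
compute_norm_stats <- function(frames) {
  if (length(frames) < 1) stop("need at least one frame")
  v <- unlist(lapply(frames, as.numeric), use.names = FALSE)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("constant input: zero pixel variance, cannot normalize")
  list(mean = mean(v), sd = s)
}

screen_config_default <- function() {
  list(input_size = 64L, n_blocks = 4L, filters = c(8L, 16L, 32L, 32L),
       lr = 1e-3, epochs = 8L, batch_size = 16L, augment = TRUE,
       rotation_deg = 10, noise_sd = 0.05, threshold = 0.5)
}

augment_frame <- function(m, rotation_deg, noise_sd) {
  if (stats::runif(1) < 0.5) m <- m[, rev(seq_len(ncol(m)))]
  ang <- stats::runif(1, -rotation_deg, rotation_deg)
  img <- EBImage::rotate(EBImage::Image(t(m)), ang,
                         output.dim = c(ncol(m), nrow(m)), bg.col = m[1, 1])
  m <- t(img[, , drop = TRUE])
  m + matrix(stats::rnorm(length(m), sd = noise_sd), nrow(m))
}

screen_prepare <- function(frames, stats, size) {
  lapply(frames, function(f)
    (resize_matrix(f, size, size) - stats$mean) / stats$sd)
}

cnn_init <- function(cfg) {
  cin <- 1L
  convs <- vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    convs[[b]] <- conv_param(3L, 3L, cin, cfg$filters[b])
    cin <- cfg$filters[b]
  }
  list(convs = convs, head = dense_param(cin, 1L))
}

cnn_forward <- function(params, x, keep_cache = FALSE) {
  cache <- list(inputs = list(), acts = list(), pools = list())
  for (b in seq_along(params$convs)) {
    if (keep_cache) cache$inputs[[b]] <- x
    a <- relu_fwd(conv_fwd(x, params$convs[[b]]))
    p <- maxpool2_fwd(a)
    if (keep_cache) {
      cache$acts[[b]] <- a
      cache$pools[[b]] <- p$idx
    }
    x <- p$Y
  }
  d <- dim(x)
  feat <- t(matrix(apply(x, c(3, 4), mean), d[3], d[4]))   # N x C
  logits <- sweep(feat %*% params$head$W, 2, params$head$b, `+`)
  prob <- sigmoid(logits)
  cache$top_dim <- d
  cache$feat <- feat
  list(prob = as.numeric(prob), cache = if (keep_cache) cache)
}

cnn_backward <- function(params, cache, dlogit) {
  # dlogit: N x 1
  grads <- list(convs = vector("list", length(params$convs)), head = list())
  grads$head$W <- t(cache$feat) %*% dlogit
  grads$head$b <- colSums(dlogit)
  dfeat <- dlogit %*% t(params$head$W)                     # N x C
  d <- cache$top_dim
  dx <- array(0, dim = d)
  per <- 1 / (d[1] * d[2])
  for (n in seq_len(d[4]))
    for (c in seq_len(d[3]))
      dx[, , c, n] <- dfeat[n, c] * per
  for (b in rev(seq_along(params$convs))) {
    a <- cache$acts[[b]]
    da <- maxpool2_bwd(cache$pools[[b]], dx, dim(a))
    dz <- relu_bwd(a, da)
    g <- conv_bwd(cache$inputs[[b]], params$convs[[b]], dz)
    grads$convs[[b]] <- list(W = g$dW, b = g$db)
    dx <- g$dX
  }
  grads
}

#' Train the covered/uncovered screening classifier
#'
#' @param frames List of numeric matrices (raw sensor counts).
#' @param labels Binary vector, 1 = uncovered.
#' @param config Optional overrides of the defaults in
#'   `screen_config_default()` (input size, conv blocks, filters, learning
#'   rate, epochs, augmentation).
#' @param seed Integer seed for initialization, batching and augmentation.
#' @return A `screen_model` with embedded normalization stats and config.
#' @export
train_screen_classifier <- function(frames, labels, config = list(),
                                    seed = 1L) {
  cfg <- utils::modifyList(screen_config_default(), config)
  labels <- as.integer(labels)
  if (length(frames) == 0) stop("empty dataset")
  if (length(unique(labels)) < 2)
    stop("both covered and uncovered classes must be present for training")
  stats <- compute_norm_stats(frames)
  prep <- screen_prepare(frames, stats, cfg$input_size)
  with_seed(seed, {
    params <- cnn_init(cfg)
    opt <- adam_init(params)
    n <- length(prep)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(n, start + cfg$batch_size - 1)]
        batch <- prep[idx]
        if (cfg$augment)
          batch <- lapply(batch, augment_frame,
                          rotation_deg = cfg$rotation_deg,
                          noise_sd = cfg$noise_sd)
        x <- frames_to_batch(batch)
        y <- labels[idx]
        fw <- cnn_forward(params, x, keep_cache = TRUE)
        dlogit <- matrix((fw$prob - y) / length(idx), ncol = 1)
        grads <- cnn_backward(params, fw$cache, dlogit)
        step <- adam_step(params, grads, opt, lr = cfg$lr)
        params <- step$params
        opt <- step$state
      }
    }
    structure(list(params = params, norm = stats, config = cfg),
              class = "screen_model")
  })
}

#' Screen frames for blanket cover
#'
#' @param model A trained `screen_model`.
#' @param frames List of numeric matrices.
#' @return `data.frame` with `frame_id`, `p_uncovered`, `is_uncovered`
#'   (decision at the configured threshold, default 0.5); one row per frame.
#' @export
screen_frames <- function(model, frames) {
  stopifnot(inherits(model, "screen_model"))
  if (length(frames) == 0)
    return(data.frame(frame_id = integer(0), p_uncovered = numeric(0),
                      is_uncovered = logical(0)))
  prep <- screen_prepare(frames, model$norm, model$config$input_size)
  p <- numeric(length(prep))
  bs <- 64L
  for (start in seq(1, length(prep), by = bs)) {
    idx <- start:min(length(prep), start + bs - 1)
    p[idx] <- cnn_forward(model$params, frames_to_batch(prep[idx]))$prob
  }
  data.frame(frame_id = seq_along(frames), p_uncovered = p,
             is_uncovered = p >= model$config$threshold)
}
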