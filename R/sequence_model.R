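#' Recurrent sequence classifier for shock windows
#'
#' An LSTM encoder reads the 256-step (CPD, heart-rate) window, honoring the
#' padding mask (hidden state carries through padded steps, so the padding
#' fill value can never influence the output), followed by dense layers with
#' dropout and a single sigmoid unit giving the shock probability.
#' Thresholding is deferred to evaluation (Youden's index).
#'
#' @name sequence_model
NULL

#' Sequence-model configuration
#'
#' @param lstm_hidden Hidden units per LSTM layer.
#' @param lstm_layers Number of stacked LSTM layers.
#' @param dense_sizes Sizes of the dense layers between the encoder and the
#'   sigmoid output.
#' @param dropout Dropout fraction after each dense layer, in `[0, 1)`.
#' @param lr Adam learning rate.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience on validation AUPRC.
#' @param feature_scale Divisors applied to the (CPD, heart-rate) columns to
#'   bring both features to order 1.
#' @return A `seq_model_config` list.
#' @export
seq_model_config <- function(lstm_hidden = 64L, lstm_layers = 1L,
                             dense_sizes = 32L, dropout = 0.2,
                             lr = 1e-3, epochs = 30L, batch_size = 32L,
                             patience = 10L, feature_scale = c(20, 150)) {
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (lstm_hidden < 1 || lstm_layers < 1) stop("invalid architecture sizes")
  structure(as.list(environment()), class = "seq_model_config")
}

#' Initialize an untrained sequence model
#'
#' @param config A [seq_model_config()].
#' @param n_features Input features per step (2: CPD, heart rate).
#' @return A `seq_model`.
#' @export
build_seq_model <- function(config = seq_model_config(), n_features = 2L) {
  H <- config$lstm_hidden
  layers <- vector("list", config$lstm_layers)
  din <- n_features
  for (l in seq_len(config$lstm_layers)) {
    W <- matrix(stats::rnorm((din + H) * 4 * H, sd = 1 / sqrt(din + H)),
                din + H, 4 * H)
    b <- numeric(4 * H)
    b[(H + 1):(2 * H)] <- 1           # forget-gate bias
    layers[[l]] <- list(W = W, b = b)
    din <- H
  }
  dense <- list()
  din <- H
  for (s in config$dense_sizes) {
    dense[[length(dense) + 1]] <- dense_param(din, s)
    din <- s
  }
  out <- dense_param(din, 1L)
  structure(list(params = list(lstm = layers, dense = dense, out = out),
                 config = config, trained = FALSE),
            class = "seq_model")
}

lstm_layer_fwd <- function(p, xs, mask, keep_cache = FALSE) {
  # xs: list of T matrices (N x D); mask: N x T (TRUE = observed)
  N <- nrow(xs[[1]]); D <- ncol(xs[[1]]); H <- length(p$b) / 4
  h <- matrix(0, N, H); cc <- matrix(0, N, H)
  Tn <- length(xs)
  hs <- vector("list", Tn)
  cache <- if (keep_cache) vector("list", Tn)
  for (t in seq_len(Tn)) {
    xh <- cbind(xs[[t]], h)
    z <- sweep(xh %*% p$W, 2, p$b, `+`)
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    cnew <- f * cc + i * g
    hnew <- o * tanh(cnew)
    m <- mask[, t]
    if (keep_cache)
      cache[[t]] <- list(xh = xh, i = i, f = f, g = g, o = o,
                         c_prev = cc, c_new = cnew, m = m)
    h <- hnew * m + h * (1 - m)
    cc <- cnew * m + cc * (1 - m)
    hs[[t]] <- h
  }
  list(hs = hs, h_last = h, cache = cache)
}

lstm_layer_bwd <- function(p, cache, dhs, dh_last) {
  # dhs: list of T (N x H) grads on the post-mask hidden sequence (may be
  # NULL per step); dh_last adds to the final step
  Tn <- length(cache)
  N <- nrow(cache[[1]]$xh)
  H <- length(p$b) / 4
  D <- ncol(cache[[1]]$xh) - H
  dW <- p$W * 0; db <- p$b * 0
  dh <- matrix(0, N, H); dc <- matrix(0, N, H)
  dxs <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    if (!is.null(dhs[[t]])) dh <- dh + dhs[[t]]
    if (t == Tn && !is.null(dh_last)) dh <- dh + dh_last
    cc <- cache[[t]]
    m <- cc$m
    dh_t <- dh * m; dh_carry <- dh * (1 - m)
    dc_t <- dc * m; dc_carry <- dc * (1 - m)
    tc <- tanh(cc$c_new)
    do_ <- dh_t * tc
    dc_t <- dc_t + dh_t * cc$o * (1 - tc^2)
    di <- dc_t * cc$g
    df <- dc_t * cc$c_prev
    dg <- dc_t * cc$i
    dc <- dc_t * cc$f + dc_carry
    dz <- cbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2), do_ * cc$o * (1 - cc$o))
    dW <- dW + t(cc$xh) %*% dz
    db <- db + colSums(dz)
    dxh <- dz %*% t(p$W)
    dxs[[t]] <- dxh[, seq_len(D), drop = FALSE]
    dh <- dxh[, D + seq_len(H), drop = FALSE] + dh_carry
  }
  list(dW = dW, db = db, dxs = dxs)
}

seq_forward <- function(params, x, mask, config, training = FALSE,
                        keep_cache = FALSE) {
  d <- dim(x)                              # N x T x F
  xs <- lapply(seq_len(d[2]), function(t) {
    m <- x[, t, , drop = FALSE]
    dim(m) <- c(d[1], d[3])
    sweep(m, 2, config$feature_scale, `/`)
  })
  mm <- mask * 1
  caches <- list()
  hs <- xs
  for (l in seq_along(params$lstm)) {
    fw <- lstm_layer_fwd(params$lstm[[l]], hs, mm, keep_cache)
    caches[[l]] <- fw$cache
    hs <- fw$hs
  }
  a <- fw$h_last
  dense_cache <- list()
  drop_masks <- list()
  for (j in seq_along(params$dense)) {
    z <- sweep(a %*% params$dense[[j]]$W, 2, params$dense[[j]]$b, `+`)
    h <- relu_fwd(z)
    if (training && config$dropout > 0) {
      dm <- matrix(stats::rbinom(length(h), 1, 1 - config$dropout),
                   nrow(h)) / (1 - config$dropout)
      h <- h * dm
      drop_masks[[j]] <- dm
    }
    dense_cache[[j]] <- list(input = a, act = h)
    a <- h
  }
  logits <- sweep(a %*% params$out$W, 2, params$out$b, `+`)
  prob <- sigmoid(logits)
  list(prob = as.numeric(prob),
       cache = if (keep_cache)
         list(lstm = caches, dense = dense_cache, drop = drop_masks,
              top = a, n_steps = d[2]))
}

seq_backward <- function(params, cache, dlogit, config) {
  grads <- list(lstm = vector("list", length(params$lstm)),
                dense = vector("list", length(params$dense)))
  grads$out <- list(W = t(cache$top) %*% dlogit, b = colSums(dlogit))
  da <- dlogit %*% t(params$out$W)
  for (j in rev(seq_along(params$dense))) {
    dcache <- cache$dense[[j]]
    if (length(cache$drop) >= j && !is.null(cache$drop[[j]]))
      da <- da * cache$drop[[j]]
    dz <- relu_bwd(dcache$act, da)
    grads$dense[[j]] <- list(W = t(dcache$input) %*% dz, b = colSums(dz))
    da <- dz %*% t(params$dense[[j]]$W)
  }
  dh_last <- da
  empty <- vector("list", cache$n_steps)
  for (l in rev(seq_along(params$lstm))) {
    bw <- lstm_layer_bwd(params$lstm[[l]], cache$lstm[[l]],
                         if (l == length(params$lstm)) empty else dhs,
                         if (l == length(params$lstm)) dh_last else NULL)
    grads$lstm[[l]] <- list(W = bw$dW, b = bw$db)
    dhs <- bw$dxs
  }
  grads
}

#' Train the sequence classifier
#'
#' Binary cross-entropy with Adam; the checkpoint with the best validation
#' AUPRC is kept (early stopping, default patience 10). The training cohort
#' should already be SMOTE-balanced; validation must be untouched.
#'
#' @param model A `seq_model` from [build_seq_model()].
#' @param train A `shock_cohort` (balanced).
#' @param validation A `shock_cohort`, or `NULL` to skip early stopping.
#' @param seed Integer seed (initialization was seeded by the caller of
#'   [build_seq_model()]; this seeds batching and dropout).
#' @return The trained `seq_model` with a `history` data.frame.
#' @export
train_seq_model <- function(model, train, validation = NULL, seed = 1L) {
  stopifnot(inherits(model, "seq_model"), inherits(train, "shock_cohort"))
  if (length(unique(train$label)) < 2)
    stop("training set must contain both classes")
  cfg <- model$config
  params <- model$params
  with_seed(seed, {
    opt <- adam_init(params)
    n <- dim(train$x)[1]
    best <- list(metric = -Inf, params = params, epoch = 0L)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_auprc = numeric(0))
    stall <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      tot <- 0; nb <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(n, start + cfg$batch_size - 1)]
        xb <- train$x[idx, , , drop = FALSE]
        mb <- train$mask[idx, , drop = FALSE]
        yb <- train$label[idx]
        fw <- seq_forward(params, xb, mb, cfg, training = TRUE,
                          keep_cache = TRUE)
        eps <- 1e-12
        tot <- tot - mean(yb * log(fw$prob + eps) +
                            (1 - yb) * log(1 - fw$prob + eps))
        nb <- nb + 1
        dlogit <- matrix((fw$prob - yb) / length(idx), ncol = 1)
        grads <- seq_backward(params, fw$cache, dlogit, cfg)
        step <- adam_step(params, grads, opt, lr = cfg$lr)
        params <- step$params
        opt <- step$state
      }
      val_ap <- NA_real_
      if (!is.null(validation) && length(unique(validation$label)) == 2) {
        vp <- seq_forward(params, validation$x, validation$mask, cfg)$prob
        val_ap <- auprc(vp, validation$label)
        if (val_ap > best$metric) {
          best <- list(metric = val_ap, params = params, epoch = ep)
          stall <- 0L
        } else stall <- stall + 1L
      }
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = tot / nb, val_auprc = val_ap))
      if (!is.null(validation) && stall >= cfg$patience) break
    }
    if (is.finite(best$metric)) params <- best$params
    structure(list(params = params, config = cfg, trained = TRUE,
                   history = history, best_epoch = best$epoch),
              class = "seq_model")
  })
}

#' Shock probabilities for a cohort of windows
#'
#' Evaluation mode (dropout disabled): deterministic for identical inputs.
#'
#' @param model A trained `seq_model`.
#' @param cohort A `shock_cohort` (or a list with `x` and `mask`).
#' @return Numeric probabilities in `(0, 1)`, one per window.
#' @export
predict_seq_model <- function(model, cohort) {
  stopifnot(inherits(model, "seq_model"))
  if (dim(cohort$x)[1] == 0) return(numeric(0))
  if (dim(cohort$x)[3] != nrow(model$params$lstm[[1]]$W) -
        model$config$lstm_hidden)
    stop("feature-shape mismatch with the trained model")
  out <- numeric(dim(cohort$x)[1])
  bs <- 256L
  for (start in seq(1, length(out), by = bs)) {
    idx <- start:min(length(out), start + bs - 1)
    out[idx] <- seq_forward(model$params, cohort$x[idx, , , drop = FALSE],
                            cohort$mask[idx, , drop = FALSE],
                            model$config)$prob
  }
  out
}
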