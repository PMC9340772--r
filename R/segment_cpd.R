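#' Abdomen/feet segmentation and CPD extraction
#'
#' A compact U-shaped encoder-decoder with residual double-conv blocks and
#' skip connections segments each masked, uncovered frame into abdomen, feet
#' and background. The center-to-peripheral difference (CPD) is then the
#' relative percent gradient between the two regions,
#' `(A - F) / A * 100`, computed from the modal intensity of each region:
#' the ratio form makes CPD invariant to global intensity gain (hence robust
#' to thermal drift), and the mode is robust to outlier pixels.
#'
#' @name segment_cpd
NULL

#' Dice coefficient between two segmentation masks
#'
#' Per-class dice `2|P.T| / (|P| + |T|)` averaged over classes; classes empty
#' in both masks are skipped. Dice loss is `1 - dice`.
#'
#' @param pred,truth Integer class-code matrices of the same shape
#'   (0 background, 1 abdomen, 2 feet).
#' @param classes Class codes to average over.
#' @param per_class Return the per-class vector instead of the mean.
#' @return Dice in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth, classes = 0:2, per_class = FALSE) {
  if (!identical(dim(pred), dim(truth))) stop("mask shape mismatch")
  d <- vapply(classes, function(k) {
    p <- pred == k
    t <- truth == k
    denom <- sum(p) + sum(t)
    if (denom == 0) NA_real_ else 2 * sum(p & t) / denom
  }, numeric(1))
  names(d) <- as.character(classes)
  if (per_class) d else mean(d, na.rm = TRUE)
}

segmenter_config_default <- function() {
  list(levels = 4L, base_filters = 8L, input_scale = 0.4,
       lr = 2e-3, epochs = 8L, batch_size = 4L,
       dice_weight = 1, ce_weight = 1, prob_cutoff = 0.5,
       n_classes = 3L)
}

res_block_param <- function(cin, cout) {
  list(conv1 = conv_param(3L, 3L, cin, cout),
       conv2 = conv_param(3L, 3L, cout, cout),
       proj = conv_param(1L, 1L, cin, cout))
}

res_block_fwd <- function(p, x, keep_cache = FALSE) {
  a1 <- relu_fwd(conv_fwd(x, p$conv1))
  z2 <- conv_fwd(a1, p$conv2)
  s <- conv_fwd(x, p$proj, pad = 0L)
  out <- relu_fwd(z2 + s)
  list(out = out, cache = if (keep_cache) list(x = x, a1 = a1, out = out))
}

res_block_bwd <- function(p, cache, dout) {
  dpre <- relu_bwd(cache$out, dout)
  g2 <- conv_bwd(cache$a1, p$conv2, dpre)
  da1 <- relu_bwd(cache$a1, g2$dX)
  g1 <- conv_bwd(cache$x, p$conv1, da1)
  gp <- conv_bwd(cache$x, p$proj, dpre, pad = 0L)
  list(grads = list(conv1 = list(W = g1$dW, b = g1$db),
                    conv2 = list(W = g2$dW, b = g2$db),
                    proj = list(W = gp$dW, b = gp$db)),
       dx = g1$dX + gp$dX)
}

unet_init <- function(cfg) {
  L <- cfg$levels
  f <- cfg$base_filters
  ch <- f * 2^(seq_len(L) - 1)
  enc <- vector("list", L)
  cin <- 1L
  for (l in seq_len(L)) {
    enc[[l]] <- res_block_param(cin, ch[l])
    cin <- ch[l]
  }
  bott <- res_block_param(ch[L], f * 2^L)
  dec <- vector("list", L)
  above <- f * 2^L
  for (l in rev(seq_len(L))) {
    dec[[l]] <- res_block_param(above + ch[l], ch[l])
    above <- ch[l]
  }
  list(enc = enc, bott = bott, dec = dec,
       head = conv_param(1L, 1L, ch[1], cfg$n_classes))
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

unet_forward <- function(params, x, keep_cache = FALSE) {
  L <- length(params$enc)
  cache <- list(enc = vector("list", L), pool = vector("list", L),
                dec = vector("list", L), cat_dims = vector("list", L))
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    e <- res_block_fwd(params$enc[[l]], x, keep_cache)
    skips[[l]] <- e$out
    cache$enc[[l]] <- e$cache
    p <- maxpool2_fwd(e$out)
    cache$pool[[l]] <- list(idx = p$idx, dims = dim(e$out))
    x <- p$Y
  }
  b <- res_block_fwd(params$bott, x, keep_cache)
  cache$bott <- b$cache
  up <- b$out
  for (l in rev(seq_len(L))) {
    u <- upsample2_fwd(up)
    ct <- cat_channels(u, skips[[l]])
    cache$cat_dims[[l]] <- c(dim(u)[3], dim(skips[[l]])[3])
    d <- res_block_fwd(params$dec[[l]], ct, keep_cache)
    cache$dec[[l]] <- d$cache
    up <- d$out
  }
  logits <- conv_fwd(up, params$head, pad = 0L)
  probs <- softmax_channels(logits)
  cache$up <- up
  list(probs = probs, cache = if (keep_cache) cache)
}

unet_backward <- function(params, cache, dlogits) {
  L <- length(params$enc)
  grads <- list(enc = vector("list", L), dec = vector("list", L))
  gh <- conv_bwd(cache$up, params$head, dlogits, pad = 0L)
  grads$head <- list(W = gh$dW, b = gh$db)
  dup <- gh$dX
  dskips <- vector("list", L)
  for (l in seq_len(L)) {              # decoder blocks, shallowest first
    bb <- res_block_bwd(params$dec[[l]], cache$dec[[l]], dup)
    grads$dec[[l]] <- bb$grads
    cu <- cache$cat_dims[[l]][1]
    du <- bb$dx[, , seq_len(cu), , drop = FALSE]
    dskips[[l]] <- bb$dx[, , cu + seq_len(cache$cat_dims[[l]][2]), ,
                         drop = FALSE]
    dup <- upsample2_bwd(du)
  }
  bb <- res_block_bwd(params$bott, cache$bott, dup)
  grads$bott <- bb$grads
  dpool <- bb$dx
  for (l in rev(seq_len(L))) {
    de <- maxpool2_bwd(cache$pool[[l]]$idx, dpool,
                       as.integer(cache$pool[[l]]$dims))
    de <- de + dskips[[l]]
    bb <- res_block_bwd(params$enc[[l]], cache$enc[[l]], de)
    grads$enc[[l]] <- bb$grads
    dpool <- bb$dx
  }
  grads
}

seg_loss_grad <- function(probs, target, cfg) {
  # combined soft-dice + cross-entropy on softmax probabilities;
  # returns loss components and the gradient w.r.t. the logits
  d <- dim(probs)
  npix <- d[1] * d[2] * d[4]
  eps <- 1e-7
  # cross-entropy via the softmax shortcut: dCE/dlogits = (P - T)/npix is
  # exact and bounded, where a dLoss/dP formulation would blow up as P -> 0
  ce <- -sum(target * log(pmax(probs, 1e-12))) / npix
  gP <- array(0, dim = d)        # dice part of dLoss/dP, through softmax
  dice_sum <- 0
  for (c in seq_len(d[3])) {
    pc <- probs[, , c, , drop = FALSE]
    tc <- target[, , c, , drop = FALSE]
    A <- sum(pc * tc)
    B <- sum(pc) + sum(tc) + eps
    dice_sum <- dice_sum + 2 * A / B
    gP[, , c, ] <- -(2 * tc * B - 2 * A) / B^2 / d[3]
  }
  dice_loss <- 1 - dice_sum / d[3]
  # softmax jacobian: dz = P * (g - sum_k g_k P_k)
  inner <- array(0, dim = c(d[1], d[2], 1, d[4]))
  for (c in seq_len(d[3]))
    inner <- inner + gP[, , c, , drop = FALSE] * probs[, , c, , drop = FALSE]
  dz <- array(0, dim = d)
  for (c in seq_len(d[3]))
    dz[, , c, ] <- cfg$dice_weight * probs[, , c, , drop = FALSE] *
      (gP[, , c, , drop = FALSE] - inner) +
      cfg$ce_weight * (probs[, , c, , drop = FALSE] -
                         target[, , c, , drop = FALSE]) / npix
  list(loss = cfg$ce_weight * ce + cfg$dice_weight * dice_loss,
       ce = ce, dice_loss = dice_loss, dz = dz)
}

seg_internal_size <- function(h0, w0, cfg) {
  m <- 2^cfg$levels
  hs <- round(h0 * cfg$input_scale)
  ws <- round(w0 * cfg$input_scale)
  c(hs = hs, ws = ws,
    hp = as.integer(ceiling(hs / m) * m), wp = as.integer(ceiling(ws / m) * m))
}

seg_prepare_frame <- function(frame, norm, cfg) {
  sz <- seg_internal_size(nrow(frame), ncol(frame), cfg)
  x <- (resize_matrix(frame, sz["hs"], sz["ws"]) - norm$mean) / norm$sd
  # pad bottom/right after uniform scaling, so the aspect ratio is untouched
  pad <- (stats::median(frame) - norm$mean) / norm$sd
  out <- matrix(pad, sz["hp"], sz["wp"])
  out[seq_len(sz["hs"]), seq_len(sz["ws"])] <- x
  out
}

mask_to_onehot <- function(mask, hp, wp, hs, ws, n_classes) {
  m <- resize_matrix_nearest(mask, hs, ws)
  full <- matrix(0L, hp, wp)     # padding is background
  full[seq_len(hs), seq_len(ws)] <- m
  oh <- array(0, dim = c(hp, wp, n_classes, 1L))
  for (c in seq_len(n_classes)) oh[, , c, 1] <- (full == c - 1L) * 1
  oh
}

resize_matrix_nearest <- function(m, h, w) {
  if (nrow(m) == h && ncol(m) == w) return(m)
  ri <- pmin(nrow(m), pmax(1L, round((seq_len(h) - 0.5) * nrow(m) / h + 0.5)))
  ci <- pmin(ncol(m), pmax(1L, round((seq_len(w) - 0.5) * ncol(m) / w + 0.5)))
  m[ri, ci, drop = FALSE]
}

#' Train the abdomen/feet segmenter
#'
#' @param frames List of numeric matrices.
#' @param masks List of integer class-code matrices (0/1/2).
#' @param config Overrides of `segmenter_config_default()` (levels, base
#'   filters, internal scale, loss weights, epochs...).
#' @param seed Integer seed.
#' @return A `seg_model` with embedded norm stats and config, plus the
#'   per-epoch training `history` (combined, cross-entropy and dice loss).
#' @export
train_segmenter <- function(frames, masks, config = list(), seed = 1L) {
  cfg <- utils::modifyList(segmenter_config_default(), config)
  if (length(frames) == 0) stop("empty dataset")
  present <- sort(unique(unlist(lapply(masks, unique))))
  if (!all(0:2 %in% present))
    warning("training masks are missing at least one class entirely")
  norm <- compute_norm_stats(frames)
  h0 <- nrow(frames[[1]]); w0 <- ncol(frames[[1]])
  sz <- seg_internal_size(h0, w0, cfg)
  xs <- lapply(frames, seg_prepare_frame, norm = norm, cfg = cfg)
  ts <- lapply(masks, mask_to_onehot, hp = sz["hp"], wp = sz["wp"],
               hs = sz["hs"], ws = sz["ws"], n_classes = cfg$n_classes)
  with_seed(seed, {
    params <- unet_init(cfg)
    opt <- adam_init(params)
    n <- length(xs)
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          ce = numeric(0), dice_loss = numeric(0))
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      tot <- c(loss = 0, ce = 0, dice = 0)
      nb <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(n, start + cfg$batch_size - 1)]
        x <- frames_to_batch(xs[idx])
        y <- array(0, dim = c(sz["hp"], sz["wp"], cfg$n_classes, length(idx)))
        for (j in seq_along(idx)) y[, , , j] <- ts[[idx[j]]][, , , 1]
        fw <- unet_forward(params, x, keep_cache = TRUE)
        lg <- seg_loss_grad(fw$probs, y, cfg)
        grads <- unet_backward(params, fw$cache, lg$dz)
        step <- adam_step(params, grads, opt, lr = cfg$lr)
        params <- step$params
        opt <- step$state
        tot <- tot + c(lg$loss, lg$ce, lg$dice_loss)
        nb <- nb + 1
      }
      history <- rbind(history, data.frame(
        epoch = ep, loss = tot[1] / nb, ce = tot[2] / nb,
        dice_loss = tot[3] / nb))
    }
    structure(list(params = params, norm = norm, config = cfg,
                   history = history),
              class = "seg_model")
  })
}

#' Segment one frame into abdomen / feet / background
#'
#' A foreground pixel keeps its argmax class only when that class probability
#' reaches `prob_cutoff`; weakly predicted pixels fall back to background.
#' Raising the cutoff therefore never grows a foreground region.
#'
#' @param model A trained `seg_model`.
#' @param frame Numeric matrix.
#' @param prob_cutoff Probability cutoff (default from the model config, 0.5).
#' @param return_probs Also return the class-probability array.
#' @return Integer class-code matrix (and `probs` when requested).
#' @export
segment_frame <- function(model, frame, prob_cutoff = NULL,
                          return_probs = FALSE) {
  stopifnot(inherits(model, "seg_model"))
  cfg <- model$config
  if (is.null(prob_cutoff)) prob_cutoff <- cfg$prob_cutoff
  h0 <- nrow(frame); w0 <- ncol(frame)
  sz <- seg_internal_size(h0, w0, cfg)
  x <- seg_prepare_frame(frame, model$norm, cfg)
  pr <- unet_forward(model$params,
                     array(x, c(nrow(x), ncol(x), 1L, 1L)))$probs
  probs <- array(0, dim = c(h0, w0, cfg$n_classes))
  for (c in seq_len(cfg$n_classes))
    probs[, , c] <- resize_matrix(pr[seq_len(sz["hs"]), seq_len(sz["ws"]),
                                     c, 1],
                                  h0, w0)
  # renormalize after interpolation
  s <- probs[, , 1]
  for (c in 2:cfg$n_classes) s <- s + probs[, , c]
  for (c in seq_len(cfg$n_classes)) probs[, , c] <- probs[, , c] / s
  cls <- apply(probs, c(1, 2), which.max) - 1L
  pmax_fg <- matrix(0, h0, w0)
  for (c in 2:cfg$n_classes) {
    sel <- cls == (c - 1L)
    pmax_fg[sel] <- probs[, , c][sel]
  }
  cls[cls > 0 & pmax_fg < prob_cutoff] <- 0L
  if (return_probs) list(mask = cls, probs = probs) else cls
}

#' Modal intensity of a segmented region
#'
#' Intensities are binned at `bin_width` (default 1, the native integer
#' sensor level); the most populated bin wins, ties going to the lower bin,
#' and the region's representative intensity is the mean of the raw values in
#' the winning bin (for integer data this is exactly the modal value).
#'
#' @param frame Numeric matrix.
#' @param mask Integer class-code matrix.
#' @param region Class code (1 abdomen, 2 feet).
#' @param bin_width Bin width in intensity units.
#' @return Modal intensity, or `NA` for an empty region.
#' @export
region_mode_intensity <- function(frame, mask, region, bin_width = 1) {
  v <- frame[mask == region]
  if (length(v) == 0) return(NA_real_)
  b <- floor(v / bin_width)
  tab <- table(b)
  win <- as.numeric(names(tab)[which.max(tab)])  # table is sorted: tie -> lower
  mean(v[b == win])
}

#' Center-to-peripheral difference, percent
#'
#' `(A - F) / A * 100`: the difference is divided by the abdomen value so the
#' measure is a relative gradient, invariant to global intensity gain.
#'
#' @param abdomen_intensity,foot_intensity Region intensities.
#' @return CPD percent, or `NA` when the abdomen intensity is not positive.
#' @export
compute_cpd <- function(abdomen_intensity, foot_intensity) {
  ifelse(is.na(abdomen_intensity) | is.na(foot_intensity) |
           abdomen_intensity <= 0,
         NA_real_,
         (abdomen_intensity - foot_intensity) / abdomen_intensity * 100)
}

#' Extract the 1-Hz CPD series from a session's frames
#'
#' One sample per uncovered frame; covered or no-patient frames yield no
#' sample. Regions smaller than `min_region` pixels give `valid = FALSE`
#' (guards the stability of the mode).
#'
#' @param frames List of numeric matrices (already person-masked if needed).
#' @param timestamps Numeric seconds, one per frame.
#' @param screen data.frame from [screen_frames()] (or any frame with an
#'   `is_uncovered` column aligned to `frames`); `NULL` treats all frames as
#'   uncovered.
#' @param masks List of ground-truth class-code matrices, or `NULL` to
#'   segment with `model`.
#' @param model A `seg_model`, used when `masks` is `NULL`.
#' @param min_region Minimum region size in pixels for a valid sample.
#' @param bin_width Intensity bin width for the region mode.
#' @param prob_cutoff Passed to [segment_frame()].
#' @return data.frame: `timestamp`, `abdomen_intensity`, `foot_intensity`,
#'   `cpd`, `valid`.
#' @export
extract_cpd_series <- function(frames, timestamps = seq_along(frames) - 1,
                               screen = NULL, masks = NULL, model = NULL,
                               min_region = 10L, bin_width = 1,
                               prob_cutoff = NULL) {
  stopifnot(!is.null(masks) || !is.null(model))
  uncovered <- if (is.null(screen)) rep(TRUE, length(frames))
               else screen$is_uncovered
  rows <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    if (!isTRUE(uncovered[i])) next
    m <- if (!is.null(masks)) masks[[i]]
         else segment_frame(model, frames[[i]], prob_cutoff)
    na <- sum(m == 1L); nf <- sum(m == 2L)
    a <- if (na >= min_region)
      region_mode_intensity(frames[[i]], m, 1L, bin_width) else NA_real_
    f <- if (nf >= min_region)
      region_mode_intensity(frames[[i]], m, 2L, bin_width) else NA_real_
    cpd <- compute_cpd(a, f)
    rows[[i]] <- data.frame(timestamp = timestamps[i],
                            abdomen_intensity = a, foot_intensity = f,
                            cpd = cpd, valid = !is.na(cpd))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(timestamp = numeric(0), abdomen_intensity = numeric(0),
                      foot_intensity = numeric(0), cpd = numeric(0),
                      valid = logical(0))
  rownames(out) <- NULL
  out
}
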