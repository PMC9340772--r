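#' Person detection and non-patient masking
#'
#' Caregivers entering the camera field would corrupt CPD extraction. An
#' anchor-free single-class detector scores per-pixel person probability with
#' a small convolutional net; connected components above a pixel threshold
#' become candidate boxes whose confidence is the mean component probability.
#' Candidates are confidence-filtered (default 0.4) and non-max-suppressed;
#' the largest-area box is kept as the patient and all other boxes are masked
#' to a background fill value.
#'
#' @name person_mask
NULL

#' Intersection over union of two boxes
#'
#' Boxes are 0-based half-open: `[x0, x1) x [y0, y1)`.
#'
#' @param a,b Lists or one-row data.frames with `x0`, `y0`, `x1`, `y1`.
#' @return IoU in `[0, 1]`; 0 for disjoint boxes.
#' @export
box_iou <- function(a, b) {
  stopifnot(a$x0 < a$x1, a$y0 < a$y1, b$x0 < b$x1, b$y0 < b$y1)
  iw <- max(0, min(a$x1, b$x1) - max(a$x0, b$x0))
  ih <- max(0, min(a$y1, b$y1) - max(a$y0, b$y0))
  inter <- iw * ih
  union <- (a$x1 - a$x0) * (a$y1 - a$y0) + (b$x1 - b$x0) * (b$y1 - b$y0) - inter
  inter / union
}

#' Greedy non-maximum suppression
#'
#' @param boxes data.frame with box coords and `confidence`.
#' @param iou_threshold Suppress any box with IoU above this against an
#'   already-kept higher-confidence box.
#' @return The retained rows of `boxes`.
#' @export
nms_boxes <- function(boxes, iou_threshold = 0.5) {
  if (nrow(boxes) <= 1) return(boxes)
  ord <- order(-boxes$confidence)
  keep <- logical(nrow(boxes))
  for (i in ord) {
    ok <- TRUE
    for (j in which(keep))
      if (box_iou(boxes[i, ], boxes[j, ]) > iou_threshold) { ok <- FALSE; break }
    keep[i] <- ok
  }
  boxes[keep, , drop = FALSE]
}

detector_config_default <- function() {
  list(input_scale = 0.5, filters = c(8L, 16L), lr = 2e-3, epochs = 6L,
       batch_size = 8L, pixel_threshold = 0.5, min_area = 40L,
       nms_iou = 0.5)
}

det_init <- function(cfg) {
  list(c1 = conv_param(3L, 3L, 1L, cfg$filters[1]),
       c2 = conv_param(3L, 3L, cfg$filters[1], cfg$filters[2]),
       head = conv_param(1L, 1L, cfg$filters[2], 1L))
}

det_forward <- function(params, x, keep_cache = FALSE) {
  a1 <- relu_fwd(conv_fwd(x, params$c1))
  a2 <- relu_fwd(conv_fwd(a1, params$c2))
  z <- conv_fwd(x = a2, p = params$head, pad = 0L)
  p <- sigmoid(z)
  list(prob = p,
       cache = if (keep_cache) list(x = x, a1 = a1, a2 = a2))
}

det_backward <- function(params, cache, dz) {
  gh <- conv_bwd(cache$a2, params$head, dz, pad = 0L)
  da2 <- relu_bwd(cache$a2, gh$dX)
  g2 <- conv_bwd(cache$a1, params$c2, da2)
  da1 <- relu_bwd(cache$a1, g2$dX)
  g1 <- conv_bwd(cache$x, params$c1, da1)
  list(c1 = list(W = g1$dW, b = g1$db),
       c2 = list(W = g2$dW, b = g2$db),
       head = list(W = gh$dW, b = gh$db))
}

boxes_to_target <- function(boxes, h, w) {
  # filled-rectangle person map from 0-based half-open boxes
  m <- matrix(0, h, w)
  if (!is.null(boxes))
    for (i in seq_len(nrow(boxes)))
      m[(boxes$y0[i] + 1):boxes$y1[i], (boxes$x0[i] + 1):boxes$x1[i]] <- 1
  m
}

#' Train the single-class person detector
#'
#' Trains the per-pixel objectness net with pixel-wise binary cross-entropy.
#' Annotations may be pixel-wise person maps (preferred: disjoint persons
#' stay separable even when their bounding rectangles overlap) or box
#' data.frames, which are filled into rectangles first.
#'
#' @param frames List of numeric matrices.
#' @param annotations List of per-frame person maps (matrices, nonzero =
#'   person) or box data.frames (0-based half-open).
#' @param config Overrides of `detector_config_default()`.
#' @param seed Integer seed.
#' @return A `det_model`.
#' @export
train_person_detector <- function(frames, annotations, config = list(),
                                  seed = 1L) {
  cfg <- utils::modifyList(detector_config_default(), config)
  if (length(frames) == 0) stop("empty dataset")
  stats <- compute_norm_stats(frames)
  h0 <- nrow(frames[[1]]); w0 <- ncol(frames[[1]])
  h <- round(h0 * cfg$input_scale); w <- round(w0 * cfg$input_scale)
  prep <- lapply(frames, function(f)
    (resize_matrix(f, h, w) - stats$mean) / stats$sd)
  targets <- lapply(annotations, function(a) {
    full <- if (is.data.frame(a)) boxes_to_target(a, h0, w0)
            else (a > 0) * 1
    resize_matrix(full, h, w)
  })
  with_seed(seed, {
    params <- det_init(cfg)
    opt <- adam_init(params)
    n <- length(prep)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(n, start + cfg$batch_size - 1)]
        x <- frames_to_batch(prep[idx])
        y <- frames_to_batch(targets[idx])
        fw <- det_forward(params, x, keep_cache = TRUE)
        dz <- (fw$prob - y) / length(fw$prob)
        grads <- det_backward(params, fw$cache, dz)
        step <- adam_step(params, grads, opt, lr = cfg$lr)
        params <- step$params
        opt <- step$state
      }
    }
    structure(list(params = params, norm = stats, config = cfg,
                   trained = TRUE),
              class = "det_model")
  })
}

#' Detect persons in a thermal frame
#'
#' @param frame Numeric matrix.
#' @param model A trained `det_model`.
#' @param conf_threshold Keep detections with confidence at or above this
#'   (default 0.4).
#' @return data.frame of boxes (`x0`, `y0`, `x1`, `y1`, `confidence`,
#'   `class_id`), confidence-filtered and non-max-suppressed; zero rows when
#'   nothing is found.
#' @export
detect_persons <- function(frame, model, conf_threshold = 0.4) {
  if (!inherits(model, "det_model") || !isTRUE(model$trained))
    stop("detector has not been trained")
  cfg <- model$config
  h0 <- nrow(frame); w0 <- ncol(frame)
  h <- round(h0 * cfg$input_scale); w <- round(w0 * cfg$input_scale)
  x <- (resize_matrix(frame, h, w) - model$norm$mean) / model$norm$sd
  p <- det_forward(model$params, array(x, c(h, w, 1L, 1L)))$prob[, , 1, 1]
  pfull <- resize_matrix(p, h0, w0)
  # orientation is irrelevant for connectivity; labels come back in the same
  # (row, col) layout they went in
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(
    (pfull >= cfg$pixel_threshold) * 1)))
  empty <- data.frame(x0 = integer(0), y0 = integer(0), x1 = integer(0),
                      y1 = integer(0), confidence = numeric(0),
                      class_id = integer(0))
  ncomp <- max(lab)
  if (ncomp == 0) return(empty)
  out <- empty
  for (k in seq_len(ncomp)) {
    sel <- lab == k
    if (sum(sel) < cfg$min_area) next
    idx <- which(sel, arr.ind = TRUE)
    out <- rbind(out, data.frame(
      x0 = min(idx[, 2]) - 1L, y0 = min(idx[, 1]) - 1L,
      x1 = max(idx[, 2]), y1 = max(idx[, 1]),
      confidence = mean(pfull[sel]), class_id = 0L))
  }
  out <- out[out$confidence >= conf_threshold, , drop = FALSE]
  nms_boxes(out, cfg$nms_iou)
}

#' Keep the largest-area box as the patient
#'
#' Ties are broken by higher confidence, then by lowest `(y0, x0)`.
#'
#' @param boxes data.frame of detections.
#' @return The selected row, or `NULL` for an empty input (no-patient frame,
#'   skipped downstream).
#' @export
select_patient_box <- function(boxes) {
  if (is.null(boxes) || nrow(boxes) == 0) return(NULL)
  area <- (boxes$x1 - boxes$x0) * (boxes$y1 - boxes$y0)
  ord <- order(-area, -boxes$confidence, boxes$y0, boxes$x0)
  boxes[ord[1], , drop = FALSE]
}

#' Mask every non-patient box to a background fill value
#'
#' Pixels inside the patient box always win: where a non-patient box overlaps
#' the patient box, the overlap is preserved so no patient signal is lost.
#'
#' @param frame Numeric matrix.
#' @param patient_box One-row data.frame (or `NULL` to mask all boxes).
#' @param other_boxes data.frame of boxes to mask.
#' @param fill Fill value (typically the scene background intensity).
#' @return The masked frame.
#' @export
mask_non_patient <- function(frame, patient_box, other_boxes, fill) {
  if (is.null(other_boxes) || nrow(other_boxes) == 0) return(frame)
  h <- nrow(frame); w <- ncol(frame)
  inmask <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(other_boxes))) {
    b <- other_boxes[i, ]
    x0 <- max(0L, b$x0); y0 <- max(0L, b$y0)
    x1 <- min(w, b$x1); y1 <- min(h, b$y1)
    if (x1 > x0 && y1 > y0)
      inmask[(y0 + 1):y1, (x0 + 1):x1] <- TRUE
  }
  if (!is.null(patient_box)) {
    b <- patient_box
    x0 <- max(0L, b$x0); y0 <- max(0L, b$y0)
    x1 <- min(w, b$x1); y1 <- min(h, b$y1)
    if (x1 > x0 && y1 > y0)
      inmask[(y0 + 1):y1, (x0 + 1):x1] <- FALSE
  }
  frame[inmask] <- fill
  frame
}
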