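test_that("dice coefficient matches hand counts and the brute-force oracle", {
  a <- matrix(0L, 4, 4); b <- matrix(0L, 4, 4)
  expect_equal(dice_coefficient(a, b), 1)            # identical -> 1
  a2 <- matrix(c(1L, 1L, 0L, 0L), 1); b2 <- matrix(c(1L, 0L, 0L, 0L), 1)
  d <- dice_coefficient(a2, b2, classes = 1, per_class = TRUE)
  expect_equal(unname(d), 2 / 3)                     # 2*1/(2+1)
  # disjoint foreground -> 0 for that class
  expect_equal(unname(dice_coefficient(matrix(c(1L, 0L), 1),
                                       matrix(c(0L, 1L), 1),
                                       classes = 1, per_class = TRUE)), 0)
  expect_error(dice_coefficient(matrix(0L, 2, 2), matrix(0L, 3, 3)), "shape")
  oracle <- function(p, t, classes = 0:2) {
    per <- c()
    for (k in classes) {
      inter <- 0; np <- 0; nt <- 0
      for (i in seq_along(p)) {
        np <- np + (p[i] == k); nt <- nt + (t[i] == k)
        inter <- inter + (p[i] == k && t[i] == k)
      }
      if (np + nt > 0) per <- c(per, 2 * inter / (np + nt))
    }
    mean(per)
  }
  set.seed(50)
  for (trial in 1:500) {
    p <- matrix(sample(0:2, 256, TRUE), 16)
    t <- matrix(sample(0:2, 256, TRUE), 16)
    expect_equal(dice_coefficient(p, t), oracle(p, t))
  }
})

test_that("CPD formula: printed examples, zero gradient, scale invariance", {
  expect_equal(compute_cpd(100, 80), 20)
  expect_equal(compute_cpd(57, 57), 0)
  a <- 173.2; f <- 141.7
  for (c in c(0.5, 2, 17.3))
    expect_equal(compute_cpd(c * a, c * f), compute_cpd(a, f))
  expect_true(is.na(compute_cpd(0, 10)))
  expect_true(is.na(compute_cpd(-5, 10)))
  # sign follows the gradient direction
  expect_lt(compute_cpd(100, 120), 0)
})

test_that("region mode uses binned intensities with lower-bin ties", {
  f <- matrix(c(3, 3, 4, 9), 2)
  m <- matrix(c(1L, 1L, 1L, 0L), 2)
  expect_equal(region_mode_intensity(f, m, 1), 3)
  f2 <- matrix(c(10, 10, 12, 12), 2); m2 <- matrix(1L, 2, 2)
  expect_equal(region_mode_intensity(f2, m2, 1), 10)   # tie -> lower
  fc <- matrix(187.326, 3, 3)
  expect_equal(region_mode_intensity(fc, matrix(1L, 3, 3), 1), 187.326)
  expect_true(is.na(region_mode_intensity(f, m, 2)))   # empty region
})

test_that("ground-truth-mask CPD recovers planted gradients exactly", {
  nl <- fx_noiseless_set()
  cpd <- extract_cpd_series(nl$frames, masks = nl$masks)
  expect_equal(nrow(cpd), length(nl$frames))
  expect_true(all(cpd$valid))
  expect_equal(cpd$cpd, nl$planted_cpd, tolerance = 1e-12)
})

test_that("covered frames yield no CPD sample", {
  s <- fx_train_set()
  screen <- data.frame(frame_id = seq_along(s$frames),
                       p_uncovered = 1 - s$covered,
                       is_uncovered = !s$covered)
  cpd <- extract_cpd_series(s$frames, screen = screen, masks = s$masks)
  expect_equal(nrow(cpd), sum(!s$covered))
  all_cov <- screen; all_cov$is_uncovered <- FALSE
  expect_equal(nrow(extract_cpd_series(s$frames, screen = all_cov,
                                       masks = s$masks)), 0)
})

test_that("tiny regions are dropped as invalid", {
  f <- matrix(100, 8, 8)
  m <- matrix(0L, 8, 8); m[1:2, 1] <- 1L; m[5:8, 5:8] <- 2L
  cpd <- extract_cpd_series(list(f), masks = list(m), min_region = 10)
  expect_false(cpd$valid[1])
})

test_that("probability cutoff thresholds the segmentation monotonically", {
  sm <- fx_seg_model()
  f <- fx_heldout_uncov()$frames[[1]]
  m0 <- segment_frame(sm, f, prob_cutoff = 0)
  m5 <- segment_frame(sm, f, prob_cutoff = 0.5)
  m9 <- segment_frame(sm, f, prob_cutoff = 0.999)
  m1 <- segment_frame(sm, f, prob_cutoff = 1)
  expect_true(all(m1 == 0L))                         # cutoff 1 -> background
  for (k in 1:2) {
    expect_true(all(which(m5 == k) %in% which(m0 == k)))
    expect_true(all(which(m9 == k) %in% which(m5 == k)))
  }
  # cutoff 0 is pure argmax
  pr <- segment_frame(sm, f, prob_cutoff = 0, return_probs = TRUE)
  expect_equal(pr$mask, apply(pr$probs, c(1, 2), which.max) - 1L)
})

test_that("segmenter memorizes a single frame", {
  s <- fx_train_uncov()
  sm1 <- train_segmenter(s$frames[1], s$masks[1],
                         config = list(levels = 2L, base_filters = 8L,
                                       input_scale = 0.25, epochs = 80L,
                                       batch_size = 1L, lr = 5e-3),
                         seed = 2)
  expect_lt(tail(sm1$history$loss, 1), 0.25)
  expect_gt(dice_coefficient(segment_frame(sm1, s$frames[[1]]), s$masks[[1]]),
            0.9)
})

test_that("segmenter training is reproducible under a fixed seed", {
  s <- fx_train_uncov()
  cfg <- list(levels = 2L, base_filters = 2L, input_scale = 0.25, epochs = 1L)
  h1 <- train_segmenter(s$frames[1:8], s$masks[1:8], cfg, seed = 3)$history
  h2 <- train_segmenter(s$frames[1:8], s$masks[1:8], cfg, seed = 3)$history
  expect_identical(h1, h2)
})

test_that("missing-class training data triggers a warning", {
  s <- fx_train_uncov()
  bg_only <- lapply(s$masks[1:2], function(m) m * 0L)
  expect_warning(train_segmenter(s$frames[1:2], bg_only,
                                 config = list(levels = 2L,
                                               base_filters = 2L,
                                               input_scale = 0.25,
                                               epochs = 1L),
                                 seed = 1),
                 "missing at least one class")
})
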