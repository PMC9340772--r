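test_that("heart-rate imputation follows the 10% rule exactly", {
  expect_equal(impute_heart_rate(c(100, NA, 110), max_missing = 0.5),
               c(100, 105, 110))     # linear midpoint
  x <- rnorm(256, 120, 5)
  x[sample(256, 30)] <- NA                 # 11.7% missing
  expect_null(impute_heart_rate(x))
  x2 <- rnorm(256); x2[sample(256, 25)] <- NA   # 9.8% -> accepted
  expect_false(is.null(impute_heart_rate(x2)))
  expect_null(impute_heart_rate(rep(NA_real_, 10)))
  # affine signals with interior gaps are recovered exactly
  ramp <- 100 + 0.5 * (0:99)
  gappy <- ramp; gappy[c(10:12, 50, 80:83)] <- NA
  expect_equal(impute_heart_rate(gappy), ramp)
  # edge gaps take the nearest observed value; observed values unchanged
  e <- c(NA, NA, 5, 7, NA)
  expect_equal(impute_heart_rate(e, max_missing = 0.7), c(5, 5, 5, 7, 7))
})

test_that("window offsets match the stated emission rule", {
  expect_equal(window_offsets(256), 0L)
  expect_equal(window_offsets(100), 0L)
  expect_equal(window_offsets(300), c(0L, 44L))
  expect_equal(window_offsets(63), integer(0))
  # independent enumeration oracle over every length 64..1000
  oracle <- function(n, L = 256, s = 128) {
    if (n < 64) return(integer(0))
    if (n <= L) return(0L)
    st <- c()
    k <- 0
    while (k + L <= n) { st <- c(st, k); k <- k + s }
    if (!((n - L) %in% st)) st <- c(st, n - L)
    as.integer(st)
  }
  for (n in 64:1000)
    expect_identical(window_offsets(n), oracle(n))
})

test_that("windows are padded at the start with a contiguous mask", {
  w1 <- make_windows(rnorm(256, 10), rnorm(256, 120))
  expect_length(w1, 1)
  expect_equal(w1[[1]]$pad_count, 0)
  w2 <- make_windows(rnorm(100, 10), rnorm(100, 120))
  expect_equal(w2[[1]]$pad_count, 156)
  expect_equal(w2[[1]]$padding_mask, c(rep(FALSE, 156), rep(TRUE, 100)))
  expect_true(all(w2[[1]]$features[1:156, ] == 0))
  # windows never cross the segment boundary; union covers the segment
  n <- 700
  ts <- 100 + (0:(n - 1))
  ws <- make_windows(rnorm(n, 10), rnorm(n, 120), ts)
  covered <- logical(n)
  for (w in ws) {
    obs <- sum(w$padding_mask)
    t_end <- w$t0
    expect_true(t_end <= ts[n])
    covered[match(t_end, ts) - obs + seq_len(obs) - 0] <- TRUE
  }
  expect_true(all(covered))
})

test_that("windows failing heart-rate imputation are dropped", {
  hr <- rnorm(256, 120); hr[1:40] <- NA
  expect_length(make_windows(rnorm(256), hr), 0)
})

test_that("labels attach per lead and missing leads drop windows", {
  cpd <- data.frame(timestamp = 0:599, abdomen_intensity = 1,
                    foot_intensity = 1, cpd = rnorm(600, 8), valid = TRUE)
  vit <- data.frame(timestamp = seq(0, 4 * 3600, by = 15))
  vit$heart_rate <- 120; vit$arterial_systolic_bp <- 100
  vit$age_months <- 100
  labels <- binarize_shock_index(
    shock_index_series(vit), vit$timestamp, 100)
  ws <- attach_labels(build_windows(cpd, vit, "A"), labels, leads = 0:6)
  expect_s3_class(ws, "window_set")
  # constant-shock stream: labeled shock wherever the stream covers the lead
  expect_true(all(ws$labels_by_lead[, "lead_0"] == 1))
  expect_true(all(ws$labels_by_lead[, "lead_4"] == 1, na.rm = TRUE))
  # stream ends at 4 h: lead 6 has no labels, lead 0 has all
  expect_true(all(is.na(ws$labels_by_lead[, "lead_6"])))
  co0 <- cohort_at_lead(ws, 0)
  co6 <- cohort_at_lead(ws, 6)
  expect_gt(dim(co0$x)[1], 0)
  expect_equal(dim(co6$x)[1], 0)
})

toy_cohort <- function(n1 = 10, n0 = 30, L = 16) {
  set.seed(42)
  n <- n1 + n0
  structure(list(
    x = array(rnorm(n * L * 2), c(n, L, 2)),
    mask = matrix(TRUE, n, L),
    label = c(rep(1L, n1), rep(0L, n0)),
    patient_id = paste0("P", rep(1:5, length.out = n)),
    t0 = seq_len(n) * 100,
    synthetic = rep(FALSE, n),
    lead = 0), class = "shock_cohort")
}

test_that("SMOTE balances class counts and flags synthetic windows", {
  co <- toy_cohort(10, 30)
  b <- smote_balance(co, seed = 1)
  expect_equal(sum(b$label == 1), sum(b$label == 0))
  expect_equal(sum(b$synthetic), 20)
  expect_true(all(!b$synthetic[1:40]))
  # already balanced: unchanged
  cob <- toy_cohort(15, 15)
  expect_identical(smote_balance(cob, seed = 1), cob)
  # observed windows are never altered
  expect_equal(b$x[1:40, , ], co$x)
})

test_that("every SMOTE sample lies on a segment between minority neighbors", {
  co <- toy_cohort(6, 40)
  b <- smote_balance(co, k = 3, seed = 2)
  flat <- matrix(co$x, 46, 32)
  mflat <- flat[co$label == 1, ]
  newflat <- matrix(b$x, dim(b$x)[1], 32)[b$synthetic, ]
  for (s in seq_len(nrow(newflat))) {
    on_segment <- FALSE
    for (i in 1:5) for (j in (i + 1):6) {
      d <- mflat[j, ] - mflat[i, ]
      v <- newflat[s, ] - mflat[i, ]
      lam <- sum(v * d) / sum(d * d)
      if (lam >= -1e-9 && lam <= 1 + 1e-9 &&
          sqrt(sum((v - lam * d)^2)) < 1e-8) on_segment <- TRUE
    }
    expect_true(on_segment)
  }
})

test_that("a minority class of one falls back to duplication with warning", {
  co <- toy_cohort(1, 9)
  expect_warning(b <- smote_balance(co, seed = 3), "duplicat")
  expect_equal(sum(b$label == 1), 9)
  expect_true(all(b$x[b$synthetic, , ] == co$x[rep(1, 8), , ]))
})
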