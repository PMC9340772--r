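#' Window cohorts for sequence classification
#'
#' CPD and heart-rate streams are cut into fixed 256-point (256 s) windows:
#' short segments are padded at the start (so the most recent physiology
#' abuts the prediction point) with the padding flagged in a mask the
#' sequence model honors; long segments are split with 50% overlap plus a
#' right-anchored final window so no trailing data are discarded. Heart rate
#' is forward-filled from the 15-s vitals grid to 1 Hz; windows missing 10%
#' or more of their heart-rate points are rejected, smaller interior gaps are
#' linearly interpolated. The training split (only) can be SMOTE-balanced.
#'
#' @name cohort_builder
NULL

#' Linear-interpolation imputation of a heart-rate window
#'
#' Accepts the series only when the missing fraction is strictly below
#' `max_missing`; interior gaps are linearly interpolated between nearest
#' observed neighbors and edge gaps take the nearest observed value.
#' Observed values are never altered.
#'
#' @param x Numeric vector with `NA` for missing.
#' @param max_missing Rejection threshold on the missing fraction (default
#'   0.10).
#' @return The imputed vector, or `NULL` when the window is rejected.
#' @export
impute_heart_rate <- function(x, max_missing = 0.10) {
  miss <- is.na(x)
  if (all(miss)) return(NULL)
  if (mean(miss) >= max_missing) return(NULL)
  if (!any(miss)) return(x)
  obs <- which(!miss)
  stats::approx(obs, x[obs], xout = seq_along(x), method = "linear",
                rule = 2)$y
}

#' Window start offsets for a segment
#'
#' The emission rule: segments shorter than `min_length` yield nothing; up to
#' `L` points yield a single (possibly padded) window; longer segments yield
#' starts at `0, stride, 2*stride, ...` while a full window fits, plus a
#' final right-anchored window ending at the segment end if not already
#' emitted. Offsets are 0-based.
#'
#' @param n Segment length in points.
#' @param L Window length (default 256).
#' @param stride Overlap stride (default 128, i.e. 50%).
#' @param min_length Minimum segment length (default 64).
#' @return Integer vector of start offsets (empty when nothing is emitted).
#' @export
window_offsets <- function(n, L = 256L, stride = 128L, min_length = 64L) {
  if (n < min_length) return(integer(0))
  if (n <= L) return(0L)
  starts <- seq(0L, n - L, by = stride)
  if (starts[length(starts)] != n - L) starts <- c(starts, n - L)
  as.integer(starts)
}

#' Cut one contiguous CPD + heart-rate segment into labeled-ready windows
#'
#' @param cpd Numeric CPD values at 1 Hz.
#' @param hr Heart rate at 1 Hz (may contain `NA`).
#' @param timestamps Seconds, one per point, consecutive.
#' @param L,stride,min_length See [window_offsets()].
#' @param max_missing Heart-rate rejection threshold per window.
#' @return List of windows: `features` (`L x 2` matrix, columns `cpd`,
#'   `heart_rate`; padded rows are zero), `padding_mask` (`L` logicals, TRUE
#'   = observed, padding contiguous at the start), `t0` (window end time),
#'   `pad_count`. Windows whose heart rate fails imputation are dropped.
#' @export
make_windows <- function(cpd, hr, timestamps = seq_along(cpd) - 1,
                         L = 256L, stride = 128L, min_length = 64L,
                         max_missing = 0.10) {
  n <- length(cpd)
  stopifnot(length(hr) == n, length(timestamps) == n)
  starts <- window_offsets(n, L, stride, min_length)
  out <- list()
  for (s in starts) {
    take <- (s + 1):min(n, s + L)
    hr_w <- impute_heart_rate(hr[take], max_missing)
    if (is.null(hr_w)) next
    k <- length(take)
    pad <- L - k
    feats <- matrix(0, L, 2, dimnames = list(NULL, c("cpd", "heart_rate")))
    feats[(pad + 1):L, 1] <- cpd[take]
    feats[(pad + 1):L, 2] <- hr_w
    out[[length(out) + 1]] <- list(
      features = feats,
      padding_mask = c(rep(FALSE, pad), rep(TRUE, k)),
      t0 = timestamps[take[k]],
      pad_count = pad)
  }
  out
}

hr_at_1hz <- function(vitals, seconds) {
  # forward-fill the 15-s grid onto a 1-Hz clock; missing ticks stay missing
  idx <- findInterval(seconds, vitals$timestamp)
  ifelse(idx >= 1, vitals$heart_rate[pmax(idx, 1L)], NA_real_)
}

contiguous_runs <- function(timestamps) {
  if (length(timestamps) == 0) return(list())
  brk <- c(0, which(diff(timestamps) != 1), length(timestamps))
  lapply(seq_len(length(brk) - 1),
         function(i) (brk[i] + 1):brk[i + 1])
}

#' Build all windows for one patient session
#'
#' Splits the valid CPD samples into contiguous 1-Hz runs, pairs them with
#' forward-filled heart rate, and cuts windows.
#'
#' @param cpd_series data.frame from [extract_cpd_series()].
#' @param vitals The session vitals (15-s grid).
#' @param patient_id Identifier carried on every window.
#' @param ... Passed to [make_windows()].
#' @return List of windows, each also carrying `patient_id`.
#' @export
build_windows <- function(cpd_series, vitals, patient_id, ...) {
  ok <- cpd_series[cpd_series$valid, , drop = FALSE]
  out <- list()
  for (run in contiguous_runs(ok$timestamp)) {
    seg <- ok[run, , drop = FALSE]
    hr <- hr_at_1hz(vitals, seg$timestamp)
    ws <- make_windows(seg$cpd, hr, seg$timestamp, ...)
    for (w in ws) {
      w$patient_id <- patient_id
      out[[length(out) + 1]] <- w
    }
  }
  out
}

#' Attach per-lead shock labels to windows
#'
#' Each window is labeled at every requested lead with the label at the grid
#' point nearest `t0 + lead` hours; windows whose label stream has ended are
#' missing at that lead (and excluded from that lead's dataset only).
#'
#' @param windows List of windows (from [build_windows()]); windows from
#'   several patients may be concatenated if each carries `patient_id` and
#'   `labels` is a named list per patient.
#' @param labels A label data.frame (single patient) or a named list of them.
#' @param leads Integer leads in hours.
#' @return A `window_set`: the windows plus a `labels_by_lead` matrix
#'   (windows x leads).
#' @export
attach_labels <- function(windows, labels, leads = 0:6) {
  lab_for <- function(pid) {
    if (is.data.frame(labels)) labels else labels[[pid]]
  }
  m <- matrix(NA_integer_, length(windows), length(leads),
              dimnames = list(NULL, paste0("lead_", leads)))
  for (i in seq_along(windows)) {
    ldf <- lab_for(windows[[i]]$patient_id)
    for (j in seq_along(leads))
      m[i, j] <- label_at_lead(ldf, windows[[i]]$t0, leads[j])
  }
  structure(list(windows = windows, labels_by_lead = m, leads = leads),
            class = "window_set")
}

#' Per-lead cohort dataset
#'
#' @param ws A `window_set`.
#' @param lead One lead hour present in `ws$leads`.
#' @return A `shock_cohort`: arrays `x` (`N x L x 2`), `mask` (`N x L`),
#'   vectors `label`, `patient_id`, `t0`, `synthetic` (all FALSE here), and
#'   the `lead`.
#' @export
cohort_at_lead <- function(ws, lead) {
  stopifnot(inherits(ws, "window_set"), lead %in% ws$leads)
  j <- match(lead, ws$leads)
  keep <- which(!is.na(ws$labels_by_lead[, j]))
  L <- if (length(ws$windows)) nrow(ws$windows[[1]]$features) else 256L
  x <- array(0, dim = c(length(keep), L, 2))
  mask <- matrix(FALSE, length(keep), L)
  for (ii in seq_along(keep)) {
    w <- ws$windows[[keep[ii]]]
    x[ii, , ] <- w$features
    mask[ii, ] <- w$padding_mask
  }
  structure(list(
    x = x, mask = mask,
    label = as.integer(ws$labels_by_lead[keep, j]),
    patient_id = vapply(ws$windows[keep], `[[`, character(1), "patient_id"),
    t0 = vapply(ws$windows[keep], `[[`, numeric(1), "t0"),
    synthetic = rep(FALSE, length(keep)),
    lead = lead), class = "shock_cohort")
}

cohort_subset <- function(cohort, idx) {
  structure(list(x = cohort$x[idx, , , drop = FALSE],
                 mask = cohort$mask[idx, , drop = FALSE],
                 label = cohort$label[idx],
                 patient_id = cohort$patient_id[idx],
                 t0 = cohort$t0[idx],
                 synthetic = cohort$synthetic[idx],
                 lead = cohort$lead), class = "shock_cohort")
}

#' SMOTE balancing of a training cohort
#'
#' Windows are flattened to feature vectors; each synthetic minority sample
#' is a uniform interpolation between a minority window and one of its `k`
#' nearest minority neighbors (k reduced to the available count). Synthetic
#' windows carry `synthetic = TRUE` and inherit the padding mask of their
#' base window; class counts are equal afterwards. Apply to the training
#' split only -- validation and test sets must stay untouched.
#'
#' @param cohort A `shock_cohort`.
#' @param k Number of nearest neighbors (default 5).
#' @param seed Integer seed.
#' @return The balanced `shock_cohort`.
#' @export
smote_balance <- function(cohort, k = 5L, seed = 1L) {
  y <- cohort$label
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == n0) return(cohort)
  minority <- if (n1 < n0) 1L else 0L
  need <- abs(n0 - n1)
  mi <- which(y == minority)
  d <- dim(cohort$x)
  flat <- matrix(cohort$x, d[1], d[2] * d[3])
  with_seed(seed, {
    if (length(mi) < 2) {
      warning("minority class has fewer than 2 members; duplicating")
      pick <- sample(mi, need, replace = TRUE)
      newx <- cohort$x[pick, , , drop = FALSE]
      newmask <- cohort$mask[pick, , drop = FALSE]
      base <- pick
    } else {
      kk <- min(k, length(mi) - 1)
      dm <- as.matrix(stats::dist(flat[mi, , drop = FALSE]))
      base <- sample(mi, need, replace = TRUE)
      newx <- array(0, dim = c(need, d[2], d[3]))
      newmask <- matrix(FALSE, need, d[2])
      for (s in seq_len(need)) {
        i <- match(base[s], mi)
        nb <- order(dm[i, ])[-1][seq_len(kk)]
        j <- nb[sample.int(kk, 1)]
        u <- stats::runif(1)
        v <- flat[mi[i], ] + u * (flat[mi[j], ] - flat[mi[i], ])
        newx[s, , ] <- array(v, dim = c(1, d[2], d[3]))
        newmask[s, ] <- cohort$mask[mi[i], ]
      }
    }
    structure(list(
      x = abind_first(cohort$x, newx),
      mask = rbind(cohort$mask, newmask),
      label = c(y, rep(minority, need)),
      patient_id = c(cohort$patient_id, cohort$patient_id[base]),
      t0 = c(cohort$t0, cohort$t0[base]),
      synthetic = c(cohort$synthetic, rep(TRUE, need)),
      lead = cohort$lead), class = "shock_cohort")
  })
}

abind_first <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1] + db[1], da[2], da[3]))
  if (da[1] > 0) out[seq_len(da[1]), , ] <- a
  if (db[1] > 0) out[da[1] + seq_len(db[1]), , ] <- b
  out
}
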