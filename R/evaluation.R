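#' Patient-wise evaluation with threshold-free and Youden-index metrics
#'
#' Patients are partitioned 60:20:20 into train/validation/test sets, never
#' sharing a patient across sets, with the shock prevalence of each set held
#' close to the global prevalence (stratified; re-drawn up to a maximum
#' number of attempts). Ten such folds give mean and standard error
#' (`sd/sqrt(k)`) for AUROC, AUPRC and the confusion metrics evaluated at
#' Youden's index.
#'
#' @name evaluation
NULL

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) form with midranks for ties; identical to
#' pairwise concordance `P(score_pos > score_neg) + 0.5 P(=)`.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise (average-precision) integral over distinct score cutpoints --
#' no trapezoidal interpolation, which would be optimistic for PR curves.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1)
  if (npos == 0 || npos == length(labels)) stop("both classes required")
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  ctp <- cumsum(y); cfp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie group
  tp <- ctp[last]; fp <- cfp[last]
  prec <- tp / (tp + fp)
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

#' Youden-optimal threshold
#'
#' Exhaustive sweep over all distinct scores as thresholds (decision:
#' predict shock iff `p >= threshold`), maximizing
#' `J = sensitivity + specificity - 1`; ties take the lower threshold.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (both classes required).
#' @return List with `threshold` and `J`.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  cand <- sort(unique(scores))
  J <- vapply(cand, function(th) {
    pred <- scores >= th
    sum(pred & labels == 1) / n1 + sum(!pred & labels == 0) / n0 - 1
  }, numeric(1))
  best <- which.max(J)                      # first max = lowest threshold
  list(threshold = cand[best], J = J[best])
}

#' Confusion-matrix metrics at a threshold, plus AUROC/AUPRC
#'
#' Prediction rule: shock iff `p >= threshold`. Ratios with zero denominators
#' are reported as `NA`, never as 0.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param threshold Decision threshold.
#' @return One-row data.frame: auprc, auroc, accuracy, sensitivity,
#'   specificity, ppv, npv, f1, youden_threshold, youden_J.
#' @export
metrics_at_threshold <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1); tn <- sum(!pred & labels == 0)
  rat <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- rat(tp, tp + fn); spec <- rat(tn, tn + fp)
  ppv <- rat(tp, tp + fp); npv <- rat(tn, tn + fn)
  f1 <- if (is.na(ppv) || is.na(sens) || (ppv + sens) == 0) NA_real_
        else 2 * ppv * sens / (ppv + sens)
  data.frame(
    auprc = auprc(scores, labels), auroc = auroc(scores, labels),
    accuracy = (tp + tn) / length(labels),
    sensitivity = sens, specificity = spec, ppv = ppv, npv = npv, f1 = f1,
    youden_threshold = threshold,
    youden_J = if (is.na(sens) || is.na(spec)) NA_real_ else sens + spec - 1)
}

#' Patient-wise stratified 60:20:20 split plan
#'
#' For each of `k` folds, patients are shuffled within prevalence strata
#' (patients above/below the median shock-window fraction), allocated
#' 60:20:20 to train/validation/test, and the draw is accepted only when the
#' window-level shock prevalence of every set is within `tol` of the global
#' prevalence (up to `max_attempts` re-draws per fold, then error).
#'
#' @param patient_id Patient id per window.
#' @param label Binary label per window.
#' @param k Number of folds.
#' @param ratios Train/validation/test fractions (sum to 1).
#' @param tol Prevalence tolerance (absolute, default 0.10).
#' @param max_attempts Re-draws per fold.
#' @param seed Integer seed.
#' @return A `split_plan`: list of folds, each with `train`, `validation`,
#'   `test` patient-id vectors.
#' @export
patient_stratified_split <- function(patient_id, label, k = 10L,
                                     ratios = c(0.6, 0.2, 0.2), tol = 0.10,
                                     max_attempts = 100L, seed = 1L) {
  stopifnot(abs(sum(ratios) - 1) < 1e-8)
  pats <- unique(patient_id)
  if (length(pats) < 5)
    stop("need at least 5 patients for a 60:20:20 patient-wise split")
  if (length(unique(label)) < 2)
    stop("both classes must be present across patients")
  prev <- vapply(pats, function(p) mean(label[patient_id == p]), numeric(1))
  global <- mean(label)
  strata <- split(pats, prev > stats::median(prev))
  np <- length(pats)
  # dealing pattern realizing the 60:20:20 ratios over a stratified order
  pattern <- rep(c(1L, 1L, 1L, 2L, 3L), length.out = np)
  with_seed(seed, {
    folds <- vector("list", k)
    for (f in seq_len(k)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        ordp <- unlist(lapply(strata, function(s)
          if (length(s) > 1) sample(s) else s), use.names = FALSE)
        pv <- function(which_set) {
          ids <- ordp[pattern == which_set]
          mean(label[patient_id %in% ids])
        }
        prevs <- c(pv(1), pv(2), pv(3))
        if (all(is.finite(prevs)) && all(abs(prevs - global) <= tol)) {
          folds[[f]] <- list(train = ordp[pattern == 1L],
                             validation = ordp[pattern == 2L],
                             test = ordp[pattern == 3L])
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not satisfy the stratification tolerance after ",
             max_attempts, " attempts")
    }
    structure(list(folds = folds, ratios = ratios, tol = tol, seed = seed),
              class = "split_plan")
  })
}

#' Cross-validated evaluation of the sequence model on a cohort
#'
#' Per fold: SMOTE-balance the training windows only, train with early
#' stopping on the validation set, score the untouched test set, and report
#' metrics at the Youden threshold of the test scores. Folds whose test set
#' collapses to one class are skipped with a warning and excluded from both
#' the mean and the SE.
#'
#' @param cohort A `shock_cohort` (one lead).
#' @param config A [seq_model_config()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed (drives the split plan, SMOTE and training).
#' @param split Optional pre-built `split_plan`.
#' @return A `metrics_report`: `per_fold` data.frame, `aggregate` (mean and
#'   `se = sd/sqrt(k_eff)` per metric), `k_effective`, `lead`.
#' @export
cross_validate <- function(cohort, config = seq_model_config(), k = 10L,
                           seed = 1L, split = NULL) {
  stopifnot(inherits(cohort, "shock_cohort"))
  if (is.null(split))
    split <- patient_stratified_split(cohort$patient_id, cohort$label,
                                      k = k, seed = seed)
  per_fold <- NULL
  for (f in seq_along(split$folds)) {
    fold <- split$folds[[f]]
    tr <- cohort_subset(cohort, which(cohort$patient_id %in% fold$train))
    va <- cohort_subset(cohort, which(cohort$patient_id %in% fold$validation))
    te <- cohort_subset(cohort, which(cohort$patient_id %in% fold$test))
    if (length(unique(te$label)) < 2 || length(unique(tr$label)) < 2) {
      warning("fold ", f, " skipped: single-class train or test set")
      next
    }
    trb <- smote_balance(tr, seed = seed + f)
    model <- with_seed(seed + 1000L + f,
                       build_seq_model(config, n_features = dim(cohort$x)[3]))
    model <- train_seq_model(model, trb,
                             validation = if (length(unique(va$label)) == 2) va,
                             seed = seed + 2000L + f)
    p <- predict_seq_model(model, te)
    yt <- youden_threshold(p, te$label)
    row <- metrics_at_threshold(p, te$label, yt$threshold)
    row$fold <- f
    per_fold <- rbind(per_fold, row)
  }
  if (is.null(per_fold)) stop("no usable folds")
  keep <- setdiff(names(per_fold), "fold")
  agg <- data.frame(metric = keep,
                    mean = vapply(keep, function(m)
                      mean(per_fold[[m]], na.rm = TRUE), numeric(1)),
                    se = vapply(keep, function(m)
                      stats::sd(per_fold[[m]], na.rm = TRUE) /
                        sqrt(sum(!is.na(per_fold[[m]]))), numeric(1)))
  rownames(agg) <- NULL
  structure(list(per_fold = per_fold, aggregate = agg,
                 k_effective = nrow(per_fold), lead = cohort$lead),
            class = "metrics_report")
}
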