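#' Shock-index labeling with age-adjusted (SIPA) cutoffs
#'
#' The shock index (SI) is the ratio of the median heart rate to the median
#' arterial systolic blood pressure over trailing windows of 30 points on the
#' 15-s vitals grid. SI is binarized with the pediatric age-adjusted (SIPA)
#' cutoff for the patient's age band; the label is 1 (shock) exactly when
#' SI strictly exceeds the cutoff. Windows are trailing (causal), never
#' centered, so labels at a time point use no future vitals.
#'
#' @name shock_label
NULL

#' Trailing-window shock-index series
#'
#' `SI(t) = median(HR over the trailing window) / median(SBP over the same
#' window)`, with missing vitals excluded from the medians. Windows shorter
#' than `window_points` at the start of the series use all available points,
#' down to a minimum of `min_points`; earlier ticks are `NA`.
#'
#' @param vitals data.frame with `timestamp` (15-s grid), `heart_rate`,
#'   `arterial_systolic_bp`.
#' @param window_points Trailing window length in points (default 30).
#' @param min_points Minimum points for a prefix window.
#' @return Numeric SI vector aligned to `vitals$timestamp` (`NA` where
#'   undefined, including a zero median SBP).
#' @export
shock_index_series <- function(vitals, window_points = 30L, min_points = 5L) {
  n <- nrow(vitals)
  si <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - window_points + 1L)
    if (i - lo + 1L < min_points) next
    hr <- stats::median(vitals$heart_rate[lo:i], na.rm = TRUE)
    bp <- stats::median(vitals$arterial_systolic_bp[lo:i], na.rm = TRUE)
    if (is.na(hr) || is.na(bp) || bp == 0) next
    si[i] <- hr / bp
  }
  si
}

default_sipa_table <- function() {
  # age bands in months -> SI cutoff; below the youngest band, the youngest
  # band's value applies
  data.frame(age_min = c(48, 84, 156), cutoff = c(1.22, 1.0, 0.9))
}

#' SIPA cutoff for an age
#'
#' Piecewise-constant cutoff from a config table (defaults: 48-83 months
#' 1.22; 84-155 months 1.0; 156 months and older 0.9; younger than the
#' youngest band, the youngest band's value).
#'
#' @param age_months Age in months (> 0).
#' @param table Optional replacement data.frame with `age_min` (ascending)
#'   and `cutoff`.
#' @return The cutoff.
#' @export
sipa_cutoff <- function(age_months, table = default_sipa_table()) {
  if (any(age_months <= 0)) stop("age_months must be positive")
  idx <- findInterval(age_months, table$age_min)
  table$cutoff[pmax(1L, idx)]
}

#' Binarize a shock-index series with the age-specific cutoff
#'
#' @param si Numeric SI series (from [shock_index_series()]).
#' @param timestamps Timestamps aligned to `si`.
#' @param age_months Patient age.
#' @param sipa_table Optional cutoff table for [sipa_cutoff()].
#' @return data.frame: `timestamp`, `shock_index`, `label` (1 iff SI strictly
#'   exceeds the cutoff; `NA` where SI is missing), `cutoff_used`.
#' @export
binarize_shock_index <- function(si, timestamps, age_months,
                                 sipa_table = default_sipa_table()) {
  cutoff <- sipa_cutoff(age_months, sipa_table)
  data.frame(timestamp = timestamps,
             shock_index = si,
             label = ifelse(is.na(si), NA_integer_,
                            as.integer(si > cutoff)),
             cutoff_used = cutoff)
}

#' Shock label at a lead time
#'
#' Returns the label at the grid point nearest to `t0 + lead_hours`, or `NA`
#' when no label lies within +/- 7.5 minutes of that time (e.g. the vitals
#' stream ended earlier) -- which is what shrinks per-lead cohorts as the
#' horizon grows.
#'
#' @param labels data.frame from [binarize_shock_index()].
#' @param t0 Anchor time (seconds, same clock as the labels).
#' @param lead_hours Integer 0-6.
#' @param max_gap_s Maximum distance to the nearest grid point (default 450).
#' @return 0/1 label or `NA`.
#' @export
label_at_lead <- function(labels, t0, lead_hours, max_gap_s = 450) {
  stopifnot(lead_hours %in% 0:6)
  target <- t0 + lead_hours * 3600
  d <- abs(labels$timestamp - target)
  i <- which.min(d)
  if (length(i) == 0 || d[i] > max_gap_s) return(NA_integer_)
  labels$label[i]
}

#' Session label stream from its vitals
#'
#' Convenience wrapper: SI series, then SIPA binarization, using the
#' session's age.
#'
#' @param session A `thermo_session`.
#' @param window_points,min_points Passed to [shock_index_series()].
#' @param sipa_table Passed to [binarize_shock_index()].
#' @return Label data.frame.
#' @export
session_labels <- function(session, window_points = 30L, min_points = 5L,
                           sipa_table = default_sipa_table()) {
  si <- shock_index_series(session$vitals, window_points, min_points)
  binarize_shock_index(si, session$vitals$timestamp, session$age_months,
                       sipa_table)
}
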