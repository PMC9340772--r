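#' End-to-end pipeline conveniences
#'
#' Helpers tying the stages together: CPD series for a session (from the
#' generator's ground truth, or through the trained vision stack on rendered
#' frames), and a multi-patient window cohort.
#'
#' @name pipeline
NULL

#' CPD series of a synthetic session
#'
#' With `screen_model`/`seg_model` supplied (and a rendered session), runs
#' the vision stack: screening, optional person masking, segmentation, CPD.
#' Without models, reads the generator's ground truth: the planted per-second
#' CPD, with covered seconds yielding no sample -- the idealized output of a
#' perfect vision stack, used to exercise the sequence stages at durations
#' where rendering every frame is not sensible.
#'
#' @param session A `thermo_session`.
#' @param screen_model,det_model,seg_model Optional trained vision models.
#' @param conf_threshold Detector confidence threshold.
#' @return data.frame as from [extract_cpd_series()].
#' @export
session_cpd_series <- function(session, screen_model = NULL,
                               det_model = NULL, seg_model = NULL,
                               conf_threshold = 0.4) {
  if (is.null(seg_model)) {
    uncov <- !session$covered_path
    return(data.frame(timestamp = session$timestamps[uncov],
                      abdomen_intensity = NA_real_,
                      foot_intensity = NA_real_,
                      cpd = session$true_cpd_path[uncov],
                      valid = TRUE))
  }
  stopifnot(!is.null(session$frames))
  frames <- session$frames
  screen <- if (!is.null(screen_model)) screen_frames(screen_model, frames)
            else data.frame(frame_id = seq_along(frames),
                            p_uncovered = 1 - session$covered_path,
                            is_uncovered = !session$covered_path)
  if (!is.null(det_model)) {
    bg <- stats::median(frames[[1]])
    frames <- lapply(seq_along(frames), function(i) {
      if (!screen$is_uncovered[i]) return(frames[[i]])
      det <- detect_persons(frames[[i]], det_model, conf_threshold)
      pat <- select_patient_box(det)
      if (is.null(pat)) return(frames[[i]])
      others <- det[!(det$x0 == pat$x0 & det$y0 == pat$y0 &
                        det$x1 == pat$x1 & det$y1 == pat$y1), , drop = FALSE]
      mask_non_patient(frames[[i]], pat, others, fill = bg)
    })
  }
  extract_cpd_series(frames, session$timestamps, screen, model = seg_model)
}

#' Build a labeled multi-patient window set
#'
#' @param sessions List of `thermo_session` objects.
#' @param leads Integer lead hours.
#' @param cpd_fn Function mapping a session to its CPD series (default
#'   [session_cpd_series()] on ground truth).
#' @param ... Passed to [build_windows()] (window length, stride...).
#' @return A `window_set` spanning all patients.
#' @export
cohort_from_sessions <- function(sessions, leads = 0:6,
                                 cpd_fn = session_cpd_series, ...) {
  windows <- list()
  labels <- list()
  for (s in sessions) {
    cpd <- cpd_fn(s)
    windows <- c(windows, build_windows(cpd, s$vitals, s$patient_id, ...))
    labels[[s$patient_id]] <- session_labels(s)
  }
  attach_labels(windows, labels, leads)
}
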