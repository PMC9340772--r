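# Shared fixtures, built once per test run. Heavy objects (trained vision
# models, the 20-patient cohort) are cached in this environment so several
# test files can reuse them.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, builder(), envir = .fx)
  get(name, envir = .fx, inherits = FALSE)
}

# --- vision-scale frame sets -------------------------------------------------

fx_train_set <- function() fx_get("train_set", function()
  render_training_set(200, covered_frac = 0.4, caregiver_frac = 0.3,
                      seed = 31))

fx_heldout_set <- function() fx_get("heldout_set", function()
  render_training_set(100, covered_frac = 0.4, caregiver_frac = 0.3,
                      seed = 32))

# uncovered-only sets for detector/segmenter work: 200 train / 50 held-out
fx_train_uncov <- function() fx_get("train_uncov", function()
  render_training_set(200, covered_frac = 0, caregiver_frac = 0.3,
                      seed = 35))

fx_heldout_uncov <- function() fx_get("heldout_uncov", function()
  render_training_set(50, covered_frac = 0, caregiver_frac = 0.3,
                      seed = 36))

fx_noiseless_set <- function() fx_get("noiseless_set", function()
  render_training_set(100, covered_frac = 0, caregiver_frac = 0,
                      noise_sd = 0, seed = 33))

# --- trained models ----------------------------------------------------------

fx_screen_model <- function() fx_get("screen_model", function() {
  s <- fx_train_set()
  train_screen_classifier(s$frames, as.integer(!s$covered), seed = 1)
})

fx_det_model <- function() fx_get("det_model", function() {
  s <- fx_train_uncov()
  train_person_detector(s$frames, s$person_maps, seed = 1)
})

fx_seg_model <- function() fx_get("seg_model", function() {
  s <- fx_train_uncov()
  train_segmenter(s$frames, s$masks, seed = 1)
})

# --- sequence-scale cohort ---------------------------------------------------

fx_sessions20 <- function() fx_get("sessions20", function()
  lapply(1:20, function(i)
    generate_session(session_config(duration_s = 7200), seed = 100 + i,
                     patient_id = sprintf("P%02d", i))))

fx_window_set <- function() fx_get("window_set", function()
  cohort_from_sessions(fx_sessions20(), leads = 0:6))

fx_cv_config <- function() seq_model_config(
  lstm_hidden = 32L, dense_sizes = 16L, epochs = 15L, patience = 5L,
  batch_size = 64L)

fx_cv_report <- function() fx_get("cv_report", function()
  cross_validate(cohort_at_lead(fx_window_set(), 0), fx_cv_config(),
                 k = 10, seed = 7))

fx_cv_report_shuffled <- function() fx_get("cv_report_shuffled", function() {
  co <- cohort_at_lead(fx_window_set(), 0)
  co$label <- with_seed_test(99, sample(co$label))
  cross_validate(co, fx_cv_config(), k = 10, seed = 7)
})

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# brute-force pixel-membership IoU oracle for integer boxes
iou_pixel_oracle <- function(a, b, lim = 32L) {
  g <- expand.grid(x = 0:(lim - 1), y = 0:(lim - 1))
  ina <- g$x >= a$x0 & g$x < a$x1 & g$y >= a$y0 & g$y < a$y1
  inb <- g$x >= b$x0 & g$x < b$x1 & g$y >= b$y0 & g$y < b$y1
  if (sum(ina | inb) == 0) return(0)
  sum(ina & inb) / sum(ina | inb)
}

rand_box <- function(lim = 20L) {
  x <- sort(sample(0:lim, 2)); y <- sort(sample(0:lim, 2))
  while (x[1] == x[2]) x <- sort(sample(0:lim, 2))
  while (y[1] == y[2]) y <- sort(sample(0:lim, 2))
  list(x0 = x[1], y0 = y[1], x1 = x[2], y1 = y[2])
}
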