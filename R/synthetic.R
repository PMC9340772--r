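#' Synthetic thermal scenes and vitals with a planted shock structure
#'
#' The generator emulates overhead thermal video of an ICU bed: a patient
#' silhouette near skin temperature on a cooler background, an abdomen region
#' warmer than two foot regions by a controlled percent gradient (the planted
#' CPD), optional blanket cover, an occasional caregiver silhouette, additive
#' sensor noise, and a linked vitals stream in which shock periods carry
#' elevated heart rate and elevated CPD. Intensities are sensor counts on a
#' nominal 0-255 scale, linear in temperature; the background default of 60
#' counts stands for the ~25 degree C ambient of the unit.
#'
#' @name synthetic_thermal
NULL

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

ellipse_spec <- function(cy, cx, ry, rx, angle = 0) {
  list(cy = cy, cx = cx, ry = ry, rx = rx, angle = angle)
}

in_ellipse <- function(rowg, colg, e) {
  dy <- rowg - e$cy
  dx <- colg - e$cx
  if (e$angle != 0) {
    a <- e$angle * pi / 180
    r <- dy * cos(a) - dx * sin(a)
    c <- dy * sin(a) + dx * cos(a)
    dy <- r; dx <- c
  }
  (dy / e$ry)^2 + (dx / e$rx)^2 <= 1
}

#' Scene parameters for a single synthetic thermal frame
#'
#' Geometry defaults scale with the frame so any resolution works; the default
#' 156 x 206 frame matches the sensor grid of a compact smartphone thermal
#' camera. Foot intensity is never a free parameter: it is derived from the
#' abdomen intensity and the planted CPD so that the CPD formula applied to
#' ground-truth regions recovers `planted_cpd` exactly on noiseless frames.
#'
#' @param frame_height,frame_width Frame size in pixels.
#' @param background_intensity Background level, sensor counts (~25 C ambient).
#' @param abdomen_intensity Abdomen (center) level, sensor counts.
#' @param planted_cpd Center-to-peripheral difference planted in the scene,
#'   percent in `[0, 100)`.
#' @param body_intensity Patient silhouette outside abdomen/feet.
#' @param blanket_intensity Blanket level used when `covered = TRUE`.
#' @param abdomen_ellipse,body_ellipse Ellipse specs (`ellipse_spec()`), pixel
#'   coordinates; `NULL` uses frame-proportional defaults.
#' @param foot_blobs List of two `list(cy, cx, r)` circles; `NULL` for defaults.
#' @param covered Render the blanket-covered variant of the scene.
#' @param caregiver `NULL`, or an ellipse spec for a caregiver silhouette whose
#'   area must stay below the patient bounding-box area.
#' @param caregiver_intensity Caregiver level, sensor counts.
#' @param noise_sd Additive Gaussian sensor noise (counts). Noisy frames are
#'   quantized to integer counts like a real sensor; noiseless frames are not.
#' @param max_intensity Saturation level of the sensor.
#' @param seed Optional integer; fixes the noise draw.
#' @return A `scene_params` list.
#' @export
scene_params <- function(frame_height = 156L, frame_width = 206L,
                         background_intensity = 60, abdomen_intensity = 200,
                         planted_cpd = 8, body_intensity = 140,
                         blanket_intensity = 110,
                         abdomen_ellipse = NULL, body_ellipse = NULL,
                         foot_blobs = NULL, covered = FALSE,
                         caregiver = NULL, caregiver_intensity = 170,
                         noise_sd = 0, max_intensity = 255, seed = NULL) {
  if (frame_height <= 0 || frame_width <= 0)
    stop("frame dimensions must be positive")
  if (planted_cpd < 0 || planted_cpd >= 100)
    stop("planted_cpd must lie in [0, 100)")
  if (abdomen_intensity > max_intensity || background_intensity < 0)
    stop("intensities must lie within the sensor range")
  h <- frame_height; w <- frame_width
  if (is.null(abdomen_ellipse))
    abdomen_ellipse <- ellipse_spec(0.40 * h, 0.50 * w, 0.15 * h, 0.20 * w)
  if (is.null(body_ellipse))
    body_ellipse <- ellipse_spec(0.46 * h, 0.50 * w, 0.38 * h, 0.30 * w)
  if (is.null(foot_blobs))
    foot_blobs <- list(list(cy = 0.80 * h, cx = 0.40 * w, r = 0.055 * h),
                       list(cy = 0.80 * h, cx = 0.60 * w, r = 0.055 * h))
  structure(list(frame_height = as.integer(frame_height),
                 frame_width = as.integer(frame_width),
                 background_intensity = background_intensity,
                 abdomen_intensity = abdomen_intensity,
                 planted_cpd = planted_cpd,
                 body_intensity = body_intensity,
                 blanket_intensity = blanket_intensity,
                 abdomen_ellipse = abdomen_ellipse,
                 body_ellipse = body_ellipse,
                 foot_blobs = foot_blobs,
                 covered = covered,
                 caregiver = caregiver,
                 caregiver_intensity = caregiver_intensity,
                 noise_sd = noise_sd,
                 max_intensity = max_intensity,
                 seed = seed),
            class = "scene_params")
}

pixel_set_box <- function(mask_logical) {
  # 0-based half-open box from a logical pixel set
  idx <- which(mask_logical, arr.ind = TRUE)
  data.frame(x0 = min(idx[, 2]) - 1L, y0 = min(idx[, 1]) - 1L,
             x1 = max(idx[, 2]), y1 = max(idx[, 1]),
             confidence = 1, class_id = 0L)
}

box_area <- function(b) (b$x1 - b$x0) * (b$y1 - b$y0)

#' Render one synthetic thermal frame with its ground truth
#'
#' @param params A [scene_params()] object.
#' @return A list with `frame` (numeric matrix, sensor counts), `mask`
#'   (integer matrix: 0 background, 1 abdomen, 2 feet), `boxes`
#'   (data.frame of 0-based half-open person boxes, patient first) and
#'   `person_map` (integer matrix: 0 none, 1 patient, 2 caregiver -- the
#'   pixel-wise person annotation).
#' @export
render_frame <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  h <- p$frame_height; w <- p$frame_width
  rowg <- matrix(seq_len(h) - 1L, h, w)
  colg <- matrix(rep(seq_len(w) - 1L, each = h), h, w)

  body <- in_ellipse(rowg, colg, p$body_ellipse)
  feet <- Reduce(`|`, lapply(p$foot_blobs, function(f)
    (rowg - f$cy)^2 + (colg - f$cx)^2 <= f$r^2))
  abdomen <- in_ellipse(rowg, colg, p$abdomen_ellipse) & !feet
  silhouette <- body | feet

  frame <- matrix(p$background_intensity, h, w)
  mask <- matrix(0L, h, w)
  if (p$covered) {
    # blanket: near-uniform texture with gentle folds, hides abdomen and feet
    folds <- 0.03 * p$blanket_intensity *
      sin(2 * pi * rowg / (0.25 * h)) * cos(2 * pi * colg / (0.35 * w))
    frame[silhouette] <- (p$blanket_intensity + folds)[silhouette]
  } else {
    foot_intensity <- p$abdomen_intensity * (1 - p$planted_cpd / 100)
    frame[body] <- p$body_intensity
    frame[abdomen] <- p$abdomen_intensity
    frame[feet] <- foot_intensity
    mask[abdomen] <- 1L
    mask[feet] <- 2L
  }

  boxes <- pixel_set_box(silhouette)
  person_map <- matrix(0L, h, w)
  person_map[silhouette] <- 1L
  if (!is.null(p$caregiver)) {
    cg <- in_ellipse(rowg, colg, p$caregiver) & !silhouette
    if (!any(cg)) stop("caregiver blob fell entirely outside the frame")
    frame[cg] <- p$caregiver_intensity
    person_map[cg] <- 2L
    cg_box <- pixel_set_box(cg)
    if (box_area(cg_box) >= box_area(boxes))
      stop("caregiver blob must be smaller than the patient bounding box")
    boxes <- rbind(boxes, cg_box)
  }

  if (p$noise_sd > 0) {
    frame <- with_seed(p$seed, {
      noisy <- frame + stats::rnorm(h * w, sd = p$noise_sd)
      round(pmin(pmax(noisy, 0), p$max_intensity))
    })
  }
  list(frame = frame, mask = mask, boxes = boxes, person_map = person_map)
}

#' Generate a vitals series conditioned on a shock state path
#'
#' Heart rate and arterial systolic blood pressure follow AR(1) fluctuations
#' around state-conditional means; the defaults reproduce the direction (and
#' location) of the clinical contrast between shock and non-shock periods,
#' with heart rate markedly elevated under shock. A configurable fraction of
#' heart-rate entries is dropped in contiguous runs, emulating sensor
#' dropouts.
#'
#' @param shock_state_path Integer vector of 0/1 states, one per 15-s tick.
#' @param vitals_params Optional overrides: `hr_mean` (c(non-shock, shock)),
#'   `hr_sd`, `sbp_mean`, `sbp_sd`, `ar_rho`, `missing_frac`,
#'   `missing_run_mean` (ticks), `age_months`.
#' @param seed Integer seed; same seed and inputs give an identical series.
#' @return A `data.frame` with `timestamp` (seconds, 15-s grid), `heart_rate`
#'   (NA where missing), `arterial_systolic_bp`, `age_months`.
#' @export
generate_vitals <- function(shock_state_path, vitals_params = list(),
                            seed = NULL) {
  if (length(shock_state_path) == 0) stop("state path must be non-empty")
  vp <- utils::modifyList(list(
    hr_mean = c(106.16, 143.17), hr_sd = c(8, 12),
    sbp_mean = c(131.94, 128.09), sbp_sd = c(6, 8),
    ar_rho = 0.8, missing_frac = 0.05, missing_run_mean = 6,
    age_months = 120), vitals_params)
  s <- as.integer(shock_state_path)
  n <- length(s)
  with_seed(seed, {
    ar1 <- function(n, rho, sd) {
      e <- stats::rnorm(n, sd = sd * sqrt(1 - rho^2))
      x <- numeric(n)
      x[1] <- stats::rnorm(1, sd = sd)
      for (i in seq_len(n)[-1]) x[i] <- rho * x[i - 1] + e[i]
      x
    }
    hr <- vp$hr_mean[s + 1] + ar1(n, vp$ar_rho, 1) * vp$hr_sd[s + 1]
    sbp <- vp$sbp_mean[s + 1] + ar1(n, vp$ar_rho, 1) * vp$sbp_sd[s + 1]
    if (vp$missing_frac > 0) {
      target <- floor(vp$missing_frac * n)
      drop <- logical(n)
      while (sum(drop) < target) {
        start <- sample.int(n, 1)
        len <- 1 + stats::rpois(1, vp$missing_run_mean - 1)
        drop[seq(start, min(n, start + len - 1))] <- TRUE
      }
      hr[drop] <- NA_real_
    }
    data.frame(timestamp = (seq_len(n) - 1) * 15,
               heart_rate = hr,
               arterial_systolic_bp = sbp,
               age_months = vp$age_months)
  })
}

#' Simulate the binary shock state as a two-state Markov chain
#'
#' Dwell times default to the hour scale on which shock evolves: mean 2.5 h
#' in the non-shock state and 1.5 h in shock, at the 15-s tick resolution.
#'
#' @param n_ticks Number of 15-s ticks.
#' @param dwell_nonshock_s,dwell_shock_s Mean dwell times, seconds.
#' @param start_state 0/1 or `"stationary"`.
#' @return Integer vector of states.
#' @keywords internal
markov_state_path <- function(n_ticks, dwell_nonshock_s = 9000,
                              dwell_shock_s = 5400, start_state = 0L) {
  p01 <- min(1, 15 / dwell_nonshock_s)
  p10 <- min(1, 15 / dwell_shock_s)
  s <- integer(n_ticks)
  if (identical(start_state, "stationary")) {
    pi1 <- if (p01 + p10 > 0) p01 / (p01 + p10) else 0
    s[1] <- stats::rbinom(1, 1, pi1)
  } else s[1] <- as.integer(start_state)
  u <- stats::runif(n_ticks)
  for (i in seq_len(n_ticks)[-1]) {
    s[i] <- if (s[i - 1] == 0L) as.integer(u[i] < p01)
            else as.integer(u[i] >= p10)
  }
  s
}

run_length_path <- function(n, mean_on, mean_off, start_on = FALSE) {
  # alternating renewal process at 1-s resolution; returns logical "on" path
  stopifnot(mean_on > 0 || mean_off > 0)
  on <- logical(0)
  state <- start_on
  while (length(on) < n) {
    m <- if (state) mean_on else mean_off
    len <- if (!is.finite(m)) n
           else if (m <= 0) 0L
           else 1 + stats::rgeom(1, 1 / max(1, m))
    if (len > 0) on <- c(on, rep(state, len))
    state <- !state
  }
  on[seq_len(n)]
}

#' Session configuration for the synthetic generator
#'
#' @param duration_s Session length in seconds (>= 256).
#' @param age_months Patient age; `NULL` draws from the 84-155 month band,
#'   whose SIPA cutoff of 1.0 sits between the planted non-shock and shock
#'   shock-index levels.
#' @param cpd_mean Non-shock and shock mean CPD, percent.
#' @param cpd_sd,cpd_rho AR(1) noise of the CPD path.
#' @param dwell_nonshock_s,dwell_shock_s Markov dwell times, seconds.
#' @param start_state Initial shock state (0/1 or "stationary").
#' @param vitals_extension_s Seconds of vitals coverage beyond the imaging
#'   window (labels at positive leads come from here). `NULL` draws uniformly
#'   from 0-6 h per session, emulating monitoring that ends at varying times
#'   after the video and thinning the cohorts at long leads.
#' @param cover_mean_s,uncover_mean_s Mean blanket-covered / uncovered episode
#'   lengths, seconds.
#' @param caregiver_rate Fraction of time a caregiver is in frame.
#' @param noise_sd Sensor noise, counts.
#' @param render_frames Render thermal frames at 1 Hz (memory-heavy; disable
#'   for long vitals-only sessions).
#' @param vitals_params Passed to [generate_vitals()].
#' @param scene Base [scene_params()] overrides (list).
#' @return A `session_config` list.
#' @export
session_config <- function(duration_s = 3600, age_months = NULL,
                           cpd_mean = c(6, 14), cpd_sd = 1, cpd_rho = 0.95,
                           dwell_nonshock_s = 9000, dwell_shock_s = 5400,
                           start_state = "stationary",
                           vitals_extension_s = NULL,
                           cover_mean_s = 300, uncover_mean_s = 900,
                           caregiver_rate = 0.05,
                           noise_sd = 0, render_frames = FALSE,
                           vitals_params = list(), scene = list()) {
  if (duration_s < 256) stop("duration must cover at least one 256-s window")
  as.list(environment())
}

#' Generate a full synthetic patient session
#'
#' Draws the shock state path, the per-second true CPD path, the linked
#' vitals, the cover/caregiver episode structure, and (optionally) the 1-Hz
#' thermal frames with ground-truth masks and boxes.
#'
#' @param config A [session_config()] list.
#' @param seed Integer seed.
#' @param patient_id Identifier stored on the session.
#' @return A `thermo_session` list; see fields in the implementation.
#' @export
generate_session <- function(config = session_config(), seed = 1L,
                             patient_id = "P01") {
  cfg <- config
  with_seed(seed, {
    n_sec <- as.integer(cfg$duration_s)
    ext <- cfg$vitals_extension_s
    if (is.null(ext)) ext <- stats::runif(1, 0, 21600)
    n_tick <- (n_sec + as.integer(ext)) %/% 15L
    state <- markov_state_path(n_tick, cfg$dwell_nonshock_s,
                               cfg$dwell_shock_s, cfg$start_state)
    age <- cfg$age_months
    if (is.null(age)) age <- sample(84:155, 1)
    vp <- utils::modifyList(cfg$vitals_params, list(age_months = age))
    vitals <- generate_vitals(state, vp, seed = NULL)

    state_sec <- rep(state, each = 15L)[seq_len(n_sec)]
    e <- stats::rnorm(n_sec, sd = cfg$cpd_sd * sqrt(1 - cfg$cpd_rho^2))
    dev <- numeric(n_sec)
    dev[1] <- stats::rnorm(1, sd = cfg$cpd_sd)
    for (i in seq_len(n_sec)[-1]) dev[i] <- cfg$cpd_rho * dev[i - 1] + e[i]
    true_cpd <- pmax(0, cfg$cpd_mean[state_sec + 1] + dev)

    covered <- run_length_path(n_sec, cfg$cover_mean_s, cfg$uncover_mean_s)
    caregiver_on <- if (cfg$caregiver_rate > 0)
      run_length_path(n_sec, 60, 60 * (1 - cfg$caregiver_rate) /
                               cfg$caregiver_rate)
    else logical(n_sec)

    frames <- masks <- boxes <- NULL
    if (cfg$render_frames) {
      frames <- vector("list", n_sec)
      masks <- vector("list", n_sec)
      boxes <- vector("list", n_sec)
      base <- do.call(scene_params, cfg$scene)
      for (t in seq_len(n_sec)) {
        pt <- base
        pt$planted_cpd <- true_cpd[t]
        pt$covered <- covered[t]
        pt$noise_sd <- cfg$noise_sd
        if (caregiver_on[t] && is.null(pt$caregiver))
          pt$caregiver <- ellipse_spec(0.50 * pt$frame_height,
                                       0.08 * pt$frame_width,
                                       0.26 * pt$frame_height,
                                       0.055 * pt$frame_width)
        r <- render_frame(pt)
        frames[[t]] <- r$frame
        masks[[t]] <- r$mask
        boxes[[t]] <- r$boxes
      }
    }
    structure(list(patient_id = patient_id, age_months = age,
                   timestamps = seq_len(n_sec) - 1,
                   frames = frames, truth_masks = masks, truth_boxes = boxes,
                   vitals = vitals,
                   shock_state_path = state,
                   true_cpd_path = true_cpd,
                   covered_path = covered,
                   caregiver_path = caregiver_on,
                   config = cfg, seed = seed),
              class = "thermo_session")
  })
}

#' Render a labeled frame set for training the vision stages
#'
#' Draws scenes with jittered geometry, planted CPD, blanket cover and
#' caregiver presence so the screening classifier, the person detector and
#' the segmenter all see class variety.
#'
#' @param n Number of frames.
#' @param covered_frac Fraction rendered covered.
#' @param caregiver_frac Fraction (of uncovered frames) with a caregiver.
#' @param cpd_range Planted CPD drawn uniformly from this range.
#' @param noise_sd Sensor noise, counts.
#' @param jitter Relative geometry jitter (fraction of frame size).
#' @param seed Integer seed.
#' @param frame_height,frame_width Frame size.
#' @return List with `frames`, `masks`, `boxes`, `covered` (logical),
#'   `planted_cpd` (numeric), `params` (list of scene_params).
#' @export
render_training_set <- function(n, covered_frac = 0.4, caregiver_frac = 0.3,
                                cpd_range = c(2, 25), noise_sd = 2,
                                jitter = 0.04, seed = 1L,
                                frame_height = 156L, frame_width = 206L) {
  with_seed(seed, {
    h <- frame_height; w <- frame_width
    out <- list(frames = vector("list", n), masks = vector("list", n),
                boxes = vector("list", n), person_maps = vector("list", n),
                covered = logical(n),
                planted_cpd = numeric(n), params = vector("list", n))
    for (i in seq_len(n)) {
      jy <- stats::rnorm(1, sd = jitter * h)
      jx <- stats::rnorm(1, sd = jitter * w)
      sc <- 1 + stats::runif(1, -jitter, jitter)
      covered <- stats::runif(1) < covered_frac
      caregiver <- !covered && stats::runif(1) < caregiver_frac
      cpd <- stats::runif(1, cpd_range[1], cpd_range[2])
      p <- scene_params(
        frame_height = h, frame_width = w,
        planted_cpd = cpd, covered = covered,
        abdomen_intensity = 200 + stats::rnorm(1, sd = 5),
        body_intensity = 140 + stats::rnorm(1, sd = 4),
        blanket_intensity = 110 + stats::rnorm(1, sd = 4),
        background_intensity = 60 + stats::rnorm(1, sd = 3),
        abdomen_ellipse = ellipse_spec(0.40 * h + jy, 0.50 * w + jx,
                                       0.15 * h * sc, 0.20 * w * sc),
        body_ellipse = ellipse_spec(0.46 * h + jy, 0.50 * w + jx,
                                    0.38 * h * sc, 0.30 * w * sc),
        foot_blobs = list(
          list(cy = 0.80 * h + jy, cx = 0.40 * w + jx, r = 0.055 * h * sc),
          list(cy = 0.80 * h + jy, cx = 0.60 * w + jx, r = 0.055 * h * sc)),
        caregiver = if (caregiver)
          ellipse_spec(0.50 * h + stats::rnorm(1, sd = 0.05 * h),
                       (if (stats::runif(1) < 0.5) 0.08 else 0.92) * w,
                       0.26 * h, 0.055 * w) else NULL,
        noise_sd = noise_sd)
      r <- render_frame(p)
      out$frames[[i]] <- r$frame
      out$masks[[i]] <- r$mask
      out$boxes[[i]] <- r$boxes
      out$person_maps[[i]] <- r$person_map
      out$covered[i] <- covered
      out$planted_cpd[i] <- cpd
      out$params[[i]] <- p
    }
    out
  })
}
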