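test_that("foot intensity is derived from abdomen intensity and planted CPD", {
  r <- render_frame(scene_params(abdomen_intensity = 200, planted_cpd = 20,
                                 noise_sd = 0))
  expect_true(all(r$frame[r$mask == 2] == 160))
  expect_true(all(r$frame[r$mask == 1] == 200))
  r0 <- render_frame(scene_params(planted_cpd = 0, noise_sd = 0))
  expect_equal(unique(r0$frame[r0$mask == 1]), unique(r0$frame[r0$mask == 2]))
})

test_that("scene validation rejects bad parameters", {
  expect_error(scene_params(frame_height = 0), "positive")
  expect_error(scene_params(planted_cpd = 100), "planted_cpd")
  expect_error(scene_params(planted_cpd = -1), "planted_cpd")
})

test_that("covered frames hide abdomen and feet classes", {
  r <- render_frame(scene_params(covered = TRUE, noise_sd = 0))
  expect_equal(sort(unique(as.vector(r$mask))), 0L)
  expect_equal(nrow(r$boxes), 1L)   # the covered patient is still a person
})

test_that("caregiver gets its own, smaller box and disjoint regions", {
  p <- scene_params(caregiver = thermoshock:::ellipse_spec(78, 16, 40, 11))
  r <- render_frame(p)
  expect_equal(nrow(r$boxes), 2L)
  area <- (r$boxes$x1 - r$boxes$x0) * (r$boxes$y1 - r$boxes$y0)
  expect_lt(area[2], area[1])
  expect_true(all(r$person_map[r$mask != 0] == 1L))   # cg never overlaps body
})

test_that("rendering is bit-identical under a fixed seed", {
  p <- scene_params(noise_sd = 3, seed = 7)
  expect_identical(render_frame(p), render_frame(p))
  s1 <- generate_session(session_config(duration_s = 600,
                                        render_frames = TRUE), seed = 5)
  s2 <- generate_session(session_config(duration_s = 600,
                                        render_frames = TRUE), seed = 5)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$vitals, s2$vitals)
})

test_that("vitals follow state-conditional distributions", {
  # all-zeros state with zero noise: constant non-shock means
  v0 <- generate_vitals(rep(0, 50),
                        list(hr_sd = c(0, 0), sbp_sd = c(0, 0),
                             missing_frac = 0), seed = 1)
  expect_equal(unique(v0$heart_rate), 106.16)
  expect_equal(unique(v0$arterial_systolic_bp), 131.94)
  expect_identical(generate_vitals(c(0, 1, 1), seed = 3),
                   generate_vitals(c(0, 1, 1), seed = 3))
  # law of large numbers: shock mean heart rate exceeds non-shock
  st <- rep(c(0, 1), each = 10000)
  v <- generate_vitals(st, seed = 2)
  m0 <- mean(v$heart_rate[st == 0], na.rm = TRUE)
  m1 <- mean(v$heart_rate[st == 1], na.rm = TRUE)
  expect_gt(m1, m0)
  expect_equal(m0, 106.16, tolerance = 0.02)
  expect_equal(m1, 143.17, tolerance = 0.02)
  # missing markers in contiguous runs near the requested fraction
  expect_gt(mean(is.na(v$heart_rate)), 0.03)
  expect_lt(mean(is.na(v$heart_rate)), 0.10)
  expect_error(generate_vitals(integer(0)), "non-empty")
})

test_that("planted heart-rate separation is strong (SMD > 1)", {
  st <- rep(c(0, 1), each = 1000)
  v <- generate_vitals(st, list(missing_frac = 0), seed = 4)
  smd <- (mean(v$heart_rate[st == 1]) - mean(v$heart_rate[st == 0])) /
    sqrt((stats::var(v$heart_rate[st == 1]) +
            stats::var(v$heart_rate[st == 0])) / 2)
  expect_gt(smd, 1)
})

test_that("degenerate Markov chains behave as forced", {
  s <- generate_session(session_config(duration_s = 1800,
                                       dwell_nonshock_s = Inf,
                                       start_state = 0L), seed = 1)
  expect_true(all(s$shock_state_path == 0L))
  s2 <- generate_session(session_config(duration_s = 900, cover_mean_s = 0,
                                        uncover_mean_s = Inf,
                                        caregiver_rate = 0,
                                        render_frames = TRUE,
                                        vitals_extension_s = 0), seed = 2)
  expect_true(all(!s2$covered_path))
  expect_true(all(vapply(s2$truth_boxes, nrow, integer(1)) == 1L))
  expect_equal(length(s2$frames), length(s2$truth_masks))
  expect_equal(length(s2$frames), length(s2$truth_boxes))
})

test_that("shock fraction approaches the chain's stationary probability", {
  # long path so the empirical fraction is tight around pi1 = p01/(p01+p10)
  cfg <- session_config(duration_s = 3600 * 200, dwell_nonshock_s = 900,
                        dwell_shock_s = 600, start_state = "stationary",
                        vitals_extension_s = 0,
                        vitals_params = list(missing_frac = 0))
  s <- generate_session(cfg, seed = 11)
  pi1 <- (15 / 900) / (15 / 900 + 15 / 600)
  frac <- mean(s$shock_state_path)
  n <- length(s$shock_state_path)
  # effective sample size accounts for dwell autocorrelation
  n_eff <- n / ((900 + 600) / 15 / 2)
  expect_lt(abs(frac - pi1), 4 * sqrt(pi1 * (1 - pi1) / n_eff))
})

test_that("vitals timestamps sit on a strictly increasing 15-s grid", {
  s <- generate_session(session_config(duration_s = 1200), seed = 3)
  expect_true(all(diff(s$vitals$timestamp) == 15))
})

test_that("session and frame files round-trip", {
  s <- generate_session(session_config(duration_s = 300, noise_sd = 2,
                                       render_frames = TRUE,
                                       vitals_extension_s = 0), seed = 9)
  dir <- withr::local_tempdir()
  write_session(s, dir)
  f <- read_frame_tiff(file.path(dir, "frames", "000000.tif"))
  expect_equal(dim(f), dim(s$frames[[1]]))
  expect_lt(max(abs(f - s$frames[[1]])), 0.01)
  m <- read_mask_png(file.path(dir, "masks", "000010.png"))
  expect_identical(m, s$truth_masks[[11]])
  b <- read_boxes_yolo(file.path(dir, "boxes", "000000.txt"),
                       ncol(f), nrow(f))
  expect_equal(b$x0, s$truth_boxes[[1]]$x0)
  expect_equal(b$y1, s$truth_boxes[[1]]$y1)
  v <- read_vitals_csv(file.path(dir, "vitals.csv"))
  expect_equal(v$timestamp, s$vitals$timestamp)
  expect_equal(v$heart_rate, s$vitals$heart_rate)
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(man$n_seconds, 300)
})
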