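#' File formats: 16-bit TIFF frames, paletted PNG masks, YOLO-dialect box
#' files, vitals CSV and YAML session manifests
#'
#' @name thermoshock_io
NULL

#' Write / read a thermal frame as 16-bit grayscale TIFF
#'
#' Sensor counts are stored as `count / max_intensity` at 16-bit depth.
#'
#' @param frame Numeric matrix of sensor counts.
#' @param path Output path.
#' @param max_intensity Full-scale count (default 255).
#' @export
write_frame_tiff <- function(frame, path, max_intensity = 255) {
  tiff::writeTIFF(pmin(pmax(frame / max_intensity, 0), 1), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_frame_tiff
#' @export
read_frame_tiff <- function(path, max_intensity = 255) {
  tiff::readTIFF(path) * max_intensity
}

#' Write / read a segmentation mask as 8-bit PNG
#'
#' Class codes (0 background, 1 abdomen, 2 feet) stored directly as pixel
#' values.
#'
#' @param mask Integer class-code matrix.
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Write / read boxes in the YOLO annotation dialect
#'
#' One text file per frame, rows `class x_center y_center width height`
#' normalized to `[0, 1]`; internal boxes are 0-based half-open pixel
#' coordinates.
#'
#' @param boxes data.frame with `x0`, `y0`, `x1`, `y1`, `class_id`.
#' @param path Output path.
#' @param frame_width,frame_height Frame size used for normalization.
#' @export
write_boxes_yolo <- function(boxes, path, frame_width, frame_height) {
  rows <- vapply(seq_len(nrow(boxes)), function(i) {
    b <- boxes[i, ]
    sprintf("%d %.6f %.6f %.6f %.6f", b$class_id,
            (b$x0 + b$x1) / 2 / frame_width, (b$y0 + b$y1) / 2 / frame_height,
            (b$x1 - b$x0) / frame_width, (b$y1 - b$y0) / frame_height)
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' @rdname write_boxes_yolo
#' @export
read_boxes_yolo <- function(path, frame_width, frame_height) {
  lines <- readLines(path)
  if (length(lines) == 0)
    return(data.frame(x0 = integer(0), y0 = integer(0), x1 = integer(0),
                      y1 = integer(0), confidence = numeric(0),
                      class_id = integer(0)))
  v <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
  data.frame(
    x0 = as.integer(round((v[, 2] - v[, 4] / 2) * frame_width)),
    y0 = as.integer(round((v[, 3] - v[, 5] / 2) * frame_height)),
    x1 = as.integer(round((v[, 2] + v[, 4] / 2) * frame_width)),
    y1 = as.integer(round((v[, 3] + v[, 5] / 2) * frame_height)),
    confidence = 1, class_id = as.integer(v[, 1]))
}

#' Write / read a vitals series as CSV with ISO-8601 timestamps
#'
#' @param vitals data.frame with `timestamp` (seconds), `heart_rate`,
#'   `arterial_systolic_bp`, `age_months`.
#' @param path Output path.
#' @param origin POSIXct origin mapped to second 0.
#' @export
write_vitals_csv <- function(vitals, path,
                             origin = as.POSIXct("2026-01-01 00:00:00",
                                                 tz = "UTC")) {
  out <- vitals
  out$timestamp <- format(origin + vitals$timestamp, "%Y-%m-%dT%H:%M:%SZ")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_vitals_csv
#' @export
read_vitals_csv <- function(path,
                            origin = as.POSIXct("2026-01-01 00:00:00",
                                                tz = "UTC")) {
  v <- utils::read.csv(path, stringsAsFactors = FALSE)
  v$timestamp <- as.numeric(difftime(
    as.POSIXct(v$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    origin, units = "secs"))
  v
}

#' Write a synthetic session to a directory
#'
#' Layout: `frames/NNNNNN.tif` (16-bit TIFF), `masks/NNNNNN.png`,
#' `boxes/NNNNNN.txt` (YOLO dialect), `vitals.csv`, `truth.csv` (per-second
#' planted CPD, cover and caregiver flags), `manifest.yaml`.
#'
#' @param session A `thermo_session` (frames may be absent).
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(session$timestamps)
  if (!is.null(session$frames)) {
    for (sub in c("frames", "masks", "boxes"))
      dir.create(file.path(dir, sub), showWarnings = FALSE)
    for (i in seq_len(n)) {
      stem <- sprintf("%06d", i - 1)
      write_frame_tiff(session$frames[[i]],
                       file.path(dir, "frames", paste0(stem, ".tif")))
      write_mask_png(session$truth_masks[[i]],
                     file.path(dir, "masks", paste0(stem, ".png")))
      write_boxes_yolo(session$truth_boxes[[i]],
                       file.path(dir, "boxes", paste0(stem, ".txt")),
                       ncol(session$frames[[i]]), nrow(session$frames[[i]]))
    }
  }
  write_vitals_csv(session$vitals, file.path(dir, "vitals.csv"))
  utils::write.csv(
    data.frame(timestamp = session$timestamps,
               true_cpd = session$true_cpd_path,
               covered = as.integer(session$covered_path),
               caregiver = as.integer(session$caregiver_path)),
    file.path(dir, "truth.csv"), row.names = FALSE)
  yaml::write_yaml(list(
    patient_id = session$patient_id,
    age_months = session$age_months,
    n_seconds = n,
    seed = session$seed,
    has_frames = !is.null(session$frames),
    shock_ticks = sum(session$shock_state_path),
    total_ticks = length(session$shock_state_path)),
    file.path(dir, "manifest.yaml"))
  invisible(dir)
}
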