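# Pre-test calibration.  Before a session the subject provides (i) about one
# minute of eyes-closed frames, from which per-eye blink thresholds are set to
# the mean closed-eye EAR, and (ii) about one minute of frontal pose, from
# which the nod baseline D' (median nose bridge-tip distance) and the frontal
# inter-ocular baseline AB are taken.  At the nominal 25 fps a one-minute
# segment holds N = 1500 samples.

#' Construct a calibration profile
#'
#' @param blink_threshold_L,blink_threshold_R per-eye blink thresholds in EAR
#'   units (dimensionless, >= 0).
#' @param nod_baseline_D baseline nose bridge-to-tip distance D' in pixels.
#' @param interocular_baseline_AB frontal inter-ocular (eye-center to
#'   eye-center) distance AB in pixels.
#' @param fps frame rate the calibration was taken at.
#' @param calibration_n number of calibration samples used.
#' @return a `calibration_profile` object.
#' @export
calibration_profile <- function(blink_threshold_L, blink_threshold_R,
                                nod_baseline_D, interocular_baseline_AB,
                                fps = 25, calibration_n = NA_integer_) {
  if (blink_threshold_L < 0 || blink_threshold_R < 0) {
    stop("blink thresholds must be >= 0", call. = FALSE)
  }
  if (nod_baseline_D <= 0) stop("nod_baseline_D must be > 0", call. = FALSE)
  if (interocular_baseline_AB <= 0) {
    stop("interocular_baseline_AB must be > 0", call. = FALSE)
  }
  structure(list(blink_threshold_L = as.numeric(blink_threshold_L),
                 blink_threshold_R = as.numeric(blink_threshold_R),
                 nod_baseline_D = as.numeric(nod_baseline_D),
                 interocular_baseline_AB = as.numeric(interocular_baseline_AB),
                 fps = as.numeric(fps),
                 calibration_n = as.integer(calibration_n)),
            class = "calibration_profile")
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat("<calibration_profile>\n")
  cat(sprintf("  blink threshold  L: %.4f  R: %.4f (EAR)\n",
              x$blink_threshold_L, x$blink_threshold_R))
  cat(sprintf("  nod baseline D': %.2f px   inter-ocular AB: %.2f px\n",
              x$nod_baseline_D, x$interocular_baseline_AB))
  cat(sprintf("  fps: %g   calibration samples: %s\n", x$fps,
              ifelse(is.na(x$calibration_n), "?", x$calibration_n)))
  invisible(x)
}

#' Blink threshold from eyes-closed EAR samples
#'
#' The threshold is the arithmetic mean of the per-frame EAR values collected
#' while the eyes are closed: Blink_threshold = (1/N) * sum(B_i).  Nominally
#' N = fps x 60 = 1500 samples at 25 fps.
#'
#' @param closed_eye_ear_samples numeric vector of closed-eye EAR values.
#' @return the threshold, EAR units.
#' @export
calibrate_blink_threshold <- function(closed_eye_ear_samples) {
  if (length(closed_eye_ear_samples) == 0L) {
    stop("cannot calibrate a blink threshold from zero samples", call. = FALSE)
  }
  if (any(!is.finite(closed_eye_ear_samples)) ||
      any(closed_eye_ear_samples < 0)) {
    stop("EAR samples must be finite and non-negative", call. = FALSE)
  }
  mean(closed_eye_ear_samples)
}

#' Nod baseline D' from a calibration stream
#'
#' D' is the median over the calibration segment of the per-frame distance
#' d = |p27 - p30| between the top of the nose bridge and the nose tip.  For
#' an even sample count the median is the mean of the two central order
#' statistics.
#'
#' @param frames a `landmark_stream` (frontal calibration segment).
#' @return D' in pixels.
#' @export
calibrate_nod_baseline <- function(frames) {
  stopifnot(inherits(frames, "landmark_stream"))
  if (length(frames) == 0L) stop("empty calibration stream", call. = FALSE)
  d <- frame_distances(frames, NOSE_BRIDGE_IDX, NOSE_TIP_IDX)
  stats::median(d)
}

#' Frontal inter-ocular baseline AB from a calibration stream
#'
#' Median over frames of the distance between the two eye centers while the
#' subject holds the initial frontal sitting orientation.  Fixed once at
#' calibration and reused for every subsequent yaw estimate.
#'
#' @param frames a `landmark_stream` (frontal calibration segment).
#' @return AB in pixels.
#' @export
calibrate_interocular <- function(frames) {
  stopifnot(inherits(frames, "landmark_stream"))
  if (length(frames) == 0L) stop("empty calibration stream", call. = FALSE)
  cl <- eye_center_series(frames, "L")
  cr <- eye_center_series(frames, "R")
  stats::median(sqrt(rowSums((cl - cr)^2)))
}

# vectorized |p_a - p_b| over a stream, 0-based indices
frame_distances <- function(stream, a, b) {
  xa <- stream$coords[, 2L * a + 1L]
  ya <- stream$coords[, 2L * a + 2L]
  xb <- stream$coords[, 2L * b + 1L]
  yb <- stream$coords[, 2L * b + 2L]
  sqrt((xa - xb)^2 + (ya - yb)^2)
}

# n x 2 matrix of per-frame eye centers
eye_center_series <- function(stream, eye) {
  idx <- if (eye == "L") EYE_L_IDX else EYE_R_IDX
  x <- rowMeans(stream$coords[, 2L * idx + 1L, drop = FALSE])
  y <- rowMeans(stream$coords[, 2L * idx + 2L, drop = FALSE])
  cbind(x = x, y = y)
}

#' Build a full calibration profile from the two pre-test segments
#'
#' Per-eye blink thresholds come from the eyes-closed segment; the nod
#' baseline and inter-ocular baseline come from the frontal segment.  Any
#' segment shorter than the nominal 60 s is accepted down to one second of
#' frames, with a warning.
#'
#' @param closed a `landmark_stream` of eyes-closed frames.
#' @param frontal a `landmark_stream` of frontal open-eye frames.
#' @return a `calibration_profile`.
#' @export
calibrate_profile <- function(closed, frontal) {
  stopifnot(inherits(closed, "landmark_stream"),
            inherits(frontal, "landmark_stream"))
  fps <- closed$fps
  for (seg in list(closed = closed, frontal = frontal)) {
    if (length(seg) < seg$fps) {
      stop("calibration segment shorter than one second of frames",
           call. = FALSE)
    }
  }
  if (length(closed) < 60 * fps) {
    warning("eyes-closed segment shorter than the nominal 60 s (",
            length(closed), " frames); threshold noisier than nominal",
            call. = FALSE)
  }
  ears <- ear_series(closed)
  calibration_profile(
    blink_threshold_L = calibrate_blink_threshold(ears$ear_l),
    blink_threshold_R = calibrate_blink_threshold(ears$ear_r),
    nod_baseline_D = calibrate_nod_baseline(frontal),
    interocular_baseline_AB = calibrate_interocular(frontal),
    fps = fps,
    calibration_n = length(closed))
}

## ---- profile persistence --------------------------------------------------

PROFILE_FIELDS <- c("blink_threshold_L", "blink_threshold_R", "nod_baseline_D",
                    "interocular_baseline_AB", "fps", "calibration_n")

#' Save / load a calibration profile as JSON
#'
#' All six fields round-trip exactly; a file missing any field is rejected
#' with a schema error.
#'
#' @param profile a `calibration_profile`.
#' @param path JSON file path.
#' @return `load_profile` returns a `calibration_profile`.
#' @export
save_profile <- function(profile, path) {
  stopifnot(inherits(profile, "calibration_profile"))
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' @rdname save_profile
#' @export
load_profile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path)
  missing_f <- setdiff(PROFILE_FIELDS, names(obj))
  if (length(missing_f)) {
    stop("profile file lacks field(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  calibration_profile(obj$blink_threshold_L, obj$blink_threshold_R,
                      obj$nod_baseline_D, obj$interocular_baseline_AB,
                      fps = obj$fps,
                      calibration_n = if (is.null(obj$calibration_n))
                        NA_integer_ else obj$calibration_n)
}
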