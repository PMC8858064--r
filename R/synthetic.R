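# Synthetic landmark and EEG generation.  A fixed schematic frontal face
# provides the 68-point template; scripted events deform it:
#   * blinks collapse an eye block's vertical extent by a depth fraction,
#   * yaw turns foreshorten the projected inter-ocular distance and push the
#     nose block laterally,
#   * nods shrink the nose bridge-to-tip distance.
# Yaw is rendered by inverting the detector's own projection formula (the
# inter-ocular compression factor is solved numerically so that the
# trigonometric estimate recovers the scripted angle exactly), which makes
# end-to-end recovery a sharp test of the pipeline rather than of a 3-D
# rendering model.
#
# Head events are *relative* rotations: each event turns the head by
# `magnitude` degrees away from its currently held orientation and the new
# orientation is held until the next event.  The magnitude is therefore
# exactly the second-to-second angle change the classifier thresholds, so
# ground truth follows from the 10/30-degree rule without simulation.

SCRIPT_KINDS <- c("blink_L", "blink_R", "blink_both", "yaw", "nod")
DEFAULT_SEED <- 20220941L

#' Schematic frontal face template
#'
#' A deterministic 68-point frontal face with open eyes (EAR exactly 0.3 per
#' eye), eye centers 120 px apart at image row 220, nose bridge top at
#' (320, 215) and nose tip at (320, 275) (baseline d = 60 px).
#'
#' @return a `landmark_frame`.
#' @export
face_template <- function() {
  pts <- matrix(NA_real_, nrow = 68L, ncol = 2L)
  a <- seq(180, 360, length.out = 17) * pi / 180          # jaw 0-16
  pts[1:17, ] <- cbind(320 + 105 * cos(a), 230 - 130 * sin(a))
  pts[18:22, ] <- cbind(seq(235, 295, length.out = 5), 195)  # brows
  pts[23:27, ] <- cbind(seq(345, 405, length.out = 5), 195)
  pts[28:31, ] <- cbind(320, seq(215, 275, length.out = 4))  # nose bridge
  pts[32:36, ] <- cbind(seq(300, 340, length.out = 5), 285)  # nostril base
  eye_l <- rbind(c(240, 220), c(252, 214), c(268, 214),
                 c(280, 220), c(268, 226), c(252, 226))
  pts[37:42, ] <- eye_l                                      # L block 36-41
  pts[43:48, ] <- eye_l + cbind(rep(120, 6), 0)              # R block 42-47
  am <- seq(0, 330, by = 30) * pi / 180                      # mouth outer
  pts[49:60, ] <- cbind(320 + 40 * cos(am), 320 + 20 * sin(am))
  ai <- seq(0, 315, by = 45) * pi / 180                      # mouth inner
  pts[61:68, ] <- cbind(320 + 25 * cos(ai), 320 + 10 * sin(ai))
  landmark_frame(pts, timestamp = 0, frame_index = 0L)
}

TEMPLATE_AB <- 120        # frontal inter-ocular distance of the template, px
TEMPLATE_D <- 60          # frontal nose bridge-to-tip distance, px
NOSE_SHIFT_GAIN <- 40     # lateral nose offset per unit sin(yaw), px

#' Build an event script
#'
#' @param onset numeric vector of event onsets, seconds (>= 0).
#' @param duration event durations, seconds; for head kinds this is the span
#'   of the associated EEG artifact (the orientation change itself is a step
#'   at onset, held until the next event on the same axis).
#' @param kind one of `"blink_L"`, `"blink_R"`, `"blink_both"`, `"yaw"`,
#'   `"nod"` per event.
#' @param magnitude blink depth fraction in [0, 1] for blink kinds; rotation
#'   in degrees (relative to the held orientation) for head kinds.
#' @param seed integer seed stored with the script (default 20220941).
#' @return an `event_script` data frame.
#' @export
event_script <- function(onset = numeric(0), duration = numeric(0),
                         kind = character(0), magnitude = numeric(0),
                         seed = DEFAULT_SEED) {
  df <- data.frame(onset = as.numeric(onset), duration = as.numeric(duration),
                   kind = as.character(kind),
                   magnitude = as.numeric(magnitude))
  if (any(!df$kind %in% SCRIPT_KINDS)) {
    stop("unknown event kind(s): ",
         paste(setdiff(df$kind, SCRIPT_KINDS), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$onset < 0) || any(df$duration <= 0)) {
    stop("event onsets must be >= 0 and durations > 0", call. = FALSE)
  }
  if (any(df$magnitude < 0)) stop("magnitudes must be >= 0", call. = FALSE)
  isblink <- grepl("^blink", df$kind)
  if (any(df$magnitude[isblink] > 1)) {
    stop("blink depth fraction must be in [0, 1]", call. = FALSE)
  }
  check_overlaps(df)
  df <- df[order(df$onset), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, seed = as.integer(seed),
            class = c("event_script", "data.frame"))
}

# Same-kind events may not overlap in time (blink_both shares both eyes).
check_overlaps <- function(df) {
  groups <- list(blink_L = c("blink_L", "blink_both"),
                 blink_R = c("blink_R", "blink_both"),
                 yaw = "yaw", nod = "nod")
  for (g in names(groups)) {
    ev <- df[df$kind %in% groups[[g]], , drop = FALSE]
    if (nrow(ev) < 2L) next
    ev <- ev[order(ev$onset), ]
    if (any(ev$onset[-1L] < (ev$onset + ev$duration)[-nrow(ev)])) {
      stop("overlapping incompatible events of the same kind (", g, ")",
           call. = FALSE)
    }
  }
}

## ---- held-orientation step functions --------------------------------------

# Each head event rotates the held angle by +/- magnitude; yaw picks the
# candidate with the smaller absolute angle (tie -> positive), nod the
# smaller candidate inside the trackable pitch range [0, 45] (beyond about
# 45 degrees of sustained pitch an upstream 68-point landmark detector loses
# the face, so no landmark stream would exist there; the cap also keeps the
# nose tip clear of the inter-ocular line, where the yaw geometry is
# ill-conditioned).  Returns breakpoints and held values.
held_angles <- function(script, axis = c("yaw", "nod")) {
  axis <- match.arg(axis)
  ev <- script[script$kind == axis, , drop = FALSE]
  breaks <- 0; values <- 0; cur <- 0
  if (nrow(ev)) {
    for (k in seq_len(nrow(ev))) {
      m <- ev$magnitude[k]
      cand <- c(cur + m, cur - m)
      cur <- if (axis == "yaw") {
        if (abs(cand[1L]) <= abs(cand[2L])) cand[1L] else cand[2L]
      } else {
        ok <- cand[cand >= 0 & cand <= 45]
        if (length(ok)) min(ok) else min(45, max(0, cand[2L]))
      }
      breaks <- c(breaks, ev$onset[k]); values <- c(values, cur)
    }
  }
  list(breaks = breaks, values = values)
}

step_at <- function(step, t) {
  step$values[findInterval(t, step$breaks)]
}

# active blink depth per timestamp for one eye ("L" or "R")
blink_depth_at <- function(script, t, eye) {
  kinds <- c(paste0("blink_", eye), "blink_both")
  ev <- script[script$kind %in% kinds, , drop = FALSE]
  depth <- numeric(length(t))
  for (k in seq_len(nrow(ev))) {
    hit <- t >= ev$onset[k] & t < ev$onset[k] + ev$duration[k]
    depth[hit] <- pmax(depth[hit], ev$magnitude[k])
  }
  depth
}

## ---- frame rendering ------------------------------------------------------

# Solve the inter-ocular compression factor c so that the detector's
# projection formula, evaluated on the rendered geometry (eye centers at
# 320 -+ c*AB/2, nose tip at E), returns exactly `m` degrees of yaw.
solve_compression <- function(m_deg, E) {
  m <- m_deg * pi / 180
  if (m_deg == 0) return(1)
  cm <- cos(m)
  c_cur <- cm
  for (it in 1:60) {
    AC <- c_cur * TEMPLATE_AB
    A <- c(320 - AC / 2, 220)
    v <- E - A
    costh <- (AC * v[1L]) / (AC * sqrt(sum(v^2)))  # u = (AC, 0)
    c_new <- cm / sqrt((1 - costh^2) + cm^2 * costh^2)
    if (abs(c_new - c_cur) < 1e-14) { c_cur <- c_new; break }
    c_cur <- c_new
  }
  c_cur
}

# Deform the template for one pose (signed yaw, nod in [0,90], per-eye blink
# depths); returns a 68 x 2 coordinate matrix.
render_face <- function(yaw_deg, nod_deg, depth_l, depth_r, template) {
  pts <- unclass(template)[, , drop = FALSE]
  # nose block lateral shift encodes yaw direction
  dx <- NOSE_SHIFT_GAIN * sin(abs(yaw_deg) * pi / 180) * sign(yaw_deg)
  pts[28:36, 1L] <- pts[28:36, 1L] + dx
  # nod shrinks the bridge-to-tip distance; lower nose points follow the tip
  scale <- 1 - nod_deg / 90
  tip_old <- pts[31L, ]
  pts[31L, ] <- pts[28L, ] + (pts[31L, ] - pts[28L, ]) * scale
  pts[32:36, ] <- pts[32:36, ] +
    matrix(pts[31L, ] - tip_old, nrow = 5, ncol = 2, byrow = TRUE)
  pts[29:30, 2L] <- pts[28L, 2L] +
    (pts[29:30, 2L] - pts[28L, 2L]) * scale
  # yaw compresses the projected inter-ocular distance about the midline
  cfac <- solve_compression(abs(yaw_deg), pts[31L, ])
  AC <- cfac * TEMPLATE_AB
  shift_l <- (320 - AC / 2) - 260
  shift_r <- (320 + AC / 2) - 380
  pts[37:42, 1L] <- pts[37:42, 1L] + shift_l
  pts[43:48, 1L] <- pts[43:48, 1L] + shift_r
  # blink collapses the eyelid points toward the eye-center row
  if (depth_l > 0) pts[37:42, 2L] <- 220 + (pts[37:42, 2L] - 220) * (1 - depth_l)
  if (depth_r > 0) pts[43:48, 2L] <- 220 + (pts[43:48, 2L] - 220) * (1 - depth_r)
  pts
}

#' Render a landmark stream (and its ground truth) from an event script
#'
#' Frames are placed at `t = 0, 1/fps, ...` up to `duration`.  Ground truth
#' is computed from the script itself, not from the rendered landmarks: blink
#' seconds are the windows containing blink-event frames (per eye), and head
#' micro/distinct seconds follow from the true held angles via the same
#' 10/30-degree second-to-second rule the detector applies.
#'
#' @param script an `event_script`.
#' @param duration stream length in seconds.
#' @param fps frame rate (default 25).
#' @param jitter_sigma standard deviation of i.i.d. Gaussian positional
#'   jitter added to every coordinate, pixels (default 0).
#' @param seed RNG seed for the jitter; defaults to the script's seed.
#' @param thresholds micro/distinct boundaries used for the ground truth
#'   (default `c(10, 30)`).
#' @return a `synthetic_scene`: list with `stream` (a `landmark_stream`),
#'   `truth` (named list of 0-based flagged-second vectors per category),
#'   `angles` (data frame of true per-frame yaw/nod), and `script`.
#' @export
render_stream <- function(script, duration, fps = 25, jitter_sigma = 0,
                          seed = attr(script, "seed"),
                          thresholds = c(10, 30)) {
  stopifnot(inherits(script, "event_script"))
  if (nrow(script) && any(script$onset >= duration)) {
    stop("event onset beyond stream duration", call. = FALSE)
  }
  n <- round(duration * fps)
  t <- (seq_len(n) - 1L) / fps
  yaw_step <- held_angles(script, "yaw")
  nod_step <- held_angles(script, "nod")
  yaw <- step_at(yaw_step, t)
  nod <- step_at(nod_step, t)
  dl <- blink_depth_at(script, t, "L")
  dr <- blink_depth_at(script, t, "R")

  template <- face_template()
  pose_key <- paste(yaw, nod, dl, dr)
  coords <- matrix(NA_real_, nrow = n, ncol = 136L)
  for (key in unique(pose_key)) {
    i <- which(pose_key == key)[1L]
    pts <- render_face(yaw[i], nod[i], dl[i], dr[i], template)
    coords[pose_key == key, ] <- matrix(as.vector(t(pts)),
                                        nrow = sum(pose_key == key),
                                        ncol = 136L, byrow = TRUE)
  }
  if (jitter_sigma > 0) {
    set.seed(seed %% .Machine$integer.max)
    coords <- coords + stats::rnorm(length(coords), sd = jitter_sigma)
  }
  stream <- landmark_stream(seq_len(n) - 1L, t, coords, fps = fps)

  truth <- script_truth(yaw, nod, dl, dr, t, thresholds)
  structure(list(stream = stream, truth = truth,
                 angles = data.frame(t = t, yaw_deg = yaw, nod_deg = nod),
                 script = script),
            class = "synthetic_scene")
}

# ground-truth flagged seconds implied by the script's true state
script_truth <- function(yaw, nod, dl, dr, t, thresholds) {
  w <- window_index_of(t, 0)
  nw <- max(w) + 1L
  psi_yaw <- window_means(yaw, w, nw)
  psi_nod <- window_means(nod, w, nw)
  hs <- integer(nw)
  for (k in seq_len(nw)) {
    if (k == 1L) { hs[k] <- 0L; next }
    hs[k] <- head_status(psi_yaw[k], psi_yaw[k - 1L],
                         psi_nod[k], psi_nod[k - 1L], thresholds)
  }
  list(blink_left = sort(unique(w[dl > 0])),
       blink_right = sort(unique(w[dr > 0])),
       head_micro = which(hs == 1L) - 1L,
       head_distinct = which(hs == 2L) - 1L)
}

#' Ground truth of a synthetic scene as an annotation track
#'
#' @param scene a `synthetic_scene` from [render_stream()].
#' @return an `annotation_track` of the scene's true events.
#' @export
truth_track <- function(scene) {
  rows <- do.call(rbind, lapply(names(scene$truth), function(lab) {
    secs <- scene$truth[[lab]]
    if (!length(secs)) return(NULL)
    data.frame(onset = as.numeric(secs), duration = 1, label = lab)
  }))
  if (is.null(rows)) {
    rows <- data.frame(onset = numeric(0), duration = numeric(0),
                       label = character(0))
  }
  rows <- rows[order(rows$onset, match(rows$label, ANNOTATION_LABELS)), ]
  rownames(rows) <- NULL
  structure(rows, class = c("annotation_track", "data.frame"))
}

## ---- synthetic EEG --------------------------------------------------------

#' Render synthetic EEG with injected artifact deflections
#'
#' Baseline is seeded band-limited noise (white noise smoothed by a short
#' moving-average FIR, rescaled to `baseline_rms`).  Blink events add a
#' large, slow positive deflection on frontal channels; head events add a
#' low-frequency high-amplitude drift on all channels.
#'
#' @param script an `event_script`.
#' @param duration recording length, seconds.
#' @param fs sampling rate, Hz (default 250).
#' @param n_channels channel count (default 4; the first half are frontal,
#'   named Fp1, Fp2, ...).
#' @param seed RNG seed; defaults to the script's seed.
#' @param baseline_rms baseline noise RMS, microvolts (default 10).
#' @param blink_amp,drift_amp artifact amplitudes, microvolts.
#' @return an `eeg_recording`.
#' @export
render_eeg <- function(script, duration, fs = 250, n_channels = 4,
                       seed = attr(script, "seed"), baseline_rms = 10,
                       blink_amp = 150, drift_amp = 200) {
  stopifnot(inherits(script, "event_script"), fs > 0)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  nf <- max(1L, n_channels %/% 2L)
  chans <- c(paste0("Fp", seq_len(nf)),
             paste0("O", seq_len(n_channels - nf)))[seq_len(n_channels)]
  set.seed(seed %% .Machine$integer.max)
  samples <- t(vapply(seq_len(n_channels), function(ch) {
    x <- stats::rnorm(n)
    x <- as.numeric(stats::filter(x, rep(1 / 8, 8), sides = 2,
                                  circular = TRUE))
    x / stats::sd(x) * baseline_rms
  }, numeric(n)))
  rownames(samples) <- chans
  frontal <- grepl("^F", chans)
  for (k in seq_len(nrow(script))) {
    span <- t >= script$onset[k] & t < script$onset[k] + script$duration[k]
    if (!any(span)) next
    u <- (t[span] - script$onset[k]) / script$duration[k]
    if (grepl("^blink", script$kind[k])) {
      bump <- blink_amp * sin(pi * u)^2
      samples[frontal, span] <- samples[frontal, span] +
        matrix(bump, nrow = sum(frontal), ncol = length(bump), byrow = TRUE)
    } else {
      drift <- drift_amp * sin(2 * pi * u)
      samples[, span] <- samples[, span] +
        matrix(drift, nrow = n_channels, ncol = length(drift), byrow = TRUE)
    }
  }
  eeg_recording(samples, fs, channel_names = chans, start_time = 0)
}

## ---- calibration segments -------------------------------------------------

#' Synthetic calibration segments
#'
#' An eyes-closed stream (eyelids collapsed to EAR exactly 0.05 before
#' jitter) and a frontal open-eye stream, both seeded.  At the defaults
#' (60 s, 25 fps) each holds 1500 frames.
#'
#' @param fps frame rate (default 25).
#' @param duration segment length, seconds (default 60).
#' @param jitter_sigma Gaussian positional jitter, pixels (default 0.5).
#' @param seed RNG seed.
#' @return list with `closed` and `frontal` `landmark_stream`s.
#' @export
calibration_segments <- function(fps = 25, duration = 60, jitter_sigma = 0.5,
                                 seed = DEFAULT_SEED) {
  if (duration < 1) stop("calibration segments need duration >= 1 s",
                         call. = FALSE)
  closed_depth <- 1 - 0.05 / 0.3   # template EAR 0.3 -> closed EAR 0.05
  closed_script <- event_script(onset = 0, duration = duration + 1,
                                kind = "blink_both",
                                magnitude = closed_depth, seed = seed)
  closed <- render_stream(closed_script, duration, fps, jitter_sigma,
                          seed = seed)$stream
  frontal <- render_stream(event_script(seed = seed), duration, fps,
                           jitter_sigma, seed = seed + 1L)$stream
  list(closed = closed, frontal = frontal)
}

## ---- presets --------------------------------------------------------------

#' Scripted demonstration and random scenario presets
#'
#' `preset = "demo"` reproduces a 24-second demonstration scenario: two
#' both-eye blinks (full depth, at 4 s and 13 s) and two head turns in
#' opposite directions (a 20-degree micro turn at 8 s, then a 40-degree
#' relative turn at 16 s), giving ground truth of two blink seconds per eye,
#' one micro and one distinct head-movement second.  `preset = "random"`
#' scripts `n_events` events at integer onsets at least 2 s apart: random
#' kinds and placement, blink depths in [0.95, 1], and head rotations fixed
#' at the demonstration scenario's representative magnitudes (20 degrees
#' micro, 40 degrees distinct, drawn with equal probability) so every true
#' second-to-second change sits 10 degrees clear of the 10/30 class
#' boundaries.
#'
#' @param preset `"demo"` or `"random"`.
#' @param duration scene length in seconds (default 24 for demo, else
#'   required).
#' @param n_events number of events for the random preset (default 20).
#' @param seed RNG seed.
#' @return an `event_script`.
#' @export
scripted_preset <- function(preset = c("demo", "random"), duration = NULL,
                            n_events = 20, seed = DEFAULT_SEED) {
  preset <- match.arg(preset)
  if (preset == "demo") {
    return(event_script(
      onset = c(4, 8, 13, 16),
      duration = c(0.2, 1, 0.2, 1),
      kind = c("blink_both", "yaw", "blink_both", "yaw"),
      magnitude = c(1, 20, 1, 40),
      seed = seed))
  }
  if (is.null(duration)) stop("random preset needs a duration", call. = FALSE)
  set.seed(seed %% .Machine$integer.max)
  slots <- seq(2, duration - 3, by = 3)
  if (length(slots) < n_events) {
    stop("duration too short for ", n_events, " events", call. = FALSE)
  }
  onset <- sort(sample(slots, n_events))
  kind <- sample(SCRIPT_KINDS, n_events, replace = TRUE)
  isblink <- grepl("^blink", kind)
  magnitude <- ifelse(isblink, stats::runif(n_events, 0.95, 1),
                      ifelse(stats::runif(n_events) < 0.5, 20, 40))
  event_script(onset = onset, duration = ifelse(isblink, 0.2, 1),
               kind = kind, magnitude = magnitude, seed = seed)
}
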