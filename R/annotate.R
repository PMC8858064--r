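# The annotation flow: over synchronized landmark and EEG streams, each
# 1-second window gets per-eye blink statuses and a head-movement status;
# flagged windows become artifact events at 1-second granularity, and the
# events project onto the EEG as a per-sample artifact mask.  Blink and
# head-movement detectors both run on every window, so a window may carry
# blink and head flags simultaneously.

ANNOTATION_LABELS <- c("blink_left", "blink_right", "head_micro",
                       "head_distinct")

#' Per-window detector statuses for a landmark stream
#'
#' Splits the stream into half-open 1-second windows `[w, w+1)` aligned to the
#' stream start and runs both detectors on every window: per-eye blink status
#' (minimum window EAR against the calibrated threshold) and head-movement
#' status (second-to-second change of the window-mean yaw and nod angles).
#' Windows that received no frames (dropped capture) get `NA` statuses and
#' are skipped by [annotate()]; the head differencing carries the last
#' observed window mean across such gaps.
#'
#' @param stream a `landmark_stream`.
#' @param profile a `calibration_profile`.
#' @param thresholds micro/distinct head boundaries in degrees,
#'   default `c(10, 30)`.
#' @param window_s window length in seconds (default 1).
#' @return a `window_status` data frame with columns `window_index`,
#'   `t_start`, `blink_L`, `blink_R`, `blink_any`, `psi_yaw`, `psi_nod`,
#'   `head_status`.
#' @export
window_statuses <- function(stream, profile, thresholds = c(10, 30),
                            window_s = 1) {
  stopifnot(inherits(stream, "landmark_stream"),
            inherits(profile, "calibration_profile"))
  empty <- structure(
    data.frame(window_index = integer(0), t_start = numeric(0),
               blink_L = integer(0), blink_R = integer(0),
               blink_any = integer(0), psi_yaw = numeric(0),
               psi_nod = numeric(0), head_status = integer(0)),
    class = c("window_status", "data.frame"))
  if (length(stream) == 0L) return(empty)

  t0 <- stream$timestamp[1L]
  nw <- n_windows_of(stream$timestamp, t0, window_s)
  w <- window_index_of(stream$timestamp, t0, window_s)

  ears <- ear_series(stream)
  bl <- blink_window_statuses(data.frame(t = ears$t, ear = ears$ear_l),
                              profile$blink_threshold_L, t0, nw)
  br <- blink_window_statuses(data.frame(t = ears$t, ear = ears$ear_r),
                              profile$blink_threshold_R, t0, nw)

  ang <- head_angle_series(stream, profile)
  psi_yaw <- window_means(ang$yaw_deg, w, nw)
  psi_nod <- window_means(ang$nod_deg, w, nw)

  hs <- rep(NA_integer_, nw)
  prev_yaw <- NA_real_; prev_nod <- NA_real_
  for (k in seq_len(nw)) {
    if (is.na(psi_yaw[k])) next  # empty window: no frames fell in it
    hs[k] <- head_status(psi_yaw[k], prev_yaw, psi_nod[k], prev_nod,
                         thresholds)
    prev_yaw <- psi_yaw[k]; prev_nod <- psi_nod[k]
  }

  structure(
    data.frame(window_index = seq_len(nw) - 1L,
               t_start = t0 + (seq_len(nw) - 1L) * window_s,
               blink_L = bl, blink_R = br,
               blink_any = as.integer(pmax(bl, br)),
               psi_yaw = psi_yaw, psi_nod = psi_nod, head_status = hs),
    class = c("window_status", "data.frame"))
}

window_means <- function(x, w, nw) {
  out <- rep(NA_real_, nw)
  m <- tapply(x, w, mean)
  out[as.integer(names(m)) + 1L] <- as.numeric(m)
  out
}

#' Turn per-window statuses into an annotation track
#'
#' Emits one event per flagged (window, category): `blink_left` and
#' `blink_right` for per-eye blink flags, `head_micro` for head status 1 and
#' `head_distinct` for status 2.  Events carry the window's absolute start
#' time as onset and a fixed 1-second duration.
#'
#' @param statuses a `window_status` data frame from [window_statuses()].
#' @param window_s event duration in seconds (default 1).
#' @return an `annotation_track` data frame with columns `onset`, `duration`,
#'   `label`, ordered by onset then label.
#' @export
annotate <- function(statuses, window_s = 1) {
  flagged <- list(blink_left = which(statuses$blink_L == 1L),
                  blink_right = which(statuses$blink_R == 1L),
                  head_micro = which(statuses$head_status == 1L),
                  head_distinct = which(statuses$head_status == 2L))
  rows <- lapply(names(flagged), function(lab) {
    idx <- flagged[[lab]]
    data.frame(onset = statuses$t_start[idx],
               label = rep(lab, length(idx)))
  })
  out <- do.call(rbind, rows)
  out$duration <- rep(window_s, nrow(out))
  out <- out[order(out$onset, match(out$label, ANNOTATION_LABELS)),
             c("onset", "duration", "label")]
  rownames(out) <- NULL
  structure(out, class = c("annotation_track", "data.frame"))
}

#' @export
print.annotation_track <- function(x, ...) {
  cat("<annotation_track> ", nrow(x), " event(s)\n", sep = "")
  if (nrow(x)) {
    tab <- table(factor(x$label, levels = ANNOTATION_LABELS))
    cat(" ", paste(names(tab), tab, sep = ": ", collapse = "  "), "\n")
  }
  invisible(x)
}

#' Read / write an annotation track as BIDS-style events TSV
#'
#' Tab-separated with header `onset  duration  label`; onsets in seconds.
#'
#' @param track an `annotation_track`.
#' @param path TSV file.
#' @return `read_events_tsv` returns an `annotation_track`.
#' @export
write_events_tsv <- function(track, path) {
  utils::write.table(as.data.frame(track)[, c("onset", "duration", "label")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "label")
  if (!all(need %in% names(df))) {
    stop("events file needs columns onset, duration, label", call. = FALSE)
  }
  if (any(df$onset < 0)) stop("event onsets must be >= 0", call. = FALSE)
  structure(df[, need], class = c("annotation_track", "data.frame"))
}

#' Project an annotation track onto EEG samples as an artifact mask
#'
#' An EEG sample is flagged for category c iff its timestamp falls inside the
#' half-open span `[onset, onset + duration)` of a c-labelled event; the
#' combined flag is the OR over categories.  Events lying entirely beyond the
#' end of the recording flag nothing (with a warning).
#'
#' @param track an `annotation_track`.
#' @param eeg an `eeg_recording` on the same clock.
#' @return an `artifact_mask` data frame with one row per EEG sample:
#'   `t`, one 0/1 column per category, and `any`.
#' @export
apply_mask <- function(track, eeg) {
  stopifnot(inherits(eeg, "eeg_recording"))
  t <- eeg_times(eeg)
  mask <- matrix(0L, nrow = length(t), ncol = length(ANNOTATION_LABELS),
                 dimnames = list(NULL, ANNOTATION_LABELS))
  if (length(t)) {
    for (k in seq_len(nrow(track))) {
      hit <- t >= track$onset[k] & t < track$onset[k] + track$duration[k]
      if (!any(hit) && track$onset[k] > t[length(t)]) {
        warning("event at ", track$onset[k], " s lies beyond the EEG end",
                call. = FALSE)
      }
      lab <- as.character(track$label[k])
      if (!lab %in% ANNOTATION_LABELS) {
        stop("unknown annotation label: ", lab, call. = FALSE)
      }
      mask[hit, lab] <- 1L
    }
  }
  out <- data.frame(t = t)
  out <- cbind(out, as.data.frame(mask))
  out$any <- as.integer(rowSums(mask) > 0)
  structure(out, class = c("artifact_mask", "data.frame"))
}

#' Write an artifact mask as CSV
#' @param mask an `artifact_mask`.
#' @param path output CSV.
#' @export
write_mask_csv <- function(mask, path) {
  utils::write.csv(as.data.frame(mask), path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Annotate a landmark stream end to end
#'
#' Convenience wrapper: [window_statuses()] then [annotate()], optionally
#' projecting the events onto an EEG recording with [apply_mask()].
#'
#' @inheritParams window_statuses
#' @param eeg optional `eeg_recording`; annotation itself needs landmarks
#'   only.
#' @return a list with `statuses`, `track` and (if EEG given) `mask`.
#' @export
annotate_stream <- function(stream, profile, eeg = NULL,
                            thresholds = c(10, 30), window_s = 1) {
  st <- window_statuses(stream, profile, thresholds, window_s)
  track <- annotate(st, window_s)
  out <- list(statuses = st, track = track)
  if (!is.null(eeg)) out$mask <- apply_mask(track, eeg)
  out
}

#' Raster plot of per-window artifact statuses
#'
#' One row per category, filled cells where the category is flagged; a quick
#' visual check of an annotation run.
#'
#' @param x a `window_status` data frame.
#' @param ... passed to [graphics::image()].
#' @export
plot.window_status <- function(x, ...) {
  z <- rbind(blink_left = x$blink_L == 1L,
             blink_right = x$blink_R == 1L,
             head_micro = x$head_status == 1L,
             head_distinct = x$head_status == 2L)
  z[is.na(z)] <- FALSE
  graphics::image(x = x$t_start + 0.5, y = seq_len(4), z = t(z * 1),
                  col = c("grey92", "firebrick"), axes = FALSE,
                  xlab = "time (s)", ylab = "", ...)
  graphics::axis(1)
  graphics::axis(2, at = seq_len(4), labels = rownames(z), las = 1,
                 tick = FALSE)
  graphics::box()
  invisible(x)
}
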