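# Blink detection from the eye aspect ratio (EAR).  Per frame and per eye,
# EAR is the sum of the two vertical eyelid distances over twice the
# horizontal eye-corner distance; it collapses toward zero when the eye
# closes.  Per one-second window, the minimum EAR is compared against the
# calibrated threshold (boundary inclusive): min <= threshold flags a blink.

#' Eye aspect ratio of one eye in one frame
#'
#' For the L block (scheme indices 36-41):
#' `(||p37 - p41|| + ||p38 - p40||) / (2 ||p36 - p39||)`;
#' for the R block (42-47):
#' `(||p43 - p47|| + ||p44 - p46||) / (2 ||p42 - p45||)`.
#' All norms Euclidean.  The ratio is invariant under rotation, translation
#' and uniform scaling of the frame.
#'
#' @param frame a `landmark_frame` or 68 x 2 matrix.
#' @param eye `"L"` or `"R"` (formula labels; see [eye_center()]).
#' @return the EAR, dimensionless and >= 0.
#' @export
compute_ear <- function(frame, eye = c("L", "R")) {
  eye <- match.arg(eye)
  i <- if (eye == "L") 36L else 42L
  horiz <- dist2(landmark_pt(frame, i), landmark_pt(frame, i + 3L))
  if (horiz <= 0) {
    stop("degenerate eye: zero horizontal span (", eye, " block)",
         call. = FALSE)
  }
  v1 <- dist2(landmark_pt(frame, i + 1L), landmark_pt(frame, i + 5L))
  v2 <- dist2(landmark_pt(frame, i + 2L), landmark_pt(frame, i + 4L))
  (v1 + v2) / (2 * horiz)
}

dist2 <- function(p, q) sqrt(sum((p - q)^2))

#' Per-frame EAR series for both eyes
#'
#' @param stream a `landmark_stream`.
#' @return an `ear_series` data frame with columns `t`, `ear_l`, `ear_r`,
#'   one row per frame in stream order.
#' @export
ear_series <- function(stream) {
  stopifnot(inherits(stream, "landmark_stream"))
  if (length(stream) == 0L) {
    return(structure(data.frame(t = numeric(0), ear_l = numeric(0),
                                ear_r = numeric(0)),
                     class = c("ear_series", "data.frame")))
  }
  el <- ear_column(stream, 36L)
  er <- ear_column(stream, 42L)
  structure(data.frame(t = stream$timestamp, ear_l = el, ear_r = er),
            class = c("ear_series", "data.frame"))
}

# vectorized EAR over a stream for the eye block starting at 0-based index i
ear_column <- function(stream, i) {
  horiz <- frame_distances(stream, i, i + 3L)
  bad <- which(horiz <= 0)
  if (length(bad)) {
    stop("degenerate eye (zero horizontal span) at frame index ",
         stream$frame_index[bad[1L]], call. = FALSE)
  }
  v1 <- frame_distances(stream, i + 1L, i + 5L)
  v2 <- frame_distances(stream, i + 2L, i + 4L)
  (v1 + v2) / (2 * horiz)
}

#' Per-second blink status from one window of EAR samples
#'
#' The window statistic is the minimum EAR over the window; the status is 1
#' (blink) when that minimum is less than or equal to the calibrated
#' threshold, else 0.  The boundary is inclusive: a minimum exactly at the
#' threshold flags a blink.
#'
#' @param window_ears numeric vector of EAR samples in one 1-s window
#'   (nominally `fps` of them; any non-empty count is accepted).
#' @param threshold calibrated blink threshold, EAR units.
#' @return integer 0 or 1.
#' @export
blink_status <- function(window_ears, threshold) {
  if (length(window_ears) == 0L) {
    stop("blink_status needs a non-empty window", call. = FALSE)
  }
  as.integer(min(window_ears) <= threshold)
}

# Per-window blink statuses for a whole series.  Windows are [w, w+1) seconds
# from the stream start; a trailing partial window still gets a status if it
# holds at least one sample.  Returns a data.frame(window, blink) with NA for
# windows that received no frames at all.
blink_window_statuses <- function(ears, threshold, t0, n_windows) {
  w <- window_index_of(ears$t, t0)
  out <- rep(NA_integer_, n_windows)
  mins <- tapply(ears$ear, w, min)
  idx <- as.integer(names(mins)) + 1L
  out[idx] <- as.integer(mins <= threshold)
  out
}
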