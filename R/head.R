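# Head-movement estimation from landmark geometry.
#
# Yaw: the eye centers A, B and the nose tip E form a roughly isosceles
# triangle; when the head turns, its projection on the image plane
# foreshortens the inter-ocular distance.  With AB the calibrated frontal
# inter-ocular distance, AC the current one, and theta the in-image angle at
# A between the rays toward B and toward E, the turn angle phi satisfies
#   cos(phi) = AC * sin(theta) / sqrt(AB^2 - AC^2 * cos^2(theta)),
# which equals 1 (phi = 0) whenever AC = AB, for any theta.  The lateral
# direction is read from the nose tip's x offset from the eye-center
# midpoint.
#
# Nod: with D' the calibrated baseline of d = |p27 - p30| (nose bridge top to
# tip), the nod angle is phi' = |d - D'| / D' * 90, in [0, 90] degrees.
#
# Per second, angles are averaged into psi; the second-to-second change
# |psi_t - psi_{t-1}| is classified per axis as static (<= 10 deg), micro
# (<= 30 deg) or distinct (> 30 deg), and the final status is the larger of
# the two axes.

#' Projected-triangle yaw cosine
#'
#' @param AB calibrated frontal inter-ocular distance, pixels (> 0).
#' @param AC current projected inter-ocular distance, pixels.
#' @param theta in-image angle at the L eye center between the rays toward the
#'   R eye center and toward the nose tip, radians, in (0, pi).
#' @return `cos(phi)`, clamped into [-1, 1].  When `AC * |cos(theta)| >= AB`
#'   (subject closer to the camera than at calibration) the value clamps to 1,
#'   i.e. the pose reads frontal.
#' @export
yaw_cosine <- function(AB, AC, theta) {
  if (AB <= 0) stop("inter-ocular baseline AB must be > 0", call. = FALSE)
  denom_sq <- AB^2 - AC^2 * cos(theta)^2
  if (denom_sq <= 0) return(1)
  min(1, max(-1, AC * sin(theta) / sqrt(denom_sq)))
}

#' Signed yaw angle of one frame
#'
#' Magnitude from [yaw_cosine()] with AC and theta measured on the frame and
#' AB from the calibration profile; sign from the nose tip's horizontal offset
#' from the eye-center midpoint (positive = nose right of midpoint).
#'
#' @param frame a `landmark_frame`.
#' @param profile a `calibration_profile`.
#' @return yaw in degrees, signed.
#' @export
yaw_angle <- function(frame, profile) {
  A <- eye_center(frame, "L")
  B <- eye_center(frame, "R")
  E <- as.numeric(landmark_pt(frame, NOSE_TIP_IDX))
  AC <- sqrt(sum((B - A)^2))
  if (AC <= 0) stop("degenerate frame: coincident eye centers", call. = FALSE)
  theta <- angle_between(B - A, E - A)
  magnitude <- acos(yaw_cosine(profile$interocular_baseline_AB, AC, theta)) *
    180 / pi
  s <- if (E[1L] < (A[1L] + B[1L]) / 2) -1 else 1
  s * magnitude
}

angle_between <- function(u, v) {
  cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(min(1, max(-1, cosang)))
}

#' Nod angle of one frame
#'
#' `phi' = |d - D'| / D' * 90` with `d = ||p27 - p30||` and D' the calibrated
#' baseline; clamped into [0, 90] degrees.  The nod direction is discarded.
#'
#' @param frame a `landmark_frame`.
#' @param profile a `calibration_profile` with `nod_baseline_D > 0`.
#' @return nod angle in degrees, in [0, 90].
#' @export
nod_angle <- function(frame, profile) {
  d <- dist2(landmark_pt(frame, NOSE_BRIDGE_IDX),
             landmark_pt(frame, NOSE_TIP_IDX))
  nod_from_d(d, profile$nod_baseline_D)
}

nod_from_d <- function(d, Dprime) {
  pmin(90, abs(d - Dprime) / Dprime * 90)
}

#' Per-frame yaw and nod angle series
#'
#' @param stream a `landmark_stream`.
#' @param profile a `calibration_profile`.
#' @return a `head_angle_series` data frame with columns `t`, `yaw_deg`
#'   (signed), `nod_deg` (in [0, 90]).
#' @export
head_angle_series <- function(stream, profile) {
  stopifnot(inherits(stream, "landmark_stream"),
            inherits(profile, "calibration_profile"))
  n <- length(stream)
  if (n == 0L) {
    return(structure(data.frame(t = numeric(0), yaw_deg = numeric(0),
                                nod_deg = numeric(0)),
                     class = c("head_angle_series", "data.frame")))
  }
  AB <- profile$interocular_baseline_AB
  cl <- eye_center_series(stream, "L")
  cr <- eye_center_series(stream, "R")
  ex <- stream$coords[, 2L * NOSE_TIP_IDX + 1L]
  ey <- stream$coords[, 2L * NOSE_TIP_IDX + 2L]
  ux <- cr[, 1L] - cl[, 1L]; uy <- cr[, 2L] - cl[, 2L]
  vx <- ex - cl[, 1L];       vy <- ey - cl[, 2L]
  AC <- sqrt(ux^2 + uy^2)
  if (any(AC <= 0)) {
    stop("degenerate frame: coincident eye centers at frame index ",
         stream$frame_index[which(AC <= 0)[1L]], call. = FALSE)
  }
  costh <- pmin(1, pmax(-1, (ux * vx + uy * vy) / (AC * sqrt(vx^2 + vy^2))))
  sinth <- sqrt(1 - costh^2)
  denom_sq <- AB^2 - AC^2 * costh^2
  cosphi <- ifelse(denom_sq <= 0, 1,
                   pmin(1, pmax(-1, AC * sinth / sqrt(pmax(denom_sq, 0)))))
  sgn <- ifelse(ex < (cl[, 1L] + cr[, 1L]) / 2, -1, 1)
  yaw <- sgn * acos(cosphi) * 180 / pi
  d <- frame_distances(stream, NOSE_BRIDGE_IDX, NOSE_TIP_IDX)
  structure(data.frame(t = stream$timestamp, yaw_deg = yaw,
                       nod_deg = nod_from_d(d, profile$nod_baseline_D)),
            class = c("head_angle_series", "data.frame"))
}

#' Mean head angle over one 1-s window
#'
#' psi, the window's representative head angle, is the arithmetic mean of the
#' per-frame angles falling in the window (nominally fps of them).
#'
#' @param frame_angles numeric vector of angles (degrees) in one window.
#' @return psi in degrees.
#' @export
window_mean_angle <- function(frame_angles) {
  if (length(frame_angles) == 0L) {
    stop("window_mean_angle needs a non-empty window", call. = FALSE)
  }
  mean(frame_angles)
}

#' Head-movement status from second-to-second angle change
#'
#' Per axis, the relative change is `|psi_t - psi_prev|`; it classifies as 0
#' (static) when <= 10 degrees, 1 (micro movement) when in (10, 30], and 2
#' (distinct movement) when > 30.  Yaw and nod axes are classified separately
#' and the final status is the larger of the two.  The first window of a
#' session, having no predecessor, is static by convention.
#'
#' @param psi_yaw,psi_nod current-window mean angles, degrees.
#' @param psi_yaw_prev,psi_nod_prev previous-window mean angles, or `NA` for
#'   the first window.
#' @param thresholds length-2 numeric, the micro and distinct boundaries in
#'   degrees (default `c(10, 30)`).
#' @return integer status in {0, 1, 2}.
#' @export
head_status <- function(psi_yaw, psi_yaw_prev, psi_nod, psi_nod_prev,
                        thresholds = c(10, 30)) {
  max(axis_status(psi_yaw, psi_yaw_prev, thresholds),
      axis_status(psi_nod, psi_nod_prev, thresholds))
}

#' @rdname head_status
#' @param psi_t,psi_prev one axis's current and previous window mean angle.
#' @export
axis_status <- function(psi_t, psi_prev, thresholds = c(10, 30)) {
  if (is.na(psi_prev) || is.na(psi_t)) return(0L)
  rel <- abs(psi_t - psi_prev)
  if (rel <= thresholds[1L]) 0L else if (rel <= thresholds[2L]) 1L else 2L
}
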