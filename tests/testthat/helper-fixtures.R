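# Shared fixtures, all built in code.

# random but valid landmark stream (coordinates have no facial structure;
# used for I/O round-trips and container invariants only)
random_stream <- function(n = 50, fps = 25, seed = 1) {
  set.seed(seed)
  coords <- matrix(runif(n * 136, 0, 640), nrow = n)
  landmark_stream(seq_len(n) - 1L, (seq_len(n) - 1L) / fps, coords, fps = fps)
}

# a frame with a hand-placed L eye of known EAR and sane remaining points
toy_eye_frame <- function() {
  pts <- unclass(face_template())
  # printed-geometry toy eye: corners (0,0)-(4,0), lids one pixel off-axis
  pts[37:42, ] <- rbind(c(0, 0), c(1, 1), c(3, 1),
                        c(4, 0), c(3, -1), c(1, -1))
  landmark_frame(pts)
}

# calibration profile matched to the synthetic face template, exact values
template_profile <- function() {
  calibration_profile(blink_threshold_L = 0.05, blink_threshold_R = 0.05,
                      nod_baseline_D = 60, interocular_baseline_AB = 120,
                      fps = 25, calibration_n = 1500L)
}

# short noiseless calibration -> profile (suppress the sub-60 s warning)
quick_profile <- function(duration = 5, jitter = 0, seed = 1) {
  segs <- calibration_segments(duration = duration, jitter_sigma = jitter,
                               seed = seed)
  suppressWarnings(calibrate_profile(segs$closed, segs$frontal))
}
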