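test_that("the face template is deterministic with the stated geometry", {
  f <- face_template()
  expect_identical(f, face_template())
  expect_equal(compute_ear(f, "L"), 0.3, tolerance = 1e-9)
  expect_equal(compute_ear(f, "R"), 0.3, tolerance = 1e-9)
  d <- sqrt(sum((landmark_pt(f, 27) - landmark_pt(f, 30))^2))
  expect_equal(d, 60)
  expect_equal(sqrt(sum((eye_center(f, "L") - eye_center(f, "R"))^2)), 120)
})

test_that("event scripts validate their fields and reject overlaps", {
  expect_error(event_script(0, 1, "wink", 1), "unknown event kind")
  expect_error(event_script(-1, 1, "yaw", 20), ">= 0")
  expect_error(event_script(0, 1, "blink_L", 1.2), "depth fraction")
  expect_error(event_script(c(1, 1.1), c(0.5, 0.5),
                            c("blink_L", "blink_both"), c(1, 1)),
               "overlapping")
  # different axes may overlap freely
  s <- event_script(c(1, 1), c(1, 1), c("yaw", "nod"), c(20, 20))
  expect_equal(nrow(s), 2L)
})

test_that("an empty script renders a constant stream with empty truth", {
  scene <- render_stream(event_script(), duration = 3, jitter_sigma = 0)
  expect_equal(length(scene$stream), 75L)
  expect_true(all(apply(scene$stream$coords, 2, function(col)
    all(col == col[1]))))
  expect_true(all(lengths(scene$truth) == 0))
})

test_that("generators are bit-reproducible given the seed", {
  script <- scripted_preset("random", duration = 40, n_events = 8, seed = 3)
  expect_identical(script,
                   scripted_preset("random", duration = 40, n_events = 8,
                                   seed = 3))
  a <- render_stream(script, 40, jitter_sigma = 0.7, seed = 5)
  b <- render_stream(script, 40, jitter_sigma = 0.7, seed = 5)
  expect_identical(a$stream$coords, b$stream$coords)
  e1 <- render_eeg(script, 40, fs = 100, seed = 5)
  expect_identical(e1$samples, render_eeg(script, 40, fs = 100,
                                          seed = 5)$samples)
})

test_that("a full-depth blink_both yields truth seconds for both eyes", {
  scene <- render_stream(event_script(3, 0.2, "blink_both", 1), duration = 6)
  expect_equal(scene$truth$blink_left, 3L)
  expect_equal(scene$truth$blink_right, 3L)
  expect_equal(scene$truth$head_micro, integer(0))
})

test_that("rendered blink frames have strictly lower EAR than the rest", {
  scene <- render_stream(event_script(2, 0.3, "blink_L", 0.7),
                         duration = 5, jitter_sigma = 0.2, seed = 9)
  es <- ear_series(scene$stream)
  blinkframes <- es$t >= 2 & es$t < 2.3
  expect_lt(max(es$ear_l[blinkframes]), min(es$ear_l[!blinkframes]))
})

test_that("the demo preset carries the documented ground truth", {
  scene <- render_stream(scripted_preset("demo"), duration = 24)
  expect_equal(scene$truth$blink_left, c(4L, 13L))
  expect_equal(scene$truth$blink_right, c(4L, 13L))
  expect_equal(scene$truth$head_micro, 8L)
  expect_equal(scene$truth$head_distinct, 16L)
  # the two turns go in opposite directions
  expect_equal(range(scene$angles$yaw_deg), c(-20, 20))
})

test_that("synthetic EEG has the scripted artifact structure", {
  quiet <- render_eeg(event_script(), duration = 10, fs = 250, seed = 2)
  rms <- sqrt(mean(quiet$samples[1, ]^2))
  expect_lt(rms, 20)  # baseline-only: no deflection beyond the noise floor
  one <- render_eeg(event_script(5, 0.4, "blink_both", 1), duration = 10,
                    fs = 250, seed = 2)
  t <- eeg_times(one)
  span <- t >= 5 & t < 5.4
  expect_gt(max(one$samples["Fp1", span]), 3 * rms)
  # blink deflections are frontal: occipital channels keep baseline scale
  expect_lt(max(abs(one$samples["O1", span])), 6 * rms)
  # head drifts hit every channel
  hm <- render_eeg(event_script(5, 1, "yaw", 40), duration = 10, fs = 250,
                   seed = 2)
  expect_gt(max(abs(hm$samples["O1", t >= 5 & t < 6])), 3 * rms)
})

test_that("calibration segments have the nominal size and EAR levels", {
  segs <- calibration_segments(fps = 25, duration = 60, jitter_sigma = 0.5,
                               seed = 6)
  expect_equal(length(segs$closed), 1500L)  # 60 s at 25 fps
  expect_equal(length(segs$frontal), 1500L)
  thr <- calibrate_blink_threshold(ear_series(segs$closed)$ear_l)
  expect_lt(abs(thr - 0.05), 0.02)
  expect_lt(abs(calibrate_interocular(segs$frontal) - 120), 0.5)
})

test_that("noiseless end-to-end recovery is exact per category", {
  prof <- quick_profile(duration = 5)
  for (sd in c(1, 2)) {
    script <- scripted_preset("random", duration = 60, n_events = 10,
                              seed = sd)
    scene <- render_stream(script, 60, jitter_sigma = 0, seed = sd)
    st <- window_statuses(scene$stream, prof)
    expect_identical(st$window_index[st$blink_L == 1L],
                     scene$truth$blink_left)
    expect_identical(st$window_index[st$blink_R == 1L],
                     scene$truth$blink_right)
    expect_identical(st$window_index[st$head_status == 1L],
                     scene$truth$head_micro)
    expect_identical(st$window_index[st$head_status == 2L],
                     scene$truth$head_distinct)
  }
})
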