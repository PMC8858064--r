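test_that("a motionless open-eye stream produces all-zero statuses", {
  scene <- render_stream(event_script(), duration = 6)
  st <- window_statuses(scene$stream, template_profile())
  expect_equal(nrow(st), 6L)
  expect_true(all(st$blink_L == 0L & st$blink_R == 0L & st$head_status == 0L))
  expect_equal(nrow(annotate(st)), 0L)
})

test_that("the 24-s demonstration scenario flags exactly its scripted windows", {
  scene <- render_stream(scripted_preset("demo"), duration = 24)
  st <- window_statuses(scene$stream, quick_profile())
  expect_equal(st$window_index[st$blink_any == 1L], c(4, 13))
  expect_equal(st$window_index[st$head_status == 1L], 8)
  expect_equal(st$window_index[st$head_status == 2L], 16)
})

test_that("a blink and a distinct turn in one window flag both categories", {
  script <- event_script(onset = c(2.2, 2), duration = c(0.3, 1),
                         kind = c("blink_both", "yaw"), magnitude = c(1, 40))
  scene <- render_stream(script, duration = 5)
  st <- window_statuses(scene$stream, template_profile())
  w2 <- st[st$window_index == 2, ]
  expect_equal(w2$blink_L, 1L)
  expect_equal(w2$blink_R, 1L)
  expect_equal(w2$head_status, 2L)
  track <- annotate(st)
  expect_setequal(track$label[track$onset == 2],
                  c("blink_left", "blink_right", "head_distinct"))
})

test_that("annotate emits one event per flagged window and category", {
  st <- window_statuses(render_stream(event_script(), 3)$stream,
                        template_profile())
  # hand-edit statuses: counting oracle
  st$blink_L[1] <- 1L; st$head_status[2] <- 2L; st$head_status[3] <- 1L
  track <- annotate(st)
  expect_equal(track$label, c("blink_left", "head_distinct", "head_micro"))
  expect_equal(track$onset, c(0, 1, 2))
  expect_true(all(track$duration == 1))
  # determinism: identical inputs give identical tracks
  expect_identical(annotate(st), track)
})

test_that("events round-trip through the TSV format", {
  st <- window_statuses(render_stream(scripted_preset("demo"), 24)$stream,
                        quick_profile())
  track <- annotate(st)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(track, path)
  expect_equal(readLines(path, n = 1), "onset\tduration\tlabel")
  expect_equal(read_events_tsv(path), track, ignore_attr = TRUE)
})

test_that("the artifact mask flags fs x duration samples per event", {
  track <- structure(data.frame(onset = 3, duration = 1,
                                label = "blink_left"),
                     class = c("annotation_track", "data.frame"))
  eeg <- render_eeg(event_script(), duration = 10, fs = 250)
  mask <- apply_mask(track, eeg)
  expect_equal(sum(mask$blink_left), 250L)
  expect_equal(sum(mask$any), 250L)
  expect_true(all(mask$t[mask$blink_left == 1] >= 3 &
                    mask$t[mask$blink_left == 1] < 4))
  # brute-force per-sample interval test agrees exactly
  brute <- as.integer(mask$t >= 3 & mask$t < 4)
  expect_identical(mask$blink_left, brute)
  # empty track -> all-false mask; out-of-range event flags nothing
  expect_equal(sum(apply_mask(track[0, ], eeg)$any), 0L)
  far <- track; far$onset <- 99
  expect_warning(m2 <- apply_mask(far, eeg), "beyond")
  expect_equal(sum(m2$any), 0L)
})

test_that("mask sample counts equal the per-event sums for random tracks", {
  set.seed(77)
  eeg <- render_eeg(event_script(), duration = 30, fs = 125)
  t <- eeg_times(eeg)
  for (k in 1:5) {
    onsets <- sort(sample(0:29, 6))
    labs <- sample(c("blink_left", "blink_right", "head_micro",
                     "head_distinct"), 6, replace = TRUE)
    track <- structure(data.frame(onset = onsets, duration = 1, label = labs),
                       class = c("annotation_track", "data.frame"))
    mask <- apply_mask(track, eeg)
    for (lab in unique(labs)) {
      ev <- track[track$label == lab, ]
      brute <- Reduce(`|`, lapply(seq_len(nrow(ev)), function(i)
        t >= ev$onset[i] & t < ev$onset[i] + ev$duration[i]))
      expect_identical(mask[[lab]], as.integer(brute))
    }
  }
})

test_that("downsampling to the analysis rate takes block means", {
  # 250 Hz ramp 0..249 down to 25 Hz: first block mean is mean(0:9) = 4.5
  eeg <- eeg_recording(matrix(0:249, nrow = 1), 250, "Cz")
  down <- downsample_to_windows(eeg, 25)
  expect_equal(ncol(down$samples), 25L)
  expect_equal(down$samples[1, 1], 4.5, ignore_attr = TRUE)
  expect_equal(down$samples[1, ], seq(4.5, 244.5, by = 10),
               ignore_attr = TRUE)
  # constant channel stays constant; identity at the native rate
  const <- eeg_recording(matrix(7, 2, 100), 250, c("a", "b"))
  expect_true(all(downsample_to_windows(const, 25)$samples == 7))
  same <- downsample_to_windows(eeg, 250)
  expect_equal(same$samples, eeg$samples, tolerance = 1e-12)
  expect_error(downsample_to_windows(eeg, -1), "positive")
})

test_that("EEG round-trips through CSV", {
  eeg <- render_eeg(event_script(), duration = 2, fs = 100, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_eeg_csv(eeg, path)
  back <- read_eeg_csv(path, sample_rate = 100)
  expect_equal(back$channel_names, eeg$channel_names)
  expect_equal(back$samples, eeg$samples, tolerance = 1e-6)
})

test_that("timestamps, not frame counts, drive window assignment", {
  # drop all frames of second 2 entirely: later windows keep their indices
  scene <- render_stream(event_script(onset = 4.2, duration = 0.3,
                                      kind = "blink_both", magnitude = 1),
                         duration = 6)
  s <- scene$stream
  keep <- !(s$timestamp >= 2 & s$timestamp < 3)
  gappy <- landmark_stream(s$frame_index[keep], s$timestamp[keep],
                           s$coords[keep, ], fps = s$fps)
  st <- window_statuses(gappy, template_profile())
  expect_equal(nrow(st), 6L)
  expect_true(is.na(st$blink_L[st$window_index == 2]))
  expect_equal(st$window_index[which(st$blink_L == 1L)], 4)
})
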