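test_that("yaw cosine matches direct substitution and the frontal identity", {
  # AB = 2, AC = 1, theta = 90 deg: denominator = AB, so cos(phi) = 1/2
  expect_equal(yaw_cosine(2, 1, pi / 2), 0.5)
  # frontal identity: AC = AB gives cos(phi) = 1 for any theta in (0, pi)
  for (th in c(0.2, pi / 3, pi / 2, 2.8)) {
    expect_equal(yaw_cosine(1.7, 1.7, th), 1, tolerance = 1e-12)
  }
  expect_error(yaw_cosine(0, 1, pi / 2), "AB")
})

test_that("yaw angle is zero at the frontal pose and inverts a known turn", {
  prof <- template_profile()
  expect_equal(yaw_angle(face_template(), prof), 0, tolerance = 1e-9)
  # eye-center distance AB*cos(40 deg) with the nose on the perpendicular
  # bisector (theta = 90 deg) must read as a 40-degree turn
  pts <- unclass(face_template())
  AC <- 120 * cos(40 * pi / 180)
  eye_l <- pts[37:42, ]; eye_r <- pts[43:48, ]
  pts[37:42, 1] <- eye_l[, 1] + ((320 - AC / 2) - 260)
  pts[43:48, 1] <- eye_r[, 1] + ((320 + AC / 2) - 380)
  pts[31, ] <- c(320 - AC / 2, 280)   # directly below the L eye center
  expect_equal(abs(yaw_angle(landmark_frame(pts), prof)), 40,
               tolerance = 1e-9)
  # coincident eye centers are degenerate
  bad <- unclass(face_template())
  bad[43:48, ] <- bad[37:42, ]
  expect_error(yaw_angle(landmark_frame(bad), prof), "degenerate")
})

test_that("x-mirroring flips the yaw sign but keeps its magnitude", {
  prof <- quick_profile()
  scene <- render_stream(event_script(onset = 1, duration = 1, kind = "yaw",
                                      magnitude = 25), duration = 3)
  f <- get_frame(scene$stream, 60)  # held at +25 degrees
  y1 <- yaw_angle(f, prof)
  mirrored <- landmark_frame(cbind(640 - unclass(f)[, 1], unclass(f)[, 2]))
  y2 <- yaw_angle(mirrored, prof)
  expect_equal(y1, 25, tolerance = 1e-6)
  expect_equal(y2, -y1, tolerance = 1e-9)
})

test_that("yaw is invariant to joint translation and scaling", {
  scene <- render_stream(event_script(onset = 1, duration = 1, kind = "yaw",
                                      magnitude = 30), duration = 3)
  f <- unclass(get_frame(scene$stream, 70))
  base <- yaw_angle(landmark_frame(f), template_profile())
  for (s in c(0.5, 2.4)) {
    g <- landmark_frame(f * s + matrix(c(17, -40), 68, 2, byrow = TRUE))
    prof_s <- calibration_profile(0.05, 0.05, 60 * s, 120 * s)
    expect_equal(yaw_angle(g, prof_s), base, tolerance = 1e-9)
  }
})

test_that("nod angle follows |d - D'| / D' * 90, clamped to [0, 90]", {
  prof12 <- calibration_profile(0.05, 0.05, 12, 120)
  mk <- function(d) {
    pts <- unclass(face_template())
    pts[31, ] <- pts[28, ] + c(0, d)
    landmark_frame(pts)
  }
  expect_equal(nod_angle(mk(12), prof12), 0)
  expect_equal(nod_angle(mk(0), prof12), 90)
  expect_equal(nod_angle(mk(9), prof12), 22.5)
  # clamp: d far beyond the baseline cannot exceed 90
  expect_equal(nod_angle(mk(100), prof12), 90)
  set.seed(3)
  for (d in runif(20, 0, 200)) {
    na <- nod_angle(mk(d), prof12)
    expect_gte(na, 0); expect_lte(na, 90)
    if (abs(d - 12) > 1e-9 && abs(d - 12) / 12 * 90 < 90) expect_gt(na, 0)
  }
})

test_that("window mean angle averages the window's samples", {
  expect_equal(window_mean_angle(rep(12, 25)), 12)
  expect_equal(window_mean_angle(c(0, 30)), 15)
  expect_error(window_mean_angle(numeric(0)), "non-empty")
  set.seed(31)
  x <- runif(25, 10, 20)
  se <- (20 - 10) / sqrt(12) / sqrt(25)
  expect_lt(abs(window_mean_angle(x) - 15), 3 * se)
})

test_that("head status thresholds are boundary-correct and use the max axis", {
  expect_equal(axis_status(10, 0), 0L)     # change of exactly 10 -> static
  expect_equal(axis_status(30, 0), 1L)     # exactly 30 -> micro
  expect_equal(axis_status(30.01, 0), 2L)  # just past 30 -> distinct
  expect_equal(axis_status(5, NA), 0L)     # first window convention
  # vertical and horizontal scored separately, the bigger one wins
  expect_equal(head_status(20, 0, 50, 0), 2L)
  expect_equal(head_status(50, 0, 20, 0), 2L)
  expect_equal(head_status(0, 0, 0, 0), 0L)
})

test_that("head status is non-decreasing in the relative angle change", {
  deltas <- sort(runif(40, 0, 60))
  st <- vapply(deltas, function(d) axis_status(d, 0), integer(1))
  expect_true(all(diff(st) >= 0))
})

test_that("per-window statuses match a direct reimplementation on true angles", {
  # scripted step function of yaw with known per-second true means
  script <- event_script(onset = c(3, 6, 10), duration = rep(1, 3),
                         kind = rep("yaw", 3), magnitude = c(15, 35, 12))
  scene <- render_stream(script, duration = 13)
  st <- window_statuses(scene$stream, template_profile())
  # independent oracle: average the true angles per window, difference,
  # threshold
  w <- floor(scene$angles$t)
  psi <- tapply(scene$angles$yaw_deg, w, mean)
  expected <- integer(length(psi))
  for (k in seq_along(psi)) {
    if (k == 1) next
    rel <- abs(psi[k] - psi[k - 1])
    expected[k] <- if (rel <= 10) 0L else if (rel <= 30) 1L else 2L
  }
  expect_equal(st$psi_yaw, as.numeric(psi), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(st$head_status, expected)
})
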