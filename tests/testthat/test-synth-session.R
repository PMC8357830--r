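test_that("identical scripts generate bit-identical sessions", {
  script <- session_script(calibration_points_9(), seed = 42)
  s1 <- generate_gaze_session(script)
  s2 <- generate_gaze_session(script)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$fixations, s2$fixations)
})

test_that("changing only the seed keeps targets but changes noise", {
  tg <- model_selection_targets()
  s1 <- generate_gaze_session(session_script(tg, seed = 1))
  s2 <- generate_gaze_session(session_script(tg, seed = 2))
  expect_identical(s1$frames$target, s2$frames$target)
  expect_identical(s1$frames$gx, s2$frames$gx)
  expect_false(isTRUE(all.equal(s1$frames$x, s2$frames$x)))
})

test_that("scripts reject overlapping targets, bad durations, off-screen points", {
  tg <- target_sequence(c(0.2, 0.8), c(0.2, 0.2), duration = 2)
  tg$onset[2] <- 1  # overlaps the first interval
  expect_error(session_script(tg), "overlap")
  tg2 <- target_sequence(0.5, 0.5, duration = 1)
  tg2$duration <- -1
  expect_error(session_script(tg2), "positive")
  expect_error(session_script(target_sequence(1.5, 0.2)), "display region")
})

test_that("noise-free linear-map sessions are exactly invertible by the 8-term model", {
  script <- session_script(calibration_points_9(), noise = no_noise(), seed = 1)
  sess <- generate_gaze_session(script, forward_map = linear_forward_map())
  fx <- dplyr::filter(sess$fixations, eye == "left")
  expect_equal(nrow(fx), 9)
  m <- suppressWarnings(
    append_sample(gaze_model(default_gaze_spec()), fx, fx[, c("gx", "gy")])
  )
  pred <- predict(m, fx)
  expect_lt(max(abs(pred$gx - fx$gx)), 1e-9)
  expect_lt(max(abs(pred$gy - fx$gy)), 1e-9)
})

test_that("the 8-pose protocol yields 120 fixations in 8 pose clusters", {
  sess <- generate_gaze_session(script_model_selection(seed = 3))
  fx <- dplyr::filter(sess$fixations, eye == "left")
  expect_equal(nrow(fx), 15 * 8)
  poses <- unique(round(cbind(fx$dm, fx$dn), 6))
  expect_equal(nrow(poses), 8)
})

test_that("step pose schedules shift the corner exactly and leave x,y pose-consistent", {
  tg <- target_sequence(rep(0.5, 4), rep(0.3, 4), duration = 1)
  pose <- pose_schedule(t = 2, dm = 10, dn = -5)
  sess <- generate_gaze_session(session_script(tg, pose = pose, noise = no_noise()),
                                forward_map = linear_forward_map())
  fx <- dplyr::filter(sess$fixations, eye == "left")
  expect_equal(fx$m[3] - fx$m[1], 10)
  expect_equal(fx$n[3] - fx$n[1], -5)
  # linear map has no pose->pupil coupling: x, y unchanged by the step
  expect_equal(fx$x[3], fx$x[1], tolerance = 1e-12)
})

test_that("fixation validity follows the 50% valid-frame quota", {
  # all-blink fixations via a blink lasting the whole session
  script <- session_script(
    target_sequence(0.5, 0.4, duration = 1),
    noise = noise_params(blink_rate = 0, drift_sd = 0),
    seed = 1
  )
  sess <- generate_gaze_session(script)
  expect_true(all(sess$fixations$valid))
  blinky <- sess$frames
  expect_false(any(is.na(blinky$x[blinky$valid])))
})

test_that("forward-map consistency: any spec family refits its own data exactly", {
  # build a session whose features come from an 8-term model family by
  # construction (linear map), fit on 9 points, predict a held-out grid
  calib <- calibration_points_9()
  probe <- accuracy_grid_targets()[1:20, ]
  probe$onset <- max(calib$onset + calib$duration) +
    c(0, cumsum(probe$duration[-20]))
  probe$target <- 9 + seq_len(20)
  script <- session_script(dplyr::bind_rows(calib, probe), noise = no_noise())
  sess <- generate_gaze_session(script, forward_map = linear_forward_map())
  fx <- dplyr::filter(sess$fixations, eye == "left")
  m <- suppressWarnings(
    append_sample(gaze_model(), fx[1:9, ], fx[1:9, c("gx", "gy")])
  )
  pred <- predict(m, fx[10:29, ])
  err <- sqrt((pred$gx - fx$gx[10:29])^2 + (pred$gy - fx$gy[10:29])^2)
  expect_lt(max(err), 1e-9)
})

test_that("session records round-trip through JSON-lines + CSV", {
  sess <- generate_gaze_session(
    session_script(target_sequence(c(0.3, 0.7), c(0.3, 0.3)), seed = 5),
    eyes = "left"
  )
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_session_jsonl(sess, path)
  back <- read_session_jsonl(path)
  expect_equal(nrow(back$frames), nrow(sess$frames))
  expect_equal(back$frames$x, sess$frames$x, tolerance = 1e-12)
  expect_equal(back$fixations$gx, sess$fixations$gx, tolerance = 1e-12)
})

test_that("protocol constructors encode the published layouts", {
  calib <- calibration_points_9()
  expect_equal(nrow(calib), 9)
  expect_equal(sum(calib$duration), 27)
  expect_equal(nrow(model_selection_targets()), 15)
  grid <- accuracy_grid_targets()
  expect_equal(nrow(grid), 180)
  expect_equal(unique(grid$duration), 1)
  # grid centers lie strictly inside the display
  expect_true(all(grid$gx > 0 & grid$gx < 1))
  expect_true(all(grid$gy > 0 & grid$gy < screen_geometry()$height))
})
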