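test_that("noise-free in-family sessions give near-zero stepwise errors", {
  calib <- calibration_points_9()
  extra <- accuracy_grid_targets()[seq(1, 180, by = 12), ]
  extra$onset <- 27 + seq(0, by = 1, length.out = nrow(extra))
  extra$target <- 9 + seq_len(nrow(extra))
  script <- session_script(dplyr::bind_rows(calib, extra), noise = no_noise())
  sess <- generate_gaze_session(script, forward_map = linear_forward_map())
  sw <- stepwise_errors(sess, n_init = 9)
  ok <- sw$prediction_defined
  expect_true(all(sw$error_regression[ok] < 1e-6))
  expect_true(all(sw$error_prediction[ok] < 1e-6))
  expect_true(all(sw$error_fixed[ok] < 1e-6))
})

test_that("mean regression error does not exceed mean prediction error", {
  for (s in 1:3) {
    sess <- generate_gaze_session(script_model_selection(seed = s))
    sw <- stepwise_errors(sess, n_init = 15)
    ok <- sw$prediction_defined
    expect_lte(mean(sw$error_regression[ok]),
               mean(sw$error_prediction[ok]) + 0.05)
  }
})

test_that("stationary-pose sessions keep fixed and progressive models close", {
  calib <- calibration_points_9()
  extra <- accuracy_grid_targets()[seq(3, 180, by = 9), ]
  extra$onset <- 27 + seq(0, by = 1, length.out = nrow(extra))
  extra$target <- 9 + seq_len(nrow(extra))
  script <- session_script(dplyr::bind_rows(calib, extra), seed = 11)
  sess <- generate_gaze_session(script)  # no pose schedule at all
  sw <- stepwise_errors(sess, n_init = 9)
  ok <- sw$prediction_defined
  ratio <- mean(sw$error_fixed[ok]) / mean(sw$error_prediction[ok])
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("pose changes blow up the fixed model but not the progressive one", {
  sess <- generate_gaze_session(script_model_selection(seed = 2))
  sw <- stepwise_errors(sess, n_init = 15)
  after <- sw[sw$event > 15 & sw$prediction_defined, ]
  expect_gt(mean(after$error_fixed), 2 * mean(after$error_prediction))
})

test_that("percentiles interpolate linearly and validate inputs", {
  expect_equal(percentile_error(c(1, 2, 3, 4, 5), 50), 3)
  expect_equal(percentile_error(rep(7, 10), 95), 7)
  expect_equal(percentile_error(c(1, 2, 3, 4, 5), 75), 4)
  expect_error(percentile_error(numeric(0), 50), "Empty")
  expect_error(percentile_error(1:5, 0), "between")
  expect_error(percentile_error(1:5, 100), "between")
})

test_that("compare_models flags specs with insufficient events", {
  short <- generate_gaze_session(
    session_script(model_selection_targets(), seed = 4)
  )
  cmp <- compare_models(short, n_init = 9)
  tab <- tibble::as_tibble(cmp)
  expect_false(tab$evaluated[tab$n_terms == 15])
  expect_true(tab$evaluated[tab$n_terms == 8])
  # a single spec yields a one-row table
  one <- compare_models(short, default_gaze_spec(), n_init = 9)
  expect_equal(nrow(tibble::as_tibble(one)), 1)
})

test_that("sessions drawn from the 8-term family give ~0 for the 8-term model", {
  # static pose: every event stays inside the observed feature span, so the
  # in-family (linear) map is recovered exactly despite single-pose rank
  # deficiency of the corner columns
  sess <- generate_gaze_session(
    session_script(script_model_selection(seed = 5)$targets,
                   noise = no_noise()),
    forward_map = linear_forward_map()
  )
  cmp <- tibble::as_tibble(compare_models(sess, n_init = 15))
  row8 <- cmp[cmp$n_terms == 8, ]
  expect_lt(row8$mean_regression, 1e-6)
  expect_lt(row8$mean_prediction, 1e-6)
  # across unseen poses, in-sample (regression) error stays ~0 while
  # prediction picks up error only at pose-entry events
  sess2 <- generate_gaze_session(
    session_script(script_model_selection(seed = 5)$targets,
                   pose = script_model_selection(seed = 5)$pose,
                   noise = no_noise()),
    forward_map = linear_forward_map()
  )
  sw <- stepwise_errors(sess2, n_init = 15)
  expect_lt(mean(sw$error_regression), 1e-6)
  at_entry <- sw$head_disp > 1e-9
  expect_true(all(sw$error_prediction[!at_entry & sw$prediction_defined] < 1e-6))
})

test_that("head displacement tracks scripted pose steps", {
  tg <- target_sequence(rep(c(0.3, 0.7), 3), rep(0.4, 6), duration = 1)
  # step aligned to the boundary between fixations 2 and 3
  pose <- pose_schedule(t = 2, dm = 10, dn = 0)
  sess <- generate_gaze_session(
    session_script(tg, pose = pose, noise = no_noise()),
    forward_map = linear_forward_map()
  )
  hd <- head_displacement(sess)
  expect_equal(hd$displacement[3], 10, tolerance = 1e-9)
  expect_true(all(hd$displacement[c(2, 4, 5, 6)] < 1e-9))
  # absolute-from-first variant
  hd0 <- head_displacement(sess, from = "first")
  expect_equal(hd0$displacement, c(0, 0, 10, 10, 10, 10), tolerance = 1e-9)
  # mm conversion is a pure scale factor
  hdmm <- head_displacement(sess, mm_per_px = 0.05)
  expect_equal(hdmm$displacement_mm, hd$displacement * 0.05)
})

test_that("stepwise errors are invariant under joint screen rescaling", {
  # rescaling all targets (and the forward map reading them) by the same
  # screen transform leaves %-of-width errors unchanged; here we check the
  # algebraic half: scaling G after generation
  sess <- generate_gaze_session(script_model_selection(seed = 6))
  sw1 <- stepwise_errors(sess, n_init = 15)
  sess2 <- sess
  sess2$fixations <- dplyr::mutate(sess2$fixations,
                                   gx = 2 * .data$gx, gy = 2 * .data$gy)
  sw2 <- stepwise_errors(sess2, n_init = 15)
  ok <- sw1$prediction_defined
  expect_equal(sw2$error_prediction[ok], 2 * sw1$error_prediction[ok],
               tolerance = 1e-6)
})

test_that("provocation spikes raise prediction error then recover", {
  res <- run_provocation_experiment(seed = 1, n_targets = 50,
                                    spike_events = c(25), spike_px = 35)
  rec <- res$recovery
  expect_gt(rec$spike_error, rec$baseline)
  expect_lte(rec$events_to_recover, 10)
  # spike event coincides with a head-displacement spike
  sw <- res$errors
  spike_row <- sw[sw$event == rec$spike_event, ]
  expect_gt(spike_row$head_disp, 20)
})

test_that("the group harness pools subjects and summarizes percentiles", {
  res <- run_group_experiment(n_subjects = 2, n_targets = 25, seed = 3)
  expect_equal(sort(unique(res$errors$subject)), 1:2)
  s <- res$summary
  expect_gt(s$p95_prediction, 0)
  expect_gt(s$p95_fixed, s$p95_prediction)
  expect_gt(s$n_events, 30)
})

test_that("stepwise result plots and comparison plots build", {
  sess <- generate_gaze_session(script_model_selection(seed = 7))
  sw <- stepwise_errors(sess, n_init = 15)
  p1 <- ggplot2::autoplot(sw)
  expect_s3_class(p1, "ggplot")
  cmp <- compare_models(sess, n_init = 15)
  p2 <- ggplot2::autoplot(cmp)
  expect_s3_class(p2, "ggplot")
  p3 <- plot_error_cdf(sw)
  expect_s3_class(p3, "ggplot")
  p4 <- ggplot2::autoplot(sess)
  expect_s3_class(p4, "ggplot")
})
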