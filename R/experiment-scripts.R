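#' Prebuilt session scripts for the evaluation protocols
#'
#' These helpers assemble complete [session_script()]s for the three
#' evaluation protocols so that tests and the acceptance harness can
#' regenerate each study condition from a single seed.
#'
#' `script_model_selection()` is the model-comparison protocol: one round of
#' 15 static targets (three rows of five) is fixated per head pose, repeated
#' for `n_poses` rounds, with a step pose change between rounds. Calibration
#' uses the first round/pose; the remaining rounds probe how each candidate
#' model generalizes to unseen poses.
#'
#' @param n_poses Number of rounds/poses (default 8).
#' @param pose_scale Scale of the random step pose offsets, pixels.
#' @param noise A [noise_params()].
#' @param fps Frame rate, Hz.
#' @param seed Integer seed; drives both the pose draw and the session noise.
#' @param screen A [screen_geometry()].
#' @return A [session_script()].
#' @export
script_model_selection <- function(n_poses = 8, pose_scale = 12,
                                   noise = noise_params(), fps = 30,
                                   seed = 1, screen = screen_geometry()) {
  round_targets <- model_selection_targets(screen)
  n_t <- nrow(round_targets)
  round_dur <- sum(round_targets$duration)
  targets <- purrr::map_dfr(seq_len(n_poses), function(r) {
    tg <- round_targets
    tg$onset <- tg$onset + (r - 1) * round_dur
    tg$target <- tg$target + (r - 1) * n_t
    tg
  })
  # pose 1 is the neutral reference; later poses are seeded random steps
  pose_off <- withr::with_seed(as.integer(seed) + 211L, {
    cbind(stats::runif(n_poses - 1, -pose_scale, pose_scale),
          stats::runif(n_poses - 1, -pose_scale, pose_scale))
  })
  pose <- pose_schedule(
    t = (seq_len(n_poses - 1)) * round_dur,
    dm = pose_off[, 1], dn = pose_off[, 2],
    mode = "step"
  )
  session_script(targets, pose = pose, noise = noise, fps = fps,
                 seed = seed, screen = screen)
}

#' @rdname script_model_selection
#' @description
#' `script_accuracy_test()` is the group accuracy protocol for one synthetic
#' subject: the standard 9-point initial calibration followed by `n_targets`
#' grid targets at 1 s intervals, with a slow head-pose drift to emulate the
#' gradual settling that occurs over a long supine session.
#'
#' @param n_targets Number of post-calibration grid targets (default 60;
#'   the full protocol uses all 180).
#' @param drift_px Total pose drift over the session, pixels (per axis
#'   scale; the drift path is a seeded smooth curve).
#' @export
script_accuracy_test <- function(n_targets = 60, drift_px = 10,
                                 noise = noise_params(), fps = 30,
                                 seed = 1, screen = screen_geometry()) {
  calib <- calibration_points_9(screen)
  grid <- accuracy_grid_targets(screen)
  stopifnot(n_targets <= nrow(grid))
  keep <- withr::with_seed(as.integer(seed) + 97L, {
    sort(sample(nrow(grid), n_targets))
  })
  test <- grid[keep, ]
  test$target <- seq_len(nrow(test)) + nrow(calib)
  test$onset <- sum(calib$duration) +
    c(0, cumsum(test$duration[-nrow(test)]))
  targets <- dplyr::bind_rows(calib, test)
  t_end <- max(targets$onset + targets$duration)
  knots <- seq(0, t_end, length.out = 6)
  pose_off <- withr::with_seed(as.integer(seed) + 131L, {
    cbind(cumsum(stats::runif(6, -0.5, 1) * drift_px / 3),
          cumsum(stats::runif(6, -0.5, 1) * drift_px / 3))
  })
  pose <- pose_schedule(knots, pose_off[, 1], pose_off[, 2], mode = "linear")
  session_script(targets, pose = pose, noise = noise, fps = fps,
                 seed = seed, screen = screen)
}

#' @rdname script_model_selection
#' @description
#' `script_provocation()` is the provocation protocol: a long run of
#' dwell-targets during which the subject deliberately makes large, sudden
#' head movements (pose spikes) at scripted events, each followed by a
#' period at the new pose so recovery can be measured.
#'
#' @param spike_events Event indices (counting post-calibration fixations) at
#'   which a sudden pose step occurs.
#' @param spike_px Magnitude of each pose step, pixels.
#' @export
script_provocation <- function(n_targets = 60,
                               spike_events = c(20, 40),
                               spike_px = 35,
                               noise = noise_params(), fps = 30,
                               seed = 1, screen = screen_geometry()) {
  calib <- calibration_points_9(screen)
  grid <- accuracy_grid_targets(screen)
  keep <- withr::with_seed(as.integer(seed) + 53L, {
    sort(sample(nrow(grid), n_targets))
  })
  test <- grid[keep, ]
  test$target <- seq_len(nrow(test)) + nrow(calib)
  test$onset <- sum(calib$duration) +
    c(0, cumsum(test$duration[-nrow(test)]))
  targets <- dplyr::bind_rows(calib, test)
  spike_t <- test$onset[spike_events]
  dirs <- withr::with_seed(as.integer(seed) + 17L, {
    stats::runif(length(spike_events), 0, 2 * pi)
  })
  dm <- cumsum(spike_px * cos(dirs))
  dn <- cumsum(spike_px * sin(dirs))
  pose <- pose_schedule(spike_t, dm, dn, mode = "step")
  session_script(targets, pose = pose, noise = noise, fps = fps,
                 seed = seed, screen = screen)
}
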