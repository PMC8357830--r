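#' Screen geometry in normalized units
#'
#' All gaze coordinates are expressed in screen units with the origin at the
#' top-left corner, `x` rightward in `[0, 1]` (screen width = 1) and `y`
#' downward in `[0, aspect]`. Distances in these units times 100 are
#' percentages of the screen width, the dimensionless error metric used
#' throughout.
#'
#' @param aspect Display height / width ratio (default 0.75, a 4:3 display).
#' @return A list with fields `width` (1), `height` (`aspect`) and `aspect`.
#' @export
screen_geometry <- function(aspect = 0.75) {
  stopifnot(is.numeric(aspect), aspect > 0)
  list(width = 1, height = aspect, aspect = aspect)
}

#' Standard 9-point initial calibration targets
#'
#' A 3 x 3 grid of fixation targets presented sequentially, each shown for
#' `duration` seconds (default 3 s, i.e. 27 s in total), used to initialize
#' the gaze model before any interaction has occurred.
#'
#' @param screen A [screen_geometry()].
#' @param duration On-screen duration per target, seconds.
#' @param margin Fractional margin between the grid and the display edge.
#' @return A target tibble with columns `target`, `gx`, `gy`, `onset`,
#'   `duration`.
#' @export
calibration_points_9 <- function(screen = screen_geometry(), duration = 3,
                                 margin = 0.12) {
  gx <- seq(margin, 1 - margin, length.out = 3)
  gy <- seq(margin * screen$height, (1 - margin) * screen$height,
            length.out = 3)
  grid <- expand.grid(gx = gx, gy = gy)
  target_sequence(grid$gx, grid$gy, duration = duration)
}

#' Model-selection target round: three rows of five locations
#'
#' One round of the model-comparison protocol: 15 static targets equally
#' spaced in three rows of five, fixated sequentially (default 3 s each).
#' The round is repeated once per head pose; 15 locations suffice to
#' determine even the largest (15-coefficient) candidate model.
#'
#' @inheritParams calibration_points_9
#' @return A target tibble (15 rows).
#' @export
model_selection_targets <- function(screen = screen_geometry(), duration = 3,
                                    margin = 0.12) {
  gx <- seq(margin, 1 - margin, length.out = 5)
  gy <- seq(margin * screen$height, (1 - margin) * screen$height,
            length.out = 3)
  grid <- expand.grid(gx = gx, gy = gy)
  target_sequence(grid$gx, grid$gy, duration = duration)
}

#' Group accuracy-test target grid (180 targets)
#'
#' The display region is partitioned into a 12 x 20 grid of rectangles;
#' targets are presented sequentially at the centers of rows 2-11 and
#' columns 2-19 (10 x 18 = 180 targets), by default at 1 s intervals.
#'
#' @inheritParams calibration_points_9
#' @param duration On-screen duration per target, seconds (default 1).
#' @return A target tibble (180 rows).
#' @export
accuracy_grid_targets <- function(screen = screen_geometry(), duration = 1) {
  cols <- (seq_len(20) - 0.5) / 20
  rows <- (seq_len(12) - 0.5) / 12 * screen$height
  grid <- expand.grid(gx = cols[2:19], gy = rows[2:11])
  grid <- grid[order(grid$gy, grid$gx), ]
  target_sequence(grid$gx, grid$gy, duration = duration)
}

#' Build a sequential target tibble
#'
#' Targets are shown back-to-back: target `k` appears at
#' `onset = (k-1) * duration` for `duration` seconds.
#'
#' @param gx,gy Target center coordinates, normalized screen units.
#' @param duration Scalar or per-target duration, seconds (must be > 0).
#' @param start Onset of the first target, seconds.
#' @return A tibble with columns `target`, `gx`, `gy`, `onset`, `duration`.
#' @export
target_sequence <- function(gx, gy, duration = 1, start = 0) {
  stopifnot(length(gx) == length(gy), all(duration > 0))
  duration <- rep_len(duration, length(gx))
  onset <- start + c(0, cumsum(duration[-length(duration)]))
  tibble::tibble(
    target = seq_along(gx),
    gx = gx, gy = gy,
    onset = onset, duration = duration
  )
}

#' Fixational-noise and blink parameters for the session generator
#'
#' Defaults emulate steady fixation on a target: white Gaussian tremor on the
#' relative pupil coordinates, Poisson-timed microsaccadic jumps that decay
#' back exponentially, a slow fixation-scale drift of the measured pupil
#' position (pupil-diameter and lighting changes move the apparent center in
#' a way the per-fixation median does not remove), and occasional blinks
#' that invalidate the affected frames.
#'
#' @param tremor_sd Tremor standard deviation, pixels per frame (default 0.3).
#' @param microsaccade_rate Microsaccade rate, events per second (default 1.5).
#' @param microsaccade_amp Amplitude range `(min, max)`, pixels (default 1-3).
#' @param microsaccade_tau Exponential decay time constant, seconds.
#' @param drift_sd Fixation-scale drift standard deviation, pixels (default
#'   0.8): an independent offset per fixation, constant within it.
#' @param blink_rate Blink rate, events per second (default 0.1).
#' @param blink_duration Blink duration, seconds.
#' @return A list of class `gaze_noise_params`.
#' @export
noise_params <- function(tremor_sd = 0.3,
                         microsaccade_rate = 1.5,
                         microsaccade_amp = c(1, 3),
                         microsaccade_tau = 0.06,
                         drift_sd = 0.8,
                         blink_rate = 0.1,
                         blink_duration = 0.2) {
  structure(
    list(
      tremor_sd = tremor_sd,
      microsaccade_rate = microsaccade_rate,
      microsaccade_amp = microsaccade_amp,
      microsaccade_tau = microsaccade_tau,
      drift_sd = drift_sd,
      blink_rate = blink_rate,
      blink_duration = blink_duration
    ),
    class = "gaze_noise_params"
  )
}

#' Noise-free generator settings
#'
#' @return A `gaze_noise_params` with all noise and blink processes off.
#' @export
no_noise <- function() {
  noise_params(tremor_sd = 0, microsaccade_rate = 0, drift_sd = 0,
               blink_rate = 0)
}

#' Step head-pose schedule
#'
#' @param t Times (s) at which new pose offsets take effect; the pose before
#'   the first time is `(0, 0)` unless `t` starts at 0.
#' @param dm,dn Pose offsets (corner displacement), pixels.
#' @param mode `"step"` (piecewise constant) or `"linear"` (smooth drift
#'   interpolating between the listed poses).
#' @return A tibble with columns `t`, `dm`, `dn` and attribute `mode`.
#' @export
pose_schedule <- function(t, dm, dn, mode = c("step", "linear")) {
  mode <- match.arg(mode)
  stopifnot(length(t) == length(dm), length(t) == length(dn),
            !is.unsorted(t))
  out <- tibble::tibble(t = t, dm = dm, dn = dn)
  attr(out, "mode") <- mode
  out
}

pose_at <- function(schedule, t) {
  if (is.null(schedule) || nrow(schedule) == 0) {
    return(matrix(0, length(t), 2))
  }
  mode <- attr(schedule, "mode") %||% "step"
  if (mode == "step") {
    idx <- findInterval(t, schedule$t)
    dm <- ifelse(idx == 0, 0, schedule$dm[pmax(idx, 1)])
    dn <- ifelse(idx == 0, 0, schedule$dn[pmax(idx, 1)])
    cbind(dm, dn)
  } else {
    dm <- stats::approx(schedule$t, schedule$dm, xout = t, rule = 2)$y
    dn <- stats::approx(schedule$t, schedule$dn, xout = t, rule = 2)$y
    cbind(dm, dn)
  }
}

#' Define a reproducible synthetic gaze-session script
#'
#' A script fully determines a session: the target sequence, the head-pose
#' schedule, the fixational-noise parameters, the frame rate and the RNG
#' seed. Identical scripts generate bit-identical sessions.
#'
#' @param targets A target tibble (see [target_sequence()]); intervals must
#'   not overlap.
#' @param pose A [pose_schedule()] or `NULL` for a static head.
#' @param noise A [noise_params()].
#' @param fps Frame rate, Hz.
#' @param seed Integer RNG seed.
#' @param screen A [screen_geometry()].
#' @return An object of class `session_script`.
#' @export
session_script <- function(targets, pose = NULL, noise = noise_params(),
                           fps = 30, seed = 1, screen = screen_geometry()) {
  stopifnot(is.data.frame(targets),
            all(c("target", "gx", "gy", "onset", "duration") %in% names(targets)))
  if (any(targets$duration <= 0)) {
    rlang::abort("Target durations must be positive.")
  }
  if (any(targets$gx < 0 | targets$gx > screen$width |
          targets$gy < 0 | targets$gy > screen$height)) {
    rlang::abort("Targets must lie inside the display region.")
  }
  o <- order(targets$onset)
  ends <- targets$onset[o] + targets$duration[o]
  if (nrow(targets) > 1 &&
      any(targets$onset[o][-1] < ends[-length(ends)] - 1e-9)) {
    rlang::abort("Target intervals overlap; a subject fixates one target at a time.")
  }
  structure(
    list(targets = targets, pose = pose, noise = noise,
         fps = fps, seed = as.integer(seed), screen = screen),
    class = "session_script"
  )
}

#' @export
print.session_script <- function(x, ...) {
  cat(sprintf(
    "<session_script> %d targets over %.1f s @ %g fps, seed %d, %s pose\n",
    nrow(x$targets),
    max(x$targets$onset + x$targets$duration),
    x$fps, x$seed,
    if (is.null(x$pose)) "static" else sprintf("%d-entry", nrow(x$pose))
  ))
  invisible(x)
}

#' Generate a ground-truth gaze session at the feature level
#'
#' Simulates a subject fixating the scripted target sequence: for every video
#' frame the true gaze point, head-pose offset and blink state are generated,
#' passed through the ground-truth forward map, and fixational noise (tremor
#' + microsaccades) is added to the relative pupil coordinates. Per-eye
#' feature streams are produced with independent noise realizations; the
#' per-fixation table holds the component-wise median features of the valid
#' frames of each fixation (a fixation needs at least 50% valid frames to be
#' emitted as a calibration event).
#'
#' The generator is deterministic: the same script (including its seed)
#' produces a bit-identical session.
#'
#' @param script A [session_script()].
#' @param forward_map A `gaze_forward_map` (ground truth for the left eye),
#'   or a named list `list(left = , right = )` with one map per eye.
#' @param eyes Which eyes to simulate.
#' @return An object of class `gaze_session`: a list with tibbles `frames`
#'   (per frame and eye: `t`, `target`, `gx`, `gy`, `dm`, `dn`, `blink`,
#'   `eye`, `x`, `y`, `m`, `n`, `valid`) and `fixations` (per fixation event
#'   and eye: median features, validity), plus the script.
#' @examples
#' script <- session_script(calibration_points_9(), seed = 7)
#' sess <- generate_gaze_session(script)
#' sess$fixations
#' @export
generate_gaze_session <- function(script,
                                  forward_map = NULL,
                                  eyes = c("left", "right")) {
  stopifnot(inherits(script, "session_script"))
  eyes <- match.arg(eyes, c("left", "right"), several.ok = TRUE)
  maps <- resolve_forward_maps(forward_map, eyes, script$screen)

  tg <- script$targets[order(script$targets$onset), ]
  t_end <- max(tg$onset + tg$duration)
  t <- seq(0, t_end - 1e-9, by = 1 / script$fps)
  # active target per frame (half-open interval [onset, onset + duration))
  idx <- findInterval(t + 1e-9, tg$onset)
  active <- idx >= 1 & (t < tg$onset[pmax(idx, 1)] + tg$duration[pmax(idx, 1)])
  target <- ifelse(active, tg$target[pmax(idx, 1)], NA_integer_)
  gx <- ifelse(active, tg$gx[pmax(idx, 1)], NA_real_)
  gy <- ifelse(active, tg$gy[pmax(idx, 1)], NA_real_)
  pose <- pose_at(script$pose, t)

  frames <- withr::with_seed(script$seed, {
    # blink onsets shared between eyes (both eyes blink together)
    blink <- sample_event_mask(t, script$noise$blink_rate,
                               script$noise$blink_duration, t_end)
    purrr::map_dfr(eyes, function(eye) {
      fm <- maps[[eye]]
      base <- fm(cbind(gx, gy), pose)
      nz <- fixational_noise(t, script$noise)
      dr <- fixation_drift(target, script$noise$drift_sd)
      tibble::tibble(
        t = t, target = target, gx = gx, gy = gy,
        dm = pose[, 1], dn = pose[, 2], blink = blink, eye = eye,
        x = base$x + nz$dx + dr$dx, y = base$y + nz$dy + dr$dy,
        m = base$m, n = base$n,
        valid = !blink & active
      )
    })
  })
  # the pupil is not visible during a blink
  frames$x[frames$blink] <- NA_real_
  frames$y[frames$blink] <- NA_real_
  fixations <- summarize_fixations(frames, tg)
  structure(
    list(frames = frames, fixations = fixations, script = script,
         forward_map = maps, eyes = eyes),
    class = "gaze_session"
  )
}

resolve_forward_maps <- function(forward_map, eyes, screen) {
  if (is.null(forward_map)) {
    return(list(
      left = eye_forward_map(screen = screen),
      right = eye_forward_map(corner = c(240, 298),
                              pupil_offset = c(70, -45),
                              gain = c(162, 162),
                              screen = screen)
    ))
  }
  if (inherits(forward_map, "gaze_forward_map")) {
    return(stats::setNames(rep(list(forward_map), length(eyes)), eyes))
  }
  stopifnot(is.list(forward_map), all(eyes %in% names(forward_map)))
  forward_map
}

# Poisson-timed events of fixed duration -> logical per-frame mask
sample_event_mask <- function(t, rate, duration, t_end) {
  mask <- rep(FALSE, length(t))
  if (rate <= 0) return(mask)
  n_ev <- stats::rpois(1, rate * t_end)
  if (n_ev == 0) return(mask)
  onsets <- sort(stats::runif(n_ev, 0, t_end))
  for (o in onsets) mask <- mask | (t >= o & t < o + duration)
  mask
}

# tremor + decaying microsaccadic jumps, in pixels on (x, y)
fixational_noise <- function(t, noise) {
  n <- length(t)
  dx <- stats::rnorm(n, 0, noise$tremor_sd)
  dy <- stats::rnorm(n, 0, noise$tremor_sd)
  if (noise$microsaccade_rate > 0 && n > 1) {
    t_end <- max(t)
    n_ms <- stats::rpois(1, noise$microsaccade_rate * t_end)
    if (n_ms > 0) {
      onsets <- stats::runif(n_ms, 0, t_end)
      amps <- stats::runif(n_ms, noise$microsaccade_amp[1],
                           noise$microsaccade_amp[2])
      dirs <- stats::runif(n_ms, 0, 2 * pi)
      for (k in seq_len(n_ms)) {
        after <- t >= onsets[k]
        decay <- exp(-(t[after] - onsets[k]) / noise$microsaccade_tau)
        dx[after] <- dx[after] + amps[k] * cos(dirs[k]) * decay
        dy[after] <- dy[after] + amps[k] * sin(dirs[k]) * decay
      }
    }
  }
  list(dx = dx, dy = dy)
}

# slow pupil-estimate drift: one offset per fixation, constant within it;
# unlike tremor this survives the per-fixation median
fixation_drift <- function(target, drift_sd) {
  n <- length(target)
  if (drift_sd <= 0) return(list(dx = numeric(n), dy = numeric(n)))
  ids <- unique(target[!is.na(target)])
  off <- matrix(stats::rnorm(2 * length(ids), 0, drift_sd), ncol = 2)
  idx <- match(target, ids)
  dx <- ifelse(is.na(idx), 0, off[idx, 1])
  dy <- ifelse(is.na(idx), 0, off[idx, 2])
  list(dx = dx, dy = dy)
}

summarize_fixations <- function(frames, targets) {
  fx <- frames |>
    dplyr::filter(!is.na(.data$target)) |>
    dplyr::group_by(.data$eye, .data$target) |>
    dplyr::summarise(
      onset = min(.data$t),
      gx = .data$gx[1], gy = .data$gy[1],
      x = stats::median(.data$x[.data$valid]),
      y = stats::median(.data$y[.data$valid]),
      m = stats::median(.data$m[.data$valid]),
      n = stats::median(.data$n[.data$valid]),
      dm = stats::median(.data$dm),
      dn = stats::median(.data$dn),
      n_frames = dplyr::n(),
      frac_valid = mean(.data$valid),
      .groups = "drop"
    ) |>
    dplyr::mutate(valid = .data$frac_valid >= 0.5) |>
    dplyr::arrange(.data$eye, .data$onset) |>
    dplyr::group_by(.data$eye) |>
    dplyr::mutate(event = dplyr::row_number(), .before = 1) |>
    dplyr::ungroup()
  fx
}

#' @export
print.gaze_session <- function(x, ...) {
  cat(sprintf(
    "<gaze_session> %d frames x %d eye(s), %d fixation events, seed %d\n",
    nrow(x$frames) / length(x$eyes), length(x$eyes),
    max(x$fixations$event), x$script$seed
  ))
  invisible(x)
}
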