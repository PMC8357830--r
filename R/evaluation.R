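#' Stepwise regression / prediction / fixed-model errors over a session
#'
#' Replays the progressive-calibration protocol over a session's fixation
#' events. Events are processed in order; at step `t` (beyond the initial
#' calibration set) three gaze estimates of the current target are formed
#' per eye and averaged across eyes:
#' \describe{
#'   \item{regression}{model fit on events `1..t` (in-sample).}
#'   \item{prediction}{model fit on events `1..t-1` only (out-of-sample,
#'     i.e. progressive calibration up to the previous event).}
#'   \item{fixed}{model fit on the initial calibration events only, never
#'     updated.}
#' }
#' Each error is the Euclidean distance between the estimate and the true
#' target center, expressed as a percentage of the screen width. Relative
#' head displacement between consecutive events (and absolute displacement
#' from the first event) is computed from the fixation-median corner
#' coordinates; an optional `mm_per_px` factor converts it to millimetres.
#'
#' Events whose prediction is undefined because fewer than `N` prior rows
#' exist are flagged (`prediction_defined = FALSE`) and skipped in summary
#' means; likewise the fixed model is undefined when the initial set is
#' smaller than `N`.
#'
#' @param session A [generate_gaze_session()] result.
#' @param spec A [gaze_model_spec()] (default: the adopted 8-term model).
#' @param n_init Number of initial calibration events.
#' @param mm_per_px Optional pixel-to-millimetre conversion for head
#'   displacement (`NA` = report pixels only).
#' @return A tibble of class `gaze_stepwise`, one row per post-calibration
#'   fixation event.
#' @export
stepwise_errors <- function(session, spec = default_gaze_spec(), n_init,
                            mm_per_px = NA_real_) {
  stopifnot(inherits(session, "gaze_session"))
  N <- n_coefficients(spec)
  eyes <- session$eyes
  per_eye <- purrr::map(eyes, function(e) {
    fx <- dplyr::filter(session$fixations, .data$eye == e, .data$valid)
    list(fx = fx, V = basis_matrix(fx, spec), G = cbind(fx$gx, fx$gy))
  })
  names(per_eye) <- eyes
  E <- min(vapply(per_eye, function(p) nrow(p$fx), numeric(1)))
  if (E < n_init + 1) {
    rlang::abort("Session needs at least n_init + 1 valid fixation events.")
  }

  fixed_coef <- purrr::map(per_eye, function(p) {
    if (n_init >= N) quiet_pinv(p$V[1:n_init, , drop = FALSE],
                                p$G[1:n_init, , drop = FALSE]) else NULL
  })

  ref <- per_eye[[1]]$fx
  rows <- vector("list", E - n_init)
  prev_corner <- corner_of(per_eye, n_init)
  first_corner <- corner_of(per_eye, 1)
  for (t in (n_init + 1):E) {
    est <- function(coefs) {
      g <- purrr::imap(per_eye, function(p, e) {
        cf <- coefs[[e]]
        if (is.null(cf)) return(c(NA_real_, NA_real_))
        drop(p$V[t, , drop = FALSE] %*% cf)
      })
      gm <- do.call(rbind, g)
      colMeans(gm, na.rm = FALSE)
    }
    reg_coef <- purrr::map(per_eye, function(p) {
      quiet_pinv(p$V[1:t, , drop = FALSE], p$G[1:t, , drop = FALSE])
    })
    pred_ok <- (t - 1) >= N
    pred_coef <- if (pred_ok) {
      purrr::map(per_eye, function(p) {
        quiet_pinv(p$V[1:(t - 1), , drop = FALSE],
                   p$G[1:(t - 1), , drop = FALSE])
      })
    } else NULL

    g_true <- c(ref$gx[t], ref$gy[t])
    g_reg <- est(reg_coef)
    g_pred <- if (pred_ok) est(pred_coef) else c(NA_real_, NA_real_)
    g_fix <- if (!is.null(fixed_coef[[1]])) est(fixed_coef) else c(NA_real_, NA_real_)

    cur_corner <- corner_of(per_eye, t)
    hd <- sqrt(sum((cur_corner - prev_corner)^2))
    hd_abs <- sqrt(sum((cur_corner - first_corner)^2))
    prev_corner <- cur_corner

    rows[[t - n_init]] <- tibble::tibble(
      event = t,
      onset = ref$onset[t],
      target = ref$target[t],
      gx = g_true[1], gy = g_true[2],
      error_regression = 100 * sqrt(sum((g_reg - g_true)^2)),
      error_prediction = 100 * sqrt(sum((g_pred - g_true)^2)),
      error_fixed = 100 * sqrt(sum((g_fix - g_true)^2)),
      head_disp = hd,
      head_disp_abs = hd_abs,
      head_disp_mm = hd * mm_per_px,
      prediction_defined = pred_ok
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "spec") <- spec$name
  attr(out, "n_terms") <- N
  attr(out, "n_init") <- n_init
  class(out) <- c("gaze_stepwise", class(out))
  out
}

corner_of <- function(per_eye, t) {
  mats <- purrr::map(per_eye, function(p) c(p$fx$m[t], p$fx$n[t]))
  colMeans(do.call(rbind, mats))
}

# rank-tolerant least squares without the rank-deficiency warning chatter:
# single-pose stretches legitimately produce deficient V along the way
quiet_pinv <- function(V, G, tol = 1e-10) {
  sv <- svd(V)
  keep <- sv$d > tol * sv$d[1]
  dinv <- ifelse(keep, 1 / sv$d, 0)
  sv$v %*% (dinv * (t(sv$u) %*% G))
}

#' Empirical percentile of an error distribution
#'
#' Linear interpolation between order statistics; used e.g. for the 95th
#' percentile of the prediction-error cumulative distribution.
#'
#' @param errors Numeric vector (NAs dropped); must be non-empty.
#' @param q Percentile in `(0, 100)`.
#' @return The q-th percentile.
#' @export
percentile_error <- function(errors, q) {
  errors <- errors[!is.na(errors)]
  if (length(errors) == 0) rlang::abort("Empty error vector.")
  if (q <= 0 || q >= 100) rlang::abort("`q` must be strictly between 0 and 100.")
  stats::quantile(errors, q / 100, type = 7, names = FALSE)
}

#' Compare candidate regression models on one session
#'
#' Runs [stepwise_errors()] for each candidate spec and tabulates the mean
#' regression and prediction errors over the events where each model is
#' defined. Models that cannot be evaluated on the session (too few events
#' for their term count) are flagged and excluded from the argmin.
#'
#' @param session A [generate_gaze_session()] result.
#' @param specs A list of [gaze_model_spec()]s (default: the built-in
#'   library of 6, 8, 12 and 15-term candidates).
#' @param n_init Number of initial calibration events.
#' @return A tibble of class `gaze_model_comparison` with columns `model`,
#'   `n_terms`, `mean_regression`, `mean_prediction`, `n_events`,
#'   `evaluated`; attributes `best_regression` and `best_prediction` name
#'   the argmin models.
#' @export
compare_models <- function(session, specs = gaze_model_library(), n_init) {
  if (inherits(specs, "gaze_model_spec")) specs <- list(specs)
  rows <- purrr::map(specs, function(spec) {
    N <- n_coefficients(spec)
    n_events <- session$fixations |>
      dplyr::filter(.data$eye == session$eyes[1], .data$valid) |>
      nrow()
    if (n_events < N + 1 || n_events < n_init + 1) {
      return(tibble::tibble(
        model = spec$name, n_terms = N,
        mean_regression = NA_real_, mean_prediction = NA_real_,
        n_events = 0L, evaluated = FALSE
      ))
    }
    sw <- stepwise_errors(session, spec, n_init = n_init)
    ok <- sw$prediction_defined
    tibble::tibble(
      model = spec$name, n_terms = N,
      mean_regression = mean(sw$error_regression[ok], na.rm = TRUE),
      mean_prediction = mean(sw$error_prediction[ok], na.rm = TRUE),
      n_events = sum(ok), evaluated = TRUE
    )
  })
  out <- dplyr::bind_rows(rows)
  ev <- dplyr::filter(out, .data$evaluated)
  attr(out, "best_regression") <- ev$model[which.min(ev$mean_regression)]
  attr(out, "best_prediction") <- ev$model[which.min(ev$mean_prediction)]
  class(out) <- c("gaze_model_comparison", class(out))
  out
}

#' @export
print.gaze_model_comparison <- function(x, ...) {
  NextMethod()
  cat(sprintf("# lowest regression error: %s; lowest prediction error: %s\n",
              attr(x, "best_regression"), attr(x, "best_prediction")))
  invisible(x)
}

#' Head displacement between fixation events
#'
#' Euclidean distance between the fixation-median corner positions `(m, n)`
#' of consecutive events (`from = "previous"`), or from the pose at the
#' first event (`from = "first"`, used in the provocation analysis).
#' Distances are averaged across eyes and reported in pixels, with an
#' optional millimetre conversion.
#'
#' @param session A `gaze_session`, or its `fixations` tibble.
#' @param from Reference pose: `"previous"` or `"first"`.
#' @param mm_per_px Optional px-to-mm conversion factor.
#' @return A tibble with columns `event`, `displacement` (px) and
#'   `displacement_mm`.
#' @export
head_displacement <- function(session, from = c("previous", "first"),
                              mm_per_px = NA_real_) {
  from <- match.arg(from)
  fx <- if (inherits(session, "gaze_session")) session$fixations else session
  fx <- dplyr::filter(fx, .data$valid)
  wide <- fx |>
    dplyr::group_by(.data$event) |>
    dplyr::summarise(m = mean(.data$m), n = mean(.data$n), .groups = "drop") |>
    dplyr::arrange(.data$event)
  if (nrow(wide) < 2) rlang::abort("Need at least 2 fixation events.")
  if (from == "previous") {
    d <- c(NA_real_, sqrt(diff(wide$m)^2 + diff(wide$n)^2))
  } else {
    d <- sqrt((wide$m - wide$m[1])^2 + (wide$n - wide$n[1])^2)
  }
  tibble::tibble(event = wide$event, displacement = d,
                 displacement_mm = d * mm_per_px)
}

#' Synthetic group accuracy experiment
#'
#' Replays the group protocol on synthetic subjects: each subject gets a
#' seeded individual forward map (anatomical gain/corner variation), a
#' 9-point initial calibration, and a run of grid targets under slow pose
#' drift. Stepwise errors are pooled over subjects and summarized by the
#' cumulative-distribution percentiles of the progressive-prediction and
#' fixed-model errors.
#'
#' The default scale (5 subjects x 60 targets) keeps runs quick; `full =
#' TRUE` switches to the 13-subject x 180-target layout of the full
#' protocol.
#'
#' @param n_subjects,n_targets Cohort size and targets per subject.
#' @param seed Integer seed; subject s uses `seed + s` offsets.
#' @param spec Gaze model spec under test.
#' @param full Use the full 13 x 180 layout.
#' @param drift_px Pose drift scale per subject session, pixels.
#' @param noise A [noise_params()].
#' @return A list of class `gaze_group_result`: `errors` (pooled stepwise
#'   tibble with `subject`), `summary` (one-row tibble with p95s and means).
#' @export
run_group_experiment <- function(n_subjects = 5, n_targets = 60, seed = 1,
                                 spec = default_gaze_spec(), full = FALSE,
                                 drift_px = 10, noise = noise_params()) {
  if (full) {
    n_subjects <- 13; n_targets <- 180
  }
  errors <- purrr::map_dfr(seq_len(n_subjects), function(s) {
    subj_seed <- as.integer(seed) * 1000L + s
    fm <- subject_forward_maps(subj_seed)
    script <- script_accuracy_test(n_targets = n_targets, drift_px = drift_px,
                                   noise = noise, seed = subj_seed)
    sess <- generate_gaze_session(script, forward_map = fm)
    sw <- stepwise_errors(sess, spec, n_init = 9)
    sw$subject <- s
    sw
  })
  ok <- errors$prediction_defined
  summary <- tibble::tibble(
    n_subjects = n_subjects,
    n_events = sum(ok),
    p95_prediction = percentile_error(errors$error_prediction[ok], 95),
    p95_fixed = percentile_error(errors$error_fixed[ok], 95),
    mean_prediction = mean(errors$error_prediction[ok], na.rm = TRUE),
    mean_fixed = mean(errors$error_fixed[ok], na.rm = TRUE),
    p95_head_disp = percentile_error(errors$head_disp[ok], 95)
  )
  structure(list(errors = errors, summary = summary),
            class = "gaze_group_result")
}

# per-subject anatomical variation of the ground-truth forward maps
subject_forward_maps <- function(seed) {
  withr::with_seed(seed + 7L, {
    gl <- stats::runif(1, 0.9, 1.1)
    gr <- stats::runif(1, 0.9, 1.1)
    cl <- c(400, 300) + stats::runif(2, -10, 10)
    cr <- c(240, 298) + stats::runif(2, -10, 10)
    list(
      left = eye_forward_map(corner = cl, gain = c(170, 170) * gl),
      right = eye_forward_map(corner = cr, pupil_offset = c(70, -45),
                              gain = c(162, 162) * gr)
    )
  })
}

#' @export
print.gaze_group_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<gaze_group_result> %d subjects, %d events\n  p95 prediction error: %.2f%% screen width (fixed model: %.2f%%)\n",
    s$n_subjects, s$n_events, s$p95_prediction, s$p95_fixed
  ))
  invisible(x)
}

#' Synthetic provocation experiment
#'
#' Replays the provocation protocol: scripted sudden pose spikes during a
#' long target run. Reports the stepwise errors together with a recovery
#' analysis per spike: the pre-spike baseline (median prediction error), the
#' error at the spike event, and how many events pass before the
#' progressive model's prediction error returns below `recover_factor x`
#' baseline.
#'
#' @param seed Integer seed.
#' @param n_targets Post-calibration targets.
#' @param spike_events Event indices (post-calibration) of the pose spikes.
#' @param spike_px Pose step magnitude, pixels.
#' @param spec Gaze model spec under test.
#' @param recover_factor Recovery threshold as a multiple of baseline.
#' @param noise A [noise_params()].
#' @return A list of class `gaze_provocation_result`: `errors` (stepwise
#'   tibble), `recovery` (per spike: `spike_event`, `baseline`,
#'   `spike_error`, `events_to_recover`), `summary`.
#' @export
run_provocation_experiment <- function(seed = 1, n_targets = 60,
                                       spike_events = c(20, 40),
                                       spike_px = 35,
                                       spec = default_gaze_spec(),
                                       recover_factor = 2,
                                       noise = noise_params()) {
  script <- script_provocation(n_targets = n_targets,
                               spike_events = spike_events,
                               spike_px = spike_px,
                               noise = noise, seed = seed)
  sess <- generate_gaze_session(script, forward_map = subject_forward_maps(seed))
  sw <- stepwise_errors(sess, spec, n_init = 9)
  # stepwise event index t corresponds to post-calibration event t - 9
  recovery <- purrr::map_dfr(spike_events, function(se) {
    ev <- se + 9
    pre <- sw$error_prediction[sw$event < ev & sw$prediction_defined]
    baseline <- stats::median(pre, na.rm = TRUE)
    spike_error <- sw$error_prediction[sw$event == ev]
    after <- sw[sw$event > ev & sw$prediction_defined, ]
    rec <- which(after$error_prediction <= recover_factor * baseline)
    tibble::tibble(
      spike_event = ev, baseline = baseline,
      spike_error = if (length(spike_error)) spike_error else NA_real_,
      events_to_recover = if (length(rec)) rec[1] else NA_integer_
    )
  })
  ok <- sw$prediction_defined
  summary <- tibble::tibble(
    p95_prediction = percentile_error(sw$error_prediction[ok], 95),
    p95_head_disp = percentile_error(sw$head_disp[ok], 95),
    max_prediction = max(sw$error_prediction[ok], na.rm = TRUE)
  )
  structure(list(errors = sw, recovery = recovery, summary = summary,
                 session = sess),
            class = "gaze_provocation_result")
}

#' @export
print.gaze_provocation_result <- function(x, ...) {
  cat(sprintf(
    "<gaze_provocation_result> p95 prediction error %.2f%%; %d spike(s), recovery within %s events\n",
    x$summary$p95_prediction, nrow(x$recovery),
    paste(x$recovery$events_to_recover, collapse = ", ")
  ))
  invisible(x)
}
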