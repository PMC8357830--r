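#' Interactive gaze target
#'
#' An interactive target couples a visual object (circle of `visual_radius`
#' at `center`) with a larger invisible landing zone that captures ambient
#' fixation, a dwell counter, and a linked event that fires exactly once per
#' dwell episode when the accumulated dwell time exceeds the threshold.
#' A threshold of 0 gives immediate interaction (trigger on the first
#' in-zone gaze sample).
#'
#' @param id Target identifier.
#' @param gx,gy Target center, normalized screen units.
#' @param visual_radius Visible radius, screen-width units.
#' @param landing_radius Landing-zone radius; must be `>= visual_radius`.
#'   `NULL` defers to the scene's adaptive [zone_schedule()].
#' @param dwell Dwell threshold, seconds (`>= 0`; 0 = immediate).
#' @param event Linked event id (defaults to `id`).
#' @return A list of class `interactive_target`.
#' @export
interactive_target <- function(id, gx, gy, visual_radius = 0.04,
                               landing_radius = NULL, dwell = 1.5,
                               event = NULL) {
  if (dwell < 0) rlang::abort("Dwell threshold must be >= 0.")
  if (!is.null(landing_radius) && landing_radius < visual_radius) {
    rlang::abort("Landing radius must be at least the visual radius.")
  }
  structure(
    list(id = id, center = c(gx = gx, gy = gy),
         visual_radius = visual_radius,
         landing_radius = landing_radius,
         dwell_threshold = dwell,
         event = event %||% id),
    class = "interactive_target"
  )
}

#' Adaptive landing-zone schedule
#'
#' Landing zones start large so that an imprecise early gaze model still
#' lands selections, then shrink as calibration samples accumulate and the
#' model becomes more accurate. If recent prediction residuals spike (e.g.
#' after sudden head movement) the zone is temporarily re-expanded, bounded
#' by the initial radius, and re-shrinks as further samples arrive.
#'
#' @param initial Initial landing radius, screen-width units (default 0.12).
#' @param minimum Floor radius (default 0.062, chosen so a 7 x 3 target
#'   array remains separable).
#' @param shrink_per_sample Radius decrease per accumulated calibration
#'   sample.
#' @param error_trigger Recent prediction error (% screen width) above which
#'   the zone re-expands.
#' @param expand_factor Multiplicative re-expansion factor.
#' @return A list of class `zone_schedule`.
#' @export
zone_schedule <- function(initial = 0.12, minimum = 0.062,
                          shrink_per_sample = 0.004,
                          error_trigger = 8, expand_factor = 1.5) {
  stopifnot(minimum <= initial, shrink_per_sample >= 0, expand_factor >= 1)
  structure(
    list(initial = initial, minimum = minimum,
         shrink_per_sample = shrink_per_sample,
         error_trigger = error_trigger, expand_factor = expand_factor),
    class = "zone_schedule"
  )
}

#' Current landing radius under the adaptive schedule
#'
#' Monotonically non-increasing in the number of accumulated calibration
#' samples while the recent prediction error stays below the trigger;
#' re-expanded (never beyond the initial radius, never below the minimum)
#' when it exceeds it.
#'
#' @param schedule A [zone_schedule()].
#' @param n_samples Number of calibration samples accumulated so far.
#' @param recent_error Recent prediction error, % of screen width.
#' @return Landing radius in screen-width units.
#' @export
landing_radius <- function(schedule, n_samples, recent_error = 0) {
  stopifnot(inherits(schedule, "zone_schedule"), n_samples >= 0)
  base <- pmax(schedule$minimum,
               schedule$initial - schedule$shrink_per_sample * n_samples)
  ifelse(recent_error > schedule$error_trigger,
         pmin(schedule$initial, base * schedule$expand_factor),
         base)
}

#' Build a gaze-interaction scene
#'
#' @param targets A list of [interactive_target()]s, or a data frame with
#'   columns `id`, `gx`, `gy` (+ optional `visual_radius`, `landing_radius`,
#'   `dwell`, `event`).
#' @param schedule A [zone_schedule()] used for targets without a fixed
#'   landing radius; `NULL` requires all targets to fix their own.
#' @param missing_reset Seconds of missing gaze after which a running dwell
#'   resets (default 0.2 s); shorter gaps pause but keep the dwell.
#' @param min_valid_frac Validity quota a dwell buffer must meet for a
#'   trigger to emit a calibration sample.
#' @return An object of class `gaze_scene`.
#' @export
gaze_scene <- function(targets, schedule = zone_schedule(),
                       missing_reset = 0.2, min_valid_frac = 0.5) {
  if (is.data.frame(targets)) {
    targets <- purrr::pmap(targets, function(id, gx, gy, ...) {
      dots <- list(...)
      interactive_target(
        id, gx, gy,
        visual_radius = dots$visual_radius %||% 0.04,
        landing_radius = dots$landing_radius,
        dwell = dots$dwell %||% 1.5,
        event = dots$event
      )
    })
  }
  stopifnot(length(targets) > 0,
            all(vapply(targets, inherits, logical(1), "interactive_target")))
  if (is.null(schedule) &&
      any(vapply(targets, function(tg) is.null(tg$landing_radius), logical(1)))) {
    rlang::abort("Without a zone schedule every target needs a fixed landing radius.")
  }
  states <- purrr::map(targets, function(tg) {
    list(hovered = FALSE, dwell = 0, armed = TRUE, buffer = list())
  })
  structure(
    list(targets = targets, states = states, schedule = schedule,
         missing_reset = missing_reset, min_valid_frac = min_valid_frac,
         time = 0, missing_time = 0,
         n_samples = 0, recent_error = 0,
         events = list(), samples = list()),
    class = "gaze_scene"
  )
}

#' Advance the interaction state machine by one gaze sample
#'
#' Processes one gaze estimate (or a missing-gaze marker) over a time step:
#' resolves which landing zone (if any) captures the gaze — nearest target
#' center wins when zones overlap — and emits `hover_enter` (with highlight
#' and sound-cue flags), `dwell_progress` (with the visual shrink fraction
#' `elapsed / threshold`), `trigger`, and `hover_exit` events. A trigger
#' fires the target's linked event exactly once per dwell episode (re-arming
#' requires leaving the zone) and, when the dwell buffer meets the validity
#' quota, emits a calibration sample pairing the buffered median features
#' with the target center. Missing gaze longer than the configured gap
#' resets running dwells.
#'
#' @param scene A [gaze_scene()].
#' @param gaze Gaze point `(gx, gy)`, or `NULL`/`NA` for missing gaze.
#' @param dt Time step, seconds (> 0).
#' @param features Optional one-row feature record (`x`, `y`, `m`, `n`,
#'   `valid`) buffered for progressive calibration.
#' @return The updated scene; per-step events are in `scene$events` and the
#'   full logs are retrieved with [interaction_events()] /
#'   [calibration_samples()].
#' @export
scene_step <- function(scene, gaze, dt, features = NULL) {
  stopifnot(inherits(scene, "gaze_scene"), dt > 0)
  scene$time <- scene$time + dt
  t_now <- scene$time

  missing <- is.null(gaze) || any(is.na(as.numeric(gaze)[1:2]))
  if (missing) {
    scene$missing_time <- scene$missing_time + dt
    if (scene$missing_time > scene$missing_reset) {
      for (k in seq_along(scene$states)) {
        if (scene$states[[k]]$hovered) {
          scene <- push_event(scene, t_now, "hover_exit", k, reason = "missing_gaze")
        }
        scene$states[[k]]$hovered <- FALSE
        scene$states[[k]]$dwell <- 0
        scene$states[[k]]$armed <- TRUE
        scene$states[[k]]$buffer <- list()
      }
    }
    return(scene)
  }
  scene$missing_time <- 0
  g <- as.numeric(gaze)[1:2]

  radii <- vapply(seq_along(scene$targets), function(k) {
    tg <- scene$targets[[k]]
    tg$landing_radius %||%
      landing_radius(scene$schedule, scene$n_samples, scene$recent_error)
  }, numeric(1))
  d <- vapply(scene$targets, function(tg) {
    sqrt(sum((unname(tg$center) - g)^2))
  }, numeric(1))
  inside <- which(d <= radii)
  hit <- if (length(inside) == 0) 0L else inside[which.min(d[inside])]

  for (k in seq_along(scene$states)) {
    st <- scene$states[[k]]
    if (k == hit) next
    if (st$hovered) {
      scene <- push_event(scene, t_now, "hover_exit", k, reason = "gaze_left")
      st$hovered <- FALSE; st$dwell <- 0; st$armed <- TRUE; st$buffer <- list()
      scene$states[[k]] <- st
    }
  }

  if (hit > 0) {
    tg <- scene$targets[[hit]]
    st <- scene$states[[hit]]
    if (!st$hovered) {
      st$hovered <- TRUE
      st$dwell <- 0
      st$buffer <- list()
      scene <- push_event(scene, t_now, "hover_enter", hit,
                          highlight = TRUE, sound_cue = TRUE)
    }
    st$dwell <- st$dwell + dt
    if (!is.null(features)) st$buffer <- c(st$buffer, list(features))
    shrink <- if (tg$dwell_threshold > 0) {
      min(st$dwell / tg$dwell_threshold, 1)
    } else 1
    scene <- push_event(scene, t_now, "dwell_progress", hit,
                        dwell = st$dwell, shrink_fraction = shrink)
    if (st$armed && st$dwell >= tg$dwell_threshold) {
      st$armed <- FALSE
      res <- on_trigger(tg, dplyr::bind_rows(st$buffer),
                        min_valid_frac = scene$min_valid_frac,
                        timestamp = t_now)
      scene <- push_event(scene, t_now, "trigger", hit,
                          event_id = tg$event, dwell = st$dwell,
                          sample_emitted = !is.null(res$sample))
      if (!is.null(res$sample)) {
        scene$samples <- c(scene$samples, list(res$sample))
        scene$n_samples <- scene$n_samples + 1
      }
    }
    scene$states[[hit]] <- st
  }
  scene
}

push_event <- function(scene, t, type, target_idx, ...) {
  tg <- scene$targets[[target_idx]]
  scene$events <- c(scene$events, list(
    tibble::tibble(t = t, type = type, target = tg$id, ...)
  ))
  scene
}

#' Calibration sample and linked event emitted by a dwell trigger
#'
#' Every dwell-triggered selection doubles as a calibration observation: the
#' subject has (by construction of the interaction) been fixating the target
#' center, so the pair (median buffered features, target center) can be
#' appended to the gaze model. If too few buffered frames are valid (e.g.
#' the dwell was mostly blinked through), the linked event still fires but
#' no sample is emitted.
#'
#' @param target An [interactive_target()].
#' @param buffer Data frame of buffered per-frame features (`x`, `y`, `m`,
#'   `n`, `valid`).
#' @param min_valid_frac Validity quota (default 0.5).
#' @param timestamp Trigger time, seconds.
#' @return A list with `event` (the linked event id) and `sample` (a one-row
#'   tibble `gx`, `gy`, `x`, `y`, `m`, `n`, `source`, `t`, or `NULL` when
#'   the quota fails).
#' @export
on_trigger <- function(target, buffer, min_valid_frac = 0.5,
                       timestamp = NA_real_) {
  med <- if (is.null(buffer) || nrow(buffer) == 0) NULL else {
    median_fixation_features(buffer, min_valid_frac = min_valid_frac)
  }
  sample <- NULL
  if (!is.null(med)) {
    sample <- tibble::tibble(
      gx = unname(target$center[1]), gy = unname(target$center[2]),
      x = med$x, y = med$y, m = med$m, n = med$n,
      source = "ui-trigger", t = timestamp
    )
  }
  list(event = target$event, sample = sample)
}

#' Run the interaction state machine over a gaze trace
#'
#' @param scene A [gaze_scene()].
#' @param trace A tibble with columns `t`, `gx`, `gy` (NA = missing gaze)
#'   and optionally per-frame feature columns `x`, `y`, `m`, `n`, `valid`.
#' @return The final scene; inspect with [interaction_events()] and
#'   [calibration_samples()].
#' @export
run_interaction <- function(scene, trace) {
  stopifnot(all(c("t", "gx", "gy") %in% names(trace)))
  has_features <- all(c("x", "y", "m", "n") %in% names(trace))
  ts <- trace$t
  dts <- if (length(ts) >= 2) diff(c(2 * ts[1] - ts[2], ts)) else 1 / 30
  for (i in seq_len(nrow(trace))) {
    feats <- NULL
    if (has_features) {
      feats <- trace[i, intersect(c("x", "y", "m", "n", "valid"), names(trace))]
      if (!"valid" %in% names(feats)) feats$valid <- !is.na(feats$x)
    }
    scene <- scene_step(scene, c(trace$gx[i], trace$gy[i]), dts[i],
                        features = feats)
  }
  scene
}

#' Event and calibration-sample logs of a scene
#'
#' @param scene A [gaze_scene()] after stepping.
#' @return `interaction_events()`: tibble of emitted events (`t`, `type`,
#'   `target`, ...); `calibration_samples()`: tibble of emitted calibration
#'   samples.
#' @export
interaction_events <- function(scene) {
  if (length(scene$events) == 0) {
    return(tibble::tibble(t = numeric(0), type = character(0),
                          target = character(0)))
  }
  dplyr::bind_rows(scene$events)
}

#' @rdname interaction_events
#' @export
calibration_samples <- function(scene) {
  if (length(scene$samples) == 0) {
    return(tibble::tibble(gx = numeric(0), gy = numeric(0)))
  }
  dplyr::bind_rows(scene$samples)
}

#' Read / write a scene description (YAML or JSON)
#'
#' A scene file is a list of targets, each with fields `id`, `gx`, `gy` and
#' optional `visual_radius`, `landing_radius`, `dwell`, `event`.
#'
#' @param path File path; format chosen by extension (`.yml`/`.yaml` or
#'   `.json`).
#' @param targets A list of [interactive_target()]s to write.
#' @return `read_scene()` returns a list of `interactive_target`s.
#' @export
read_scene <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  purrr::map(raw, function(tg) {
    interactive_target(
      id = tg$id, gx = tg$gx, gy = tg$gy,
      visual_radius = tg$visual_radius %||% 0.04,
      landing_radius = tg$landing_radius,
      dwell = tg$dwell %||% 1.5,
      event = tg$event
    )
  })
}

#' @rdname read_scene
#' @export
write_scene <- function(targets, path) {
  raw <- purrr::map(targets, function(tg) {
    list(id = tg$id, gx = unname(tg$center[1]), gy = unname(tg$center[2]),
         visual_radius = tg$visual_radius,
         landing_radius = tg$landing_radius,
         dwell = tg$dwell_threshold, event = tg$event)
  })
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(raw, path)
  } else {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}
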