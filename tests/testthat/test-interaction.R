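three_targets <- function(dwell = 1.5, landing = 0.1) {
  list(
    interactive_target("a", 0.2, 0.2, landing_radius = landing, dwell = dwell),
    interactive_target("b", 0.5, 0.4, landing_radius = landing, dwell = dwell),
    interactive_target("c", 0.8, 0.6, landing_radius = landing, dwell = dwell)
  )
}

hold_trace <- function(gx, gy, duration, fps = 30, t0 = 0) {
  n <- round(duration * fps)
  tibble::tibble(t = t0 + seq_len(n) / fps, gx = gx, gy = gy)
}

test_that("holding gaze on a target for the threshold fires exactly one trigger", {
  scene <- gaze_scene(three_targets(dwell = 0.5), schedule = NULL)
  scene <- run_interaction(scene, hold_trace(0.5, 0.4, 2))
  ev <- interaction_events(scene)
  expect_equal(sum(ev$type == "trigger"), 1)
  expect_equal(ev$target[ev$type == "trigger"], "b")
  expect_equal(sum(ev$type == "hover_enter"), 1)
  # linked event id is forwarded
  expect_equal(ev$event_id[ev$type == "trigger"], "b")
})

test_that("fast sweeps across all targets trigger nothing (Midas touch)", {
  scene <- gaze_scene(three_targets(dwell = 1.5), schedule = NULL)
  # a 0.5 s sweep passing through every target center
  n <- 15
  trace <- tibble::tibble(
    t = seq_len(n) / 30,
    gx = seq(0.1, 0.9, length.out = n),
    gy = seq(0.13, 0.67, length.out = n)
  )
  scene <- run_interaction(scene, trace)
  ev <- interaction_events(scene)
  expect_equal(sum(ev$type == "trigger"), 0)
  expect_gt(sum(ev$type == "hover_enter"), 0)
})

test_that("zero dwell threshold triggers on the first in-zone sample", {
  scene <- gaze_scene(three_targets(dwell = 0), schedule = NULL)
  scene <- scene_step(scene, c(0.5, 0.4), dt = 1 / 30)
  ev <- interaction_events(scene)
  expect_equal(sum(ev$type == "trigger"), 1)
})

test_that("landing zones capture ambient fixation beyond the visual radius", {
  tg <- interactive_target("a", 0.5, 0.4, visual_radius = 0.03,
                           landing_radius = 0.12, dwell = 1)
  scene <- gaze_scene(list(tg), schedule = NULL)
  # gaze inside the landing zone but outside the visible circle
  scene <- scene_step(scene, c(0.58, 0.4), dt = 1 / 30)
  ev <- interaction_events(scene)
  expect_equal(sum(ev$type == "hover_enter"), 1)
  expect_true(ev$highlight[ev$type == "hover_enter"])
})

test_that("re-arming requires hover exit; re-entry can trigger again", {
  scene <- gaze_scene(three_targets(dwell = 0.3), schedule = NULL)
  scene <- run_interaction(scene, hold_trace(0.5, 0.4, 1))
  scene <- run_interaction(scene, hold_trace(0.9, 0.1, 0.5, t0 = 1))   # away
  scene <- run_interaction(scene, hold_trace(0.5, 0.4, 1, t0 = 1.5))
  ev <- interaction_events(scene)
  expect_equal(sum(ev$type == "trigger"), 2)
})

test_that("short gaze dropouts pause the dwell; long ones reset it", {
  tg <- list(interactive_target("a", 0.5, 0.4, landing_radius = 0.1,
                                dwell = 0.4))
  # 0.3 s dwell, 0.1 s missing (held), then 0.2 s more -> trigger
  scene <- gaze_scene(tg, schedule = NULL)
  scene <- run_interaction(scene, hold_trace(0.5, 0.4, 0.3))
  for (k in 1:3) scene <- scene_step(scene, NULL, dt = 1 / 30)
  scene <- run_interaction(scene, hold_trace(0.5, 0.4, 0.2, t0 = 0.4))
  expect_equal(sum(interaction_events(scene)$type == "trigger"), 1)
  # same but with a 0.4 s dropout -> reset, no trigger from the second leg alone
  scene2 <- gaze_scene(tg, schedule = NULL)
  scene2 <- run_interaction(scene2, hold_trace(0.5, 0.4, 0.3))
  for (k in 1:12) scene2 <- scene_step(scene2, NULL, dt = 1 / 30)
  scene2 <- run_interaction(scene2, hold_trace(0.5, 0.4, 0.2, t0 = 0.7))
  expect_equal(sum(interaction_events(scene2)$type == "trigger"), 0)
})

test_that("overlapping zones resolve to the nearest target center", {
  tgs <- list(
    interactive_target("near", 0.50, 0.40, landing_radius = 0.2, dwell = 0),
    interactive_target("far", 0.60, 0.40, landing_radius = 0.2, dwell = 0)
  )
  scene <- gaze_scene(tgs, schedule = NULL)
  scene <- scene_step(scene, c(0.52, 0.40), dt = 1 / 30)
  ev <- interaction_events(scene)
  expect_equal(ev$target[ev$type == "trigger"], "near")
})

test_that("triggers emit calibration samples from the buffered median features", {
  tg <- list(interactive_target("a", 0.25, 0.4, landing_radius = 0.1,
                                dwell = 0.2))
  scene <- gaze_scene(tg, schedule = NULL)
  trace <- hold_trace(0.25, 0.4, 0.5)
  trace$x <- -30 + c(rep(0, 12), rep(3, 3))  # late microsaccade outlier
  trace$y <- -20
  trace$m <- 220
  trace$n <- 150
  scene <- run_interaction(scene, trace)
  smp <- calibration_samples(scene)
  expect_equal(nrow(smp), 1)
  expect_equal(c(smp$gx, smp$gy), c(0.25, 0.4))
  expect_equal(smp$x, -30)  # median rejects the outlier
  expect_equal(smp$source, "ui-trigger")
})

test_that("blink-heavy dwells fire the event but emit no sample", {
  tg <- list(interactive_target("a", 0.25, 0.4, landing_radius = 0.1,
                                dwell = 0.2))
  scene <- gaze_scene(tg, schedule = NULL)
  trace <- hold_trace(0.25, 0.4, 0.4)
  trace$x <- -30; trace$y <- -20; trace$m <- 220; trace$n <- 150
  trace$valid <- rep(c(FALSE, FALSE, FALSE, TRUE, FALSE), length.out = nrow(trace))
  scene <- run_interaction(scene, trace)
  ev <- interaction_events(scene)
  expect_equal(sum(ev$type == "trigger"), 1)
  expect_false(ev$sample_emitted[ev$type == "trigger"])
  expect_equal(nrow(calibration_samples(scene)), 0)
})

test_that("landing radius shrinks with samples, floors, and re-expands on error spikes", {
  sch <- zone_schedule(initial = 0.12, minimum = 0.062,
                       shrink_per_sample = 0.004, error_trigger = 8)
  expect_equal(landing_radius(sch, 0), 0.12)
  expect_equal(landing_radius(sch, 5), 0.12 - 0.02)
  expect_equal(landing_radius(sch, 1000), 0.062)  # floor
  r <- landing_radius(sch, 0:40)
  expect_true(all(diff(r) <= 0))
  # error spike re-expands, bounded by the initial radius
  expect_gt(landing_radius(sch, 10, recent_error = 12),
            landing_radius(sch, 10, recent_error = 0))
  expect_lte(landing_radius(sch, 0, recent_error = 50), 0.12)
  # re-shrinks once the error clears and samples accumulate
  expect_lt(landing_radius(sch, 30, recent_error = 0),
            landing_radius(sch, 10, recent_error = 12))
})

test_that("false-trigger rate on random-walk gaze falls as zones shrink", {
  tgs <- three_targets(dwell = 0.4)
  tgs <- purrr::map(tgs, function(tg) { tg$landing_radius <- NULL; tg })
  count_triggers <- function(n_samples, seed) {
    sch <- zone_schedule()
    scene <- gaze_scene(tgs, schedule = sch)
    scene$n_samples <- n_samples
    trace <- withr::with_seed(seed, {
      n <- 240
      tibble::tibble(
        t = seq_len(n) / 30,
        gx = pmin(pmax(cumsum(stats::rnorm(n, 0, 0.02)) + 0.5, 0), 1),
        gy = pmin(pmax(cumsum(stats::rnorm(n, 0, 0.02)) + 0.37, 0), 0.75)
      )
    })
    scene <- run_interaction(scene, trace)
    sum(interaction_events(scene)$type == "trigger")
  }
  wide <- sum(vapply(1:8, function(s) count_triggers(0, s), numeric(1)))
  narrow <- sum(vapply(1:8, function(s) count_triggers(1000, s), numeric(1)))
  expect_lte(narrow, wide)
})

test_that("scene descriptions round-trip through YAML and JSON", {
  tgs <- three_targets()
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_scene(tgs, path)
    back <- read_scene(path)
    expect_equal(length(back), 3)
    expect_equal(back[[2]]$id, "b")
    expect_equal(unname(back[[2]]$center), c(0.5, 0.4))
    expect_equal(back[[2]]$dwell_threshold, 1.5)
  }
})

test_that("target invariants are enforced", {
  expect_error(interactive_target("a", 0.5, 0.5, visual_radius = 0.1,
                                  landing_radius = 0.05), "at least")
  expect_error(interactive_target("a", 0.5, 0.5, dwell = -1), ">= 0")
  expect_error(zone_schedule(initial = 0.05, minimum = 0.1))
})
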