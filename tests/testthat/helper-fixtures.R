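# Small shared fixtures; everything is generated in code at test time.

# quarter-size render config keeps per-frame cost low in unit tests
small_render <- function(noise_sd = 0.01, ...) {
  render_config(width = 320, height = 240, pupil_axes = c(20, 15),
                iris_radius = 45, corner_size = 20,
                outer_offset = c(-90, -3), noise_sd = noise_sd, ...)
}

small_features <- function(x = -35, y = -25, m = 220, n = 150, blink = FALSE) {
  list(x = x, y = y, m = m, n = n, blink = blink)
}

# noise-free 12-sample design spanning gaze x pose, well conditioned for
# any spec up to 15 terms when poses vary
conditioned_features <- function(n = 20, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      x = stats::runif(n, -40, 40),
      y = stats::runif(n, -30, 30),
      m = 400 + stats::runif(n, -40, 40),
      n = 300 + stats::runif(n, -40, 40)
    )
  })
}

expect_px_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}
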