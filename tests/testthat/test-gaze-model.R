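test_that("noise-free coefficient recovery is exact for any spec", {
  for (spec in gaze_model_library()) {
    N <- n_coefficients(spec)
    feats <- conditioned_features(n = N + 12, seed = N)
    V <- basis_matrix(feats, spec)
    c0 <- withr::with_seed(N + 1, matrix(stats::rnorm(2 * N, sd = 0.01), N, 2))
    G <- V %*% c0
    m <- gaze_model(spec)
    m <- append_sample(m, feats, tibble::tibble(gx = G[, 1], gy = G[, 2]))
    rel <- max(abs(m$coef - c0)) / max(abs(c0))
    expect_lt(rel, 1e-8)
    pred <- predict(m, feats)
    expect_lt(max(abs(cbind(pred$gx, pred$gy) - G)), 1e-8)
  }
})

test_that("an exactly determined system interpolates with zero residual", {
  spec <- default_gaze_spec()
  feats <- conditioned_features(n = 8, seed = 3)
  targets <- withr::with_seed(4, tibble::tibble(gx = stats::runif(8),
                                                gy = stats::runif(8, 0, 0.75)))
  m <- append_sample(gaze_model(spec), feats, targets)
  expect_equal(nrow(m$V), 8)
  pred <- predict(m, feats)
  expect_lt(max(abs(pred$gx - targets$gx)), 1e-8)
  expect_lt(max(abs(pred$gy - targets$gy)), 1e-8)
})

test_that("duplicating all rows leaves the solution unchanged", {
  spec <- default_gaze_spec()
  feats <- conditioned_features(n = 12, seed = 5)
  targets <- withr::with_seed(6, tibble::tibble(gx = stats::runif(12),
                                                gy = stats::runif(12, 0, 0.75)))
  m1 <- append_sample(gaze_model(spec), feats, targets)
  m2 <- append_sample(m1, feats, targets)
  expect_equal(m2$coef, m1$coef, tolerance = 1e-10)
})

test_that("refit is idempotent and append-then-fit equals batch fit", {
  spec <- default_gaze_spec()
  feats <- conditioned_features(n = 14, seed = 8)
  targets <- withr::with_seed(9, tibble::tibble(gx = stats::runif(14),
                                                gy = stats::runif(14, 0, 0.75)))
  batch <- append_sample(gaze_model(spec), feats, targets)
  incr <- gaze_model(spec)
  for (i in seq_len(14)) {
    incr <- append_sample(incr, feats[i, ], targets[i, ],
                          refit = i >= n_coefficients(spec))
  }
  expect_equal(incr$coef, batch$coef, tolerance = 1e-10)
  expect_equal(fit_gaze_model(batch)$coef, batch$coef, tolerance = 1e-12)
})

test_that("underdetermined fits error; rank-deficient fits warn", {
  spec <- default_gaze_spec()
  feats <- conditioned_features(n = 5)
  m <- append_sample(gaze_model(spec), feats,
                     tibble::tibble(gx = stats::runif(5), gy = stats::runif(5)),
                     refit = FALSE)
  expect_error(fit_gaze_model(m), "Not enough calibration samples")
  # constant corner columns (single pose) collide with the constant term
  feats2 <- conditioned_features(n = 10)
  feats2$m <- 400; feats2$n <- 300
  m2 <- append_sample(gaze_model(spec), feats2,
                      tibble::tibble(gx = stats::runif(10), gy = stats::runif(10)),
                      refit = FALSE)
  expect_warning(fit_gaze_model(m2), "rank-deficient")
})

test_that("screen-affine rescaling of targets rescales predictions exactly", {
  spec <- default_gaze_spec()
  feats <- conditioned_features(n = 12, seed = 11)
  targets <- withr::with_seed(12, tibble::tibble(gx = stats::runif(12),
                                                 gy = stats::runif(12, 0, 0.75)))
  m1 <- append_sample(gaze_model(spec), feats, targets)
  scaled <- tibble::tibble(gx = 2 * targets$gx + 0.1, gy = 3 * targets$gy - 0.2)
  m2 <- append_sample(gaze_model(spec), feats, scaled)
  p1 <- predict(m1, feats[1:4, ])
  p2 <- predict(m2, feats[1:4, ])
  expect_equal(p2$gx, 2 * p1$gx + 0.1, tolerance = 1e-8)
  expect_equal(p2$gy, 3 * p1$gy - 0.2, tolerance = 1e-8)
})

test_that("appending a model-consistent sample barely moves the fit", {
  spec <- default_gaze_spec()
  N <- n_coefficients(spec)
  feats <- conditioned_features(n = 20, seed = 13)
  V <- basis_matrix(feats, spec)
  c0 <- withr::with_seed(14, matrix(stats::rnorm(2 * N, sd = 0.01), N, 2))
  G <- V %*% c0
  m <- append_sample(gaze_model(spec), feats[1:19, ],
                     tibble::tibble(gx = G[1:19, 1], gy = G[1:19, 2]))
  before <- m$coef
  m <- append_sample(m, feats[20, ], c(G[20, 1], G[20, 2]))
  expect_equal(nrow(m$V), 20)
  expect_lt(max(abs(m$coef - before)), 1e-6)
})

test_that("per-eye averaging handles missing eyes per the fallback contract", {
  expect_equal(combine_eyes(c(0.4, 0.5), c(0.6, 0.5)),
               tibble::tibble(gx = 0.5, gy = 0.5))
  expect_equal(combine_eyes(c(0.3, 0.3), c(0.3, 0.3)),
               tibble::tibble(gx = 0.3, gy = 0.3))
  expect_equal(combine_eyes(NULL, c(0.3, 0.3)),
               tibble::tibble(gx = 0.3, gy = 0.3))
  expect_equal(combine_eyes(c(NA, NA), c(0.3, 0.3)),
               tibble::tibble(gx = 0.3, gy = 0.3))
  both <- combine_eyes(NULL, NULL)
  expect_true(is.na(both$gx) && is.na(both$gy))
})

test_that("median fixation features are robust to outliers and quota-gated", {
  buf <- tibble::tibble(
    x = c(rep(10, 9), 30), y = c(rep(10, 9), 30),
    m = rep(100, 10), n = rep(100, 10), valid = TRUE
  )
  med <- median_fixation_features(buf)
  expect_equal(unlist(med), c(x = 10, y = 10, m = 100, n = 100))
  # constant buffer returns the constant
  bufc <- tibble::tibble(x = 5, y = 6, m = 7, n = 8, valid = TRUE)[rep(1, 6), ]
  expect_equal(unlist(median_fixation_features(bufc)),
               c(x = 5, y = 6, m = 7, n = 8))
  # alternating +/- 1 px tremor cancels
  buft <- tibble::tibble(x = 10 + c(-1, 1), y = 10 + c(1, -1),
                         m = 100, n = 100, valid = TRUE)[rep(1:2, 5), ]
  expect_equal(median_fixation_features(buft)$x, 10)
  # 60% invalid frames -> no sample
  bufb <- buf
  bufb$valid <- rep(c(FALSE, FALSE, FALSE, TRUE, TRUE), 2)
  expect_null(median_fixation_features(bufb, min_valid_frac = 0.5))
  expect_null(median_fixation_features(buf[0, ]))
})

test_that("tidy and glance summarize a fitted model", {
  feats <- conditioned_features(n = 12, seed = 15)
  targets <- withr::with_seed(16, tibble::tibble(gx = stats::runif(12),
                                                 gy = stats::runif(12, 0, 0.75)))
  m <- append_sample(gaze_model(default_gaze_spec(), eye = "left"),
                     feats, targets)
  td <- tidy(m)
  expect_equal(nrow(td), 16)
  expect_setequal(unique(td$coordinate), c("gx", "gy"))
  gl <- glance(m)
  expect_equal(gl$n_samples, 12)
  expect_equal(gl$n_terms, 8)
  expect_true(gl$rmse >= 0)
})

test_that("model state round-trips through JSON", {
  feats <- conditioned_features(n = 10, seed = 17)
  targets <- withr::with_seed(18, tibble::tibble(gx = stats::runif(10),
                                                 gy = stats::runif(10, 0, 0.75)))
  m <- append_sample(gaze_model(default_gaze_spec(), eye = "right"),
                     feats, targets)
  path <- withr::local_tempfile(fileext = ".json")
  write_gaze_model(m, path)
  m2 <- read_gaze_model(path)
  expect_equal(m2$spec$terms, m$spec$terms)
  expect_equal(m2$V, m$V, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(m2$coef, m$coef, ignore_attr = TRUE, tolerance = 1e-12)
  p1 <- predict(m, feats[1, ]); p2 <- predict(m2, feats[1, ])
  expect_equal(p1, p2, tolerance = 1e-10)
})
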