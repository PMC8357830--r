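#' Polynomial gaze regression model with online sample appending
#'
#' A gaze model maps the 4D eye feature vector `e = (x, y, m, n)` to a 2D
#' screen gaze point `g = (gx, gy)` (normalized units, screen width = 1).
#' Calibration samples are accumulated as rows of an observation matrix `V`
#' (monomial basis rows) and a target matrix `G`; the coefficient matrix `c`
#' (`N x 2`) solves the least-squares problem `G = V c`. The model is
#' designed for progressive calibration: every confirmed gaze selection can
#' be appended with [append_sample()] and the model is refit immediately, so
#' accuracy improves (and adapts to head-pose change) as the session runs.
#'
#' One model instance is kept per eye; the final gaze estimate is the mean of
#' the per-eye predictions ([combine_eyes()]).
#'
#' @param spec A [gaze_model_spec()]; defaults to the adopted 8-term spec.
#' @param eye Optional label (`"left"`, `"right"`), carried in printouts.
#' @return An object of class `gaze_model`.
#' @examples
#' m <- gaze_model()
#' feats <- tibble::tibble(x = rnorm(12), y = rnorm(12),
#'                         m = 400 + rnorm(12), n = 300 + rnorm(12))
#' targets <- tibble::tibble(gx = runif(12), gy = runif(12, 0, 0.75))
#' m <- append_sample(m, feats, targets)
#' predict(m, feats[1, ])
#' @export
gaze_model <- function(spec = default_gaze_spec(), eye = NULL) {
  stopifnot(inherits(spec, "gaze_model_spec"))
  structure(
    list(
      spec = spec,
      eye = eye,
      V = matrix(numeric(0), nrow = 0, ncol = n_coefficients(spec)),
      G = matrix(numeric(0), nrow = 0, ncol = 2),
      coef = NULL,
      rank = NA_integer_
    ),
    class = "gaze_model"
  )
}

#' @export
print.gaze_model <- function(x, ...) {
  cat(sprintf(
    "<gaze_model> %s%s: M = %d samples, N = %d terms, %s\n",
    x$spec$name,
    if (!is.null(x$eye)) paste0(" [", x$eye, " eye]") else "",
    nrow(x$V), n_coefficients(x$spec),
    if (is.null(x$coef)) "unfitted" else sprintf("fitted (rank %d)", x$rank)
  ))
  invisible(x)
}

#' Append calibration samples and refit
#'
#' Adds one row per sample to both `V` (basis-expanded features) and `G`
#' (known target centers), keeping all prior rows with equal weight, then
#' refits immediately when enough samples are available (`M >= N`).
#'
#' @param model A [gaze_model()].
#' @param features Feature vector(s): a numeric `(x, y, m, n)` vector or a
#'   data frame with columns `x`, `y`, `m`, `n`.
#' @param target Matching target(s): numeric `(gx, gy)` or a data frame with
#'   columns `gx`, `gy`, in normalized screen units.
#' @param refit Refit after appending (default `TRUE`). Refitting with
#'   unchanged data is idempotent.
#' @return The updated `gaze_model`.
#' @export
append_sample <- function(model, features, target, refit = TRUE) {
  stopifnot(inherits(model, "gaze_model"))
  Vnew <- basis_matrix(features, model$spec)
  Gnew <- as_target_matrix(target)
  if (nrow(Vnew) != nrow(Gnew)) {
    rlang::abort("`features` and `target` must have the same number of rows.")
  }
  model$V <- rbind(model$V, Vnew)
  model$G <- rbind(model$G, Gnew)
  if (refit && nrow(model$V) >= n_coefficients(model$spec)) {
    model <- fit_gaze_model(model)
  }
  model
}

as_target_matrix <- function(target) {
  if (is.data.frame(target)) {
    as.matrix(target[, c("gx", "gy")])
  } else {
    v <- as.numeric(target)
    if (length(v) %% 2 != 0) rlang::abort("A gaze target has 2 coordinates.")
    matrix(v, ncol = 2, byrow = TRUE)
  }
}

#' Fit the gaze model by rank-tolerant least squares
#'
#' Solves `G = V c` in the least-squares sense via the singular value
#' decomposition with a relative rank tolerance of `1e-10` (the Moore-Penrose
#' pseudo-inverse), which is numerically equivalent to the normal-equation
#' solution `c = (V'V)^{-1} V'G` on well-conditioned data but returns the
#' minimum-norm solution (with a warning) instead of failing when `V` is
#' rank-deficient — as happens, for instance, while every calibration sample
#' still comes from a single head pose so the corner columns are constant.
#'
#' @param model A [gaze_model()] with at least `N` appended samples.
#' @param rank_tol Relative singular-value cutoff.
#' @return The fitted `gaze_model` (fields `coef`, `rank` populated).
#' @export
fit_gaze_model <- function(model, rank_tol = 1e-10) {
  stopifnot(inherits(model, "gaze_model"))
  M <- nrow(model$V)
  N <- n_coefficients(model$spec)
  if (M < N) {
    rlang::abort(sprintf(
      "Not enough calibration samples to fit: M = %d < N = %d.", M, N
    ))
  }
  sv <- svd(model$V)
  keep <- sv$d > rank_tol * sv$d[1]
  r <- sum(keep)
  if (r < N) {
    rlang::warn(sprintf(
      "Observation matrix is rank-deficient (rank %d < %d terms); returning the minimum-norm solution.",
      r, N
    ))
  }
  dinv <- ifelse(keep, 1 / sv$d, 0)
  model$coef <- sv$v %*% (dinv * (t(sv$u) %*% model$G))
  rownames(model$coef) <- model$spec$terms
  colnames(model$coef) <- c("gx", "gy")
  model$rank <- r
  model
}

#' Predict on-screen gaze from eye features
#'
#' @param object A fitted [gaze_model()].
#' @param newdata Feature vector(s): numeric `(x, y, m, n)` or a data frame
#'   with columns `x`, `y`, `m`, `n`. Rows with any `NA` feature yield `NA`
#'   predictions (missing-gaze marker).
#' @param ... Unused.
#' @return A tibble with columns `gx`, `gy` (normalized screen units).
#' @export
predict.gaze_model <- function(object, newdata, ...) {
  if (is.null(object$coef)) {
    rlang::abort("Model is unfitted; append at least N samples and fit first.")
  }
  V <- basis_matrix(newdata, object$spec)
  g <- V %*% object$coef
  tibble::tibble(gx = g[, 1], gy = g[, 2])
}

#' Average the two per-eye gaze predictions
#'
#' The final gaze location is the unweighted mean of the points predicted by
#' the separate per-eye models. If one eye's prediction is missing (e.g. its
#' pupil was not detected) the other is used alone; if both are missing, an
#' `NA` row (missing-gaze marker) is returned.
#'
#' @param g_left,g_right Gaze points: numeric `(gx, gy)` vectors or data
#'   frames with columns `gx`, `gy`; `NULL` or `NA` marks a missing
#'   prediction.
#' @return A tibble with columns `gx`, `gy`.
#' @export
combine_eyes <- function(g_left, g_right) {
  L <- eye_pred_matrix(g_left)
  R <- eye_pred_matrix(g_right)
  if (is.null(L) && is.null(R)) {
    return(tibble::tibble(gx = NA_real_, gy = NA_real_))
  }
  if (is.null(L)) L <- matrix(NA_real_, nrow(R), 2)
  if (is.null(R)) R <- matrix(NA_real_, nrow(L), 2)
  if (nrow(L) != nrow(R)) rlang::abort("Per-eye predictions differ in length.")
  gx <- rowMeans(cbind(L[, 1], R[, 1]), na.rm = TRUE)
  gy <- rowMeans(cbind(L[, 2], R[, 2]), na.rm = TRUE)
  gx[is.nan(gx)] <- NA_real_
  gy[is.nan(gy)] <- NA_real_
  tibble::tibble(gx = gx, gy = gy)
}

eye_pred_matrix <- function(g) {
  if (is.null(g)) return(NULL)
  if (is.data.frame(g)) return(cbind(g$gx, g$gy))
  v <- as.numeric(g)
  if (all(is.na(v))) return(NULL)
  matrix(v, ncol = 2, byrow = TRUE)
}

#' Median feature vector over a fixation frame buffer
#'
#' Even during steady fixation the pupil jitters (tremor, drift,
#' microsaccades), so the feature vector attached to a calibration target is
#' the component-wise median of the per-frame features buffered while the
#' target was fixated. Only frames with a valid pupil detection contribute; a
#' buffer with fewer than `min_valid_frac` valid frames emits no sample.
#'
#' @param frames A data frame with columns `x`, `y`, `m`, `n` and logical
#'   `valid`.
#' @param min_valid_frac Minimum fraction of valid frames required to emit a
#'   sample (default 0.5).
#' @return A one-row tibble `(x, y, m, n)`, or `NULL` when the buffer fails
#'   the validity quota.
#' @export
median_fixation_features <- function(frames, min_valid_frac = 0.5) {
  if (is.null(frames) || nrow(frames) == 0) return(NULL)
  valid <- if ("valid" %in% names(frames)) frames$valid else rep(TRUE, nrow(frames))
  valid[is.na(valid)] <- FALSE
  if (sum(valid) == 0 || mean(valid) < min_valid_frac) return(NULL)
  ok <- frames[valid, ]
  tibble::tibble(
    x = stats::median(ok$x), y = stats::median(ok$y),
    m = stats::median(ok$m), n = stats::median(ok$n)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the coefficients of a fitted gaze model
#'
#' @param x A fitted [gaze_model()].
#' @param ... Unused.
#' @return A tibble with one row per (term, gaze coordinate) pair and columns
#'   `term`, `coordinate`, `estimate`.
#' @method tidy gaze_model
#' @export
tidy.gaze_model <- function(x, ...) {
  if (is.null(x$coef)) rlang::abort("Model is unfitted.")
  tibble::tibble(
    term = rep(x$spec$terms, times = 2),
    coordinate = rep(c("gx", "gy"), each = n_coefficients(x$spec)),
    estimate = c(x$coef[, 1], x$coef[, 2])
  )
}

#' One-row summary of a gaze model fit
#'
#' @param x A [gaze_model()].
#' @param ... Unused.
#' @return A tibble with columns `model`, `n_terms`, `n_samples`, `rank`,
#'   `rmse` (in-sample residual RMS distance, % of screen width).
#' @method glance gaze_model
#' @export
glance.gaze_model <- function(x, ...) {
  rmse <- NA_real_
  if (!is.null(x$coef) && nrow(x$V) > 0) {
    resid <- x$G - x$V %*% x$coef
    rmse <- 100 * sqrt(mean(rowSums(resid^2)))
  }
  tibble::tibble(
    model = x$spec$name,
    n_terms = n_coefficients(x$spec),
    n_samples = nrow(x$V),
    rank = x$rank,
    rmse = rmse
  )
}

#' Serialize / restore a gaze model as JSON
#'
#' Stores the spec's monomials, the accumulated `V` and `G` matrices and the
#' current coefficients, so a session's calibration state can be saved and
#' resumed.
#'
#' @param model A [gaze_model()].
#' @param path File path to write to / read from.
#' @return `write_gaze_model()` returns `path` invisibly;
#'   `read_gaze_model()` returns the restored `gaze_model`.
#' @export
write_gaze_model <- function(model, path) {
  stopifnot(inherits(model, "gaze_model"))
  obj <- list(
    spec = list(name = model$spec$name, terms = model$spec$terms),
    eye = model$eye,
    V = model$V,
    G = model$G,
    coef = model$coef
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_gaze_model
#' @export
read_gaze_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- gaze_model_spec(obj$spec$terms, name = obj$spec$name)
  model <- gaze_model(spec, eye = obj$eye)
  if (length(obj$V) > 0) {
    model$V <- matrix(as.numeric(obj$V), ncol = n_coefficients(spec))
    model$G <- matrix(as.numeric(obj$G), ncol = 2)
  }
  if (!is.null(obj$coef) && length(obj$coef) > 0) {
    model$coef <- matrix(as.numeric(obj$coef), ncol = 2,
                         dimnames = list(spec$terms, c("gx", "gy")))
    sv <- svd(model$V)
    model$rank <- sum(sv$d > 1e-10 * sv$d[1])
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
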