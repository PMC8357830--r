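#' Assemble the 4D eye feature vector from a frame's detections
#'
#' The per-frame feature vector is `e = (x, y, m, n)` where `(m, n)` is the
#' tracked inner eye-corner position and `(x, y) = (px - m, py - n)` are the
#' pupil coordinates relative to the corner; the subtraction is exact. An
#' invalid pupil detection (blink, occlusion) propagates a missing-feature
#' marker (`NA` pupil fields, `valid = FALSE`) rather than an error.
#'
#' @param pupil A [segment_pupil()] result.
#' @param track A `corner_track`.
#' @param t Frame timestamp, seconds.
#' @return A one-row tibble with columns `t`, `px`, `py`, `m`, `n`, `x`, `y`,
#'   `valid`.
#' @export
extract_features <- function(pupil, track, t = NA_real_) {
  m <- unname(track$corner[1]); n <- unname(track$corner[2])
  if (isTRUE(pupil$valid)) {
    px <- unname(pupil$center[1]); py <- unname(pupil$center[2])
    tibble::tibble(t = t, px = px, py = py, m = m, n = n,
                   x = px - m, y = py - n, valid = TRUE)
  } else {
    tibble::tibble(t = t, px = NA_real_, py = NA_real_, m = m, n = n,
                   x = NA_real_, y = NA_real_, valid = FALSE)
  }
}

#' Run the full vision front end over an eye-camera frame sequence
#'
#' For each frame: update the corner tracker, segment the pupil inside the
#' current eye-region box, and emit the feature vector. Frames can be
#' supplied as a list of matrices or as a provider function `function(i)`
#' returning the i-th frame (so long sequences never need to be held in
#' memory at once).
#'
#' @param frames List of grayscale matrices, or `function(i)` frame provider.
#' @param n_frames Number of frames (required when `frames` is a function).
#' @param inner,outer Operator corner marks on the first frame.
#' @param times Optional timestamps (default `0, 1/fps, ...`).
#' @param fps Frame rate used when `times` is missing.
#' @param backend Tracker backend for [init_corner_tracker()].
#' @param pupil_config A [pupil_config()].
#' @param ... Passed to [init_corner_tracker()].
#' @return A tibble with one row per frame: the [extract_features()] columns
#'   plus `corner_lost`.
#' @export
track_eye_sequence <- function(frames, inner, outer, n_frames = NULL,
                               times = NULL, fps = 30,
                               backend = ncc_tracker(),
                               pupil_config = progaze::pupil_config(), ...) {
  get_frame <- if (is.function(frames)) {
    stopifnot(!is.null(n_frames))
    frames
  } else {
    n_frames <- length(frames)
    function(i) frames[[i]]
  }
  if (is.null(times)) times <- (seq_len(n_frames) - 1) / fps

  first <- get_frame(1)
  track <- init_corner_tracker(first, inner, outer, backend = backend, ...)
  out <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    fr <- if (i == 1) first else get_frame(i)
    if (i > 1) track <- update_corner_tracker(track, fr)
    pup <- segment_pupil(fr, track$eye_region, pupil_config)
    row <- extract_features(pup, track, t = times[i])
    row$corner_lost <- track$lost
    out[[i]] <- row
  }
  dplyr::bind_rows(out)
}

#' Write / read a per-eye feature log as CSV
#'
#' One file per eye with columns `t`, `px`, `py`, `m`, `n`, `x`, `y`,
#' `valid`.
#'
#' @param features Feature tibble (as from [track_eye_sequence()]).
#' @param path CSV path.
#' @return `write_features_csv()` returns `path` invisibly;
#'   `read_features_csv()` returns the tibble.
#' @export
write_features_csv <- function(features, path) {
  cols <- intersect(c("t", "px", "py", "m", "n", "x", "y", "valid"),
                    names(features))
  utils::write.csv(features[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path)
  df$valid <- as.logical(df$valid)
  tibble::as_tibble(df)
}
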