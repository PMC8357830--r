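#' Write / read a session record as JSON-lines + CSV fixation table
#'
#' The per-frame record is written as JSON-lines (one JSON object per
#' frame), and the per-fixation table as CSV next to it (same stem,
#' `_fixations.csv` suffix), so downstream tooling can consume either
#' granularity.
#'
#' @param session A `gaze_session`.
#' @param path Path of the JSON-lines file.
#' @return `write_session_jsonl()` returns `path` invisibly;
#'   `read_session_jsonl()` returns a list with tibbles `frames` and
#'   `fixations` (the script itself is not round-tripped).
#' @export
write_session_jsonl <- function(session, path) {
  stopifnot(inherits(session, "gaze_session"))
  con <- file(path, open = "w")
  on.exit(close(con))
  jsonlite::stream_out(as.data.frame(session$frames), con, verbose = FALSE,
                       digits = NA)
  fix_path <- fixations_path(path)
  utils::write.csv(session$fixations, fix_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_jsonl
#' @export
read_session_jsonl <- function(path) {
  con <- file(path, open = "r")
  on.exit(close(con))
  frames <- tibble::as_tibble(jsonlite::stream_in(con, verbose = FALSE))
  fix_path <- fixations_path(path)
  fixations <- NULL
  if (file.exists(fix_path)) {
    fixations <- tibble::as_tibble(utils::read.csv(fix_path))
    fixations$valid <- as.logical(fixations$valid)
  }
  list(frames = frames, fixations = fixations)
}

fixations_path <- function(path) {
  paste0(sub("\\.jsonl?$", "", path), "_fixations.csv")
}

#' Write an interaction event log as JSON-lines
#'
#' One JSON object per emitted event, timestamped, suitable for replay and
#' diagnosis.
#'
#' @param events An [interaction_events()] tibble (or a scene, from which
#'   the events are taken).
#' @param path Path of the JSON-lines file.
#' @return `path`, invisibly.
#' @export
write_events_jsonl <- function(events, path) {
  if (inherits(events, "gaze_scene")) events <- interaction_events(events)
  con <- file(path, open = "w")
  on.exit(close(con))
  jsonlite::stream_out(as.data.frame(events), con, verbose = FALSE,
                       digits = NA)
  invisible(path)
}

#' Write an eye frame (or any grayscale matrix) as PNG
#'
#' @param image Matrix in `[0, 1]`, or an `eye_frame`.
#' @param path PNG path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(image, path) {
  if (inherits(image, "eye_frame")) image <- image$image
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname write_frame_png
#' @export
read_frame_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
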