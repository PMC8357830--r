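#' Normalized cross-correlation template tracker backend
#'
#' The baseline tracker backend: a correlation-filter-family tracker that
#' matches a fixed-size template around the last known position by
#' normalized cross-correlation, with parabolic sub-pixel refinement, an
#' optional slow template update, and a correlation confidence score used to
#' flag lost tracking. Any backend implementing the same `init`/`update`
#' contract can be plugged into [init_corner_tracker()].
#'
#' @param template_size Side of the square template, pixels.
#' @param search_radius Search radius around the last position, pixels.
#' @param update_rate Template running-average rate in `[0, 1]`; 0 keeps the
#'   initial template.
#' @param conf_threshold NCC score below which the track is flagged lost.
#' @param subpixel Refine the peak to sub-pixel accuracy.
#' @return A list of class `tracker_backend` with functions
#'   `init(frame, center, ...)` and `update(state, frame)`; `update` returns
#'   `list(state, center, confidence)`.
#' @export
ncc_tracker <- function(template_size = 32, search_radius = 14,
                        update_rate = 0.05, conf_threshold = 0.4,
                        subpixel = TRUE) {
  init <- function(frame, center) {
    tmpl <- crop_centered(frame, center, template_size)
    list(template = tmpl, center = center, size = template_size)
  }
  update <- function(state, frame) {
    h <- nrow(frame); w <- ncol(frame)
    half <- state$size / 2
    cx <- state$center[1]; cy <- state$center[2]
    offs <- -search_radius:search_radius
    tmpl <- as.numeric(state$template)
    tmpl <- tmpl - mean(tmpl)
    tnorm <- sqrt(sum(tmpl^2))
    score <- matrix(-Inf, length(offs), length(offs))
    for (iy in seq_along(offs)) {
      for (ix in seq_along(offs)) {
        px <- round(cx) + offs[ix]; py <- round(cy) + offs[iy]
        if (px - half < 0 || px + half > w || py - half < 0 || py + half > h) next
        patch <- as.numeric(crop_centered(frame, c(px, py), state$size))
        patch <- patch - mean(patch)
        pn <- sqrt(sum(patch^2))
        if (pn < 1e-9 || tnorm < 1e-9) next
        score[iy, ix] <- sum(patch * tmpl) / (pn * tnorm)
      }
    }
    best <- which(score == max(score), arr.ind = TRUE)[1, ]
    conf <- score[best[1], best[2]]
    dx <- offs[best[2]]; dy <- offs[best[1]]
    if (subpixel) {
      dx <- dx + parabolic_offset(score, best[1], best[2], axis = "x")
      dy <- dy + parabolic_offset(score, best[1], best[2], axis = "y")
    }
    center <- c(round(cx) + dx, round(cy) + dy)
    if (is.finite(conf) && conf >= conf_threshold && update_rate > 0) {
      new_patch <- crop_centered(frame, round(center), state$size)
      state$template <- (1 - update_rate) * state$template +
        update_rate * new_patch
    }
    state$center <- center
    list(state = state, center = center, confidence = conf)
  }
  structure(
    list(init = init, update = update,
         conf_threshold = conf_threshold,
         name = "ncc"),
    class = "tracker_backend"
  )
}

crop_centered <- function(frame, center, size) {
  half <- size / 2
  x0 <- round(center[1] - half) + 1
  y0 <- round(center[2] - half) + 1
  x0 <- max(1, min(x0, ncol(frame) - size + 1))
  y0 <- max(1, min(y0, nrow(frame) - size + 1))
  frame[y0:(y0 + size - 1), x0:(x0 + size - 1)]
}

# 1D parabolic interpolation of the correlation peak; clamped to +/- 0.5 px
parabolic_offset <- function(score, iy, ix, axis) {
  if (axis == "x") {
    if (ix <= 1 || ix >= ncol(score)) return(0)
    s <- score[iy, (ix - 1):(ix + 1)]
  } else {
    if (iy <= 1 || iy >= nrow(score)) return(0)
    s <- score[(iy - 1):(iy + 1), ix]
  }
  if (any(!is.finite(s))) return(0)
  denom <- s[1] - 2 * s[2] + s[3]
  if (abs(denom) < 1e-12) return(0)
  max(-0.5, min(0.5, 0.5 * (s[1] - s[3]) / denom))
}

#' Initialize eye-corner tracking from operator marks
#'
#' The operator marks the inner and outer eye corners on the first frame
#' (the marks need not be pixel-accurate: the corner is a textured region,
#' not a point feature). Two boxes are derived: a small corner box (default
#' 32 x 32 px) centered on the inner-corner mark, and an eye-region box
#' spanning the two corners with a fixed width:height ratio (default 4:3)
#' plus a margin, inside which pupil segmentation is performed.
#'
#' @param frame First grayscale frame.
#' @param inner,outer Operator marks `(x, y)`, pixels; must be inside the
#'   frame and distinct.
#' @param backend A tracker backend (default [ncc_tracker()]).
#' @param box_size Corner-box side, pixels.
#' @param aspect Eye-region width:height ratio.
#' @param margin Fractional widening of the eye-region box beyond the
#'   corner-to-corner span.
#' @param inner_side Expected side of the inner corner relative to the outer
#'   (`"right"` for the left eye in this camera setup); `swap` controls what
#'   happens when the marks violate it.
#' @param swap `"error"` rejects swapped marks; `"auto"` swaps them.
#' @return An object of class `corner_track` with fields `corner` (`(m, n)`),
#'   `corner_box`, `eye_region` ([px_rect()]s), `lost`, `confidence`.
#' @export
init_corner_tracker <- function(frame, inner, outer,
                                backend = ncc_tracker(),
                                box_size = 32, aspect = 4 / 3,
                                margin = 0.3,
                                inner_side = c("right", "left"),
                                swap = c("error", "auto")) {
  inner_side <- match.arg(inner_side)
  swap <- match.arg(swap)
  h <- nrow(frame); w <- ncol(frame)
  inner <- as.numeric(inner); outer <- as.numeric(outer)
  if (any(inner < 1) || inner[1] > w || inner[2] > h ||
      any(outer < 1) || outer[1] > w || outer[2] > h) {
    rlang::abort("Corner marks must lie inside the frame.")
  }
  if (sqrt(sum((inner - outer)^2)) < 1e-6) {
    rlang::abort("Inner and outer corner marks coincide.")
  }
  wrong_order <- (inner_side == "right" && inner[1] < outer[1]) ||
    (inner_side == "left" && inner[1] > outer[1])
  if (wrong_order) {
    if (swap == "error") {
      rlang::abort(
        "Corner marks appear swapped (inner/outer on the wrong sides); pass swap = \"auto\" to accept either order."
      )
    }
    tmp <- inner; inner <- outer; outer <- tmp
  }

  state <- backend$init(frame, inner)
  track <- structure(
    list(
      corner = c(m = inner[1], n = inner[2]),
      outer = outer,
      corner_box = centered_box(inner, box_size, w, h),
      eye_region = eye_region_box(inner, outer, aspect, margin, w, h),
      box_size = box_size, aspect = aspect, margin = margin,
      backend = backend, state = state,
      lost = FALSE, confidence = 1,
      ref = c(m = inner[1], n = inner[2])
    ),
    class = "corner_track"
  )
  track
}

centered_box <- function(center, size, w, h) {
  x0 <- round(center[1] - size / 2)
  y0 <- round(center[2] - size / 2)
  x0 <- max(1, min(x0, w - size + 1))
  y0 <- max(1, min(y0, h - size + 1))
  px_rect(x0, y0, x0 + size, y0 + size)
}

# spans inner -> outer horizontally widened by `margin`, fixed aspect
eye_region_box <- function(inner, outer, aspect, margin, w, h) {
  span <- abs(inner[1] - outer[1])
  bw <- span * (1 + margin)
  bh <- bw / aspect
  cx <- (inner[1] + outer[1]) / 2
  cy <- (inner[2] + outer[2]) / 2
  x0 <- max(1, round(cx - bw / 2)); x1 <- min(w + 1, round(cx + bw / 2))
  y0 <- max(1, round(cy - bh / 2)); y1 <- min(h + 1, round(cy + bh / 2))
  px_rect(x0, y0, x1, y1)
}

#' Track the eye corner into the next frame
#'
#' Runs the tracker backend around the last known corner position. When the
#' backend's confidence falls below its threshold (occlusion, blink over the
#' corner), the track is flagged `lost` and the last position is held; the
#' tracker keeps looking from that position, so it recovers when the
#' landmark reappears. Both the corner box and the eye-region box follow the
#' tracked corner.
#'
#' @param track A `corner_track` from [init_corner_tracker()].
#' @param frame Next grayscale frame.
#' @return The updated `corner_track`.
#' @export
update_corner_tracker <- function(track, frame) {
  stopifnot(inherits(track, "corner_track"))
  res <- track$backend$update(track$state, frame)
  conf <- res$confidence
  if (!is.finite(conf) || conf < track$backend$conf_threshold) {
    track$lost <- TRUE
    track$confidence <- conf
    # hold position; reset backend center so the search stays anchored
    track$state$center <- unname(track$corner)
    return(track)
  }
  delta <- res$center - unname(track$corner)
  track$state <- res$state
  track$corner <- c(m = res$center[1], n = res$center[2])
  track$outer <- track$outer + delta
  w <- ncol(frame); h <- nrow(frame)
  track$corner_box <- centered_box(res$center, track$box_size, w, h)
  track$eye_region <- eye_region_box(res$center, track$outer, track$aspect,
                                     track$margin, w, h)
  track$lost <- FALSE
  track$confidence <- conf
  track
}

#' @export
print.corner_track <- function(x, ...) {
  cat(sprintf(
    "<corner_track> corner (%.1f, %.1f), %s (conf %.2f), backend %s\n",
    x$corner[1], x$corner[2],
    if (x$lost) "LOST" else "locked", x$confidence, x$backend$name
  ))
  invisible(x)
}
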