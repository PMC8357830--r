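#' Half-open integer pixel rectangle
#'
#' Rectangles select the pixel columns `xmin:(xmax-1)` and rows
#' `ymin:(ymax-1)` (half-open on the right/bottom), in the package's image
#' convention (origin top-left, x rightward, y downward, 1-based).
#'
#' @param xmin,ymin,xmax,ymax Integer bounds.
#' @return A list of class `px_rect`.
#' @export
px_rect <- function(xmin, ymin, xmax, ymax) {
  xmin <- as.integer(round(xmin)); ymin <- as.integer(round(ymin))
  xmax <- as.integer(round(xmax)); ymax <- as.integer(round(ymax))
  if (xmax <= xmin || ymax <= ymin) {
    rlang::abort("Rectangle must have positive width and height.")
  }
  structure(list(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax),
            class = "px_rect")
}

#' @export
print.px_rect <- function(x, ...) {
  cat(sprintf("<px_rect> [%d, %d) x [%d, %d)  (%d x %d px)\n",
              x$xmin, x$xmax, x$ymin, x$ymax,
              x$xmax - x$xmin, x$ymax - x$ymin))
  invisible(x)
}

rect_inside <- function(rect, width, height) {
  rect$xmin >= 1 && rect$ymin >= 1 &&
    rect$xmax <= width + 1 && rect$ymax <= height + 1
}

rect_shift <- function(rect, dx, dy) {
  px_rect(rect$xmin + dx, rect$ymin + dy, rect$xmax + dx, rect$ymax + dy)
}

rect_crop <- function(img, rect) {
  img[rect$ymin:(rect$ymax - 1), rect$xmin:(rect$xmax - 1), drop = FALSE]
}

#' Pupil segmentation settings
#'
#' @param area_bounds Accepted blob area range, pixels.
#' @param max_axis_ratio Maximum major/minor axis ratio of an accepted blob.
#' @param max_fill_mismatch Maximum relative mismatch between the blob area
#'   and the area of its moment-fitted ellipse; rejects non-elliptical blobs
#'   (eyelid bars, shadows).
#' @param max_mean_intensity Maximum mean intensity of an accepted blob; the
#'   pupil is genuinely dark, which distinguishes it from merely
#'   lower-contrast structures (corner texture, shadows) that an adaptive
#'   threshold can pick up when no pupil is visible.
#' @param dark_quantile Fallback threshold quantile when no histogram valley
#'   is found below the darkest mode.
#' @param brush_size Diameter of the disc structuring element used for the
#'   morphological closing that bridges specular-highlight holes.
#' @return A list of class `pupil_config`.
#' @export
pupil_config <- function(area_bounds = c(300, 30000),
                         max_axis_ratio = 3,
                         max_fill_mismatch = 0.3,
                         max_mean_intensity = 0.25,
                         dark_quantile = 0.05,
                         brush_size = 7) {
  structure(
    list(area_bounds = area_bounds, max_axis_ratio = max_axis_ratio,
         max_fill_mismatch = max_fill_mismatch,
         max_mean_intensity = max_mean_intensity,
         dark_quantile = dark_quantile, brush_size = brush_size),
    class = "pupil_config"
  )
}

#' Segment the pupil inside an eye-region box
#'
#' Pipeline: adaptive intensity thresholding (the histogram valley below the
#' darkest mode, falling back to a fixed low quantile), morphological closing
#' and opening to bridge highlight holes and remove speckle, connected-
#' component labelling, and a moment-based ellipse fit of each candidate
#' blob. Candidates are accepted if their area, axis ratio and ellipse-fill
#' consistency pass the configured bounds; the largest accepted blob wins.
#'
#' The operation never fails on a blink or occlusion: when no acceptable dark
#' elliptical blob exists it returns `valid = FALSE`.
#'
#' @param frame Grayscale image matrix (`height x width`, values in `[0, 1]`).
#' @param region A [px_rect()] eye-region box; must lie inside the frame.
#' @param config A [pupil_config()].
#' @return An object of class `pupil_detection`: `center` (`(px, py)`, full-
#'   frame pixel coordinates), `axes` (semi-axes, major first), `angle`
#'   (radians), `valid`, `area`.
#' @export
segment_pupil <- function(frame, region = NULL, config = pupil_config()) {
  h <- nrow(frame); w <- ncol(frame)
  if (is.null(region)) region <- px_rect(1, 1, w + 1, h + 1)
  if (!rect_inside(region, w, h)) {
    rlang::abort("Eye-region box extends outside the frame.")
  }
  crop <- rect_crop(frame, region)

  thr <- dark_threshold(crop, config$dark_quantile)
  mask <- crop < thr
  if (!any(mask)) return(invalid_pupil())

  mask1 <- mask * 1
  brush <- EBImage::makeBrush(config$brush_size, shape = "disc")
  mask1 <- EBImage::closing(mask1, brush)
  mask1 <- EBImage::opening(mask1, EBImage::makeBrush(3, shape = "box"))
  labels <- EBImage::bwlabel(mask1)
  n_comp <- max(labels)
  if (n_comp == 0) return(invalid_pupil())

  best <- NULL
  for (k in seq_len(n_comp)) {
    idx <- which(labels == k)
    area <- length(idx)
    if (area < config$area_bounds[1] || area > config$area_bounds[2]) next
    ys <- (idx - 1) %% nrow(labels) + 1
    xs <- (idx - 1) %/% nrow(labels) + 1
    if (mean(crop[cbind(ys, xs)]) > config$max_mean_intensity) next
    fit <- ellipse_from_moments(xs, ys)
    if (fit$axes[1] / fit$axes[2] > config$max_axis_ratio) next
    ell_area <- pi * fit$axes[1] * fit$axes[2]
    if (abs(ell_area - area) / area > config$max_fill_mismatch) next
    if (is.null(best) || area > best$area) {
      best <- c(fit, list(area = area))
    }
  }
  if (is.null(best)) return(invalid_pupil())

  structure(
    list(
      center = c(px = best$center[1] + region$xmin - 1,
                 py = best$center[2] + region$ymin - 1),
      axes = best$axes,
      angle = best$angle,
      valid = TRUE,
      area = best$area
    ),
    class = "pupil_detection"
  )
}

invalid_pupil <- function() {
  structure(
    list(center = c(px = NA_real_, py = NA_real_),
         axes = c(NA_real_, NA_real_), angle = NA_real_,
         valid = FALSE, area = 0L),
    class = "pupil_detection"
  )
}

#' @export
print.pupil_detection <- function(x, ...) {
  if (x$valid) {
    cat(sprintf(
      "<pupil_detection> center (%.1f, %.1f), semi-axes (%.1f, %.1f), angle %.2f rad\n",
      x$center[1], x$center[2], x$axes[1], x$axes[2], x$angle
    ))
  } else {
    cat("<pupil_detection> invalid (no acceptable pupil blob)\n")
  }
  invisible(x)
}

# Histogram-valley threshold: first local minimum after the darkest mode of a
# smoothed 64-bin histogram; falls back to a low quantile when the histogram
# is unimodal (e.g. a blink frame with no dark pupil pixels).
dark_threshold <- function(v, fallback_quantile) {
  v <- as.numeric(v)
  br <- seq(0, 1, length.out = 65)
  counts <- graphics::hist(pmin(pmax(v, 0), 1), breaks = br, plot = FALSE)$counts
  sm <- stats::filter(counts, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- 0
  sm <- as.numeric(sm)
  nb <- length(sm)
  mode1 <- NA_integer_
  for (i in 2:(nb - 1)) {
    if (sm[i] > 0 && sm[i] >= sm[i - 1] && sm[i] >= sm[i + 1]) {
      mode1 <- i; break
    }
  }
  if (!is.na(mode1)) {
    for (i in (mode1 + 1):(nb - 1)) {
      if (sm[i] <= sm[i - 1] && sm[i] <= sm[i + 1] && sm[i] < 0.5 * sm[mode1]) {
        return(br[i + 1])
      }
    }
  }
  stats::quantile(v, fallback_quantile, names = FALSE)
}

# Moment-based ellipse fit of a pixel blob: centroid + second central
# moments; for a solid ellipse the semi-axes are 2 * sqrt(eigenvalues).
ellipse_from_moments <- function(xs, ys) {
  cx <- mean(xs); cy <- mean(ys)
  dx <- xs - cx; dy <- ys - cy
  # + 1/12: variance of the uniform distribution over one pixel
  cxx <- mean(dx^2) + 1 / 12
  cyy <- mean(dy^2) + 1 / 12
  cxy <- mean(dx * dy)
  e <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
  axes <- 2 * sqrt(pmax(e$values, 1e-12))
  angle <- atan2(e$vectors[2, 1], e$vectors[1, 1])
  list(center = c(cx, cy), axes = axes, angle = angle)
}
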