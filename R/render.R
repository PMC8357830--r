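#' Rendering configuration for synthetic eye-camera frames
#'
#' Frames are grayscale matrices (`height x width`, values in `[0, 1]`) with
#' the image convention used throughout the package: origin at the top-left,
#' `x` rightward (columns), `y` downward (rows), pixel centers at integer
#' coordinates starting from 1.
#'
#' @param width,height Frame size in pixels (default 640 x 480).
#' @param pupil_axes Pupil ellipse semi-axes `(a, b)`, pixels.
#' @param pupil_angle Pupil ellipse rotation, radians.
#' @param iris_radius Iris disc radius, pixels.
#' @param sclera,iris,pupil,skin Base intensities of each region.
#' @param corner_size Side of the square textured corner landmark, pixels.
#' @param outer_offset Outer-corner position relative to the inner corner,
#'   pixels.
#' @param noise_sd Additive Gaussian pixel noise standard deviation.
#' @param distractors Optional bright-disc distractors: a data frame with
#'   columns `x`, `y`, `r` (absolute pixel positions and radii), or `NULL`.
#' @param texture_seed Seed for the deterministic corner-landmark texture.
#' @return A list of class `eye_render_config`.
#' @export
render_config <- function(width = 640, height = 480,
                          pupil_axes = c(40, 30), pupil_angle = 0,
                          iris_radius = 85,
                          sclera = 0.78, iris = 0.45, pupil = 0.07,
                          skin = 0.72,
                          corner_size = 24,
                          outer_offset = c(-150, -5),
                          noise_sd = 0.02,
                          distractors = NULL,
                          texture_seed = 42) {
  if (any(pupil_axes <= 0)) {
    rlang::abort("Pupil ellipse semi-axes must be positive.")
  }
  cfg <- list(
    width = width, height = height,
    pupil_axes = pupil_axes, pupil_angle = pupil_angle,
    iris_radius = iris_radius,
    sclera = sclera, iris = iris, pupil = pupil, skin = skin,
    corner_size = corner_size, outer_offset = outer_offset,
    noise_sd = noise_sd, distractors = distractors,
    texture_seed = texture_seed
  )
  cfg$corner_texture <- corner_texture(corner_size, texture_seed)
  class(cfg) <- "eye_render_config"
  cfg
}

# Deterministic high-gradient landmark texture: a corner-like wedge over
# band-limited noise, so correlation trackers have structure to lock onto.
corner_texture <- function(size, seed) {
  withr::with_seed(seed, {
    u <- matrix(stats::runif(size * size), size, size)
  })
  u <- box_blur(u, 2)
  i <- row(u) - (size + 1) / 2
  j <- col(u) - (size + 1) / 2
  wedge <- 0.35 * exp(-((i - j)^2) / (0.18 * size^2)) +
    0.25 * exp(-(i^2 + j^2) / (0.08 * size^2))
  tex <- 0.35 + 0.45 * (u - min(u)) / (max(u) - min(u)) - wedge
  # keep the landmark clearly lighter than the pupil so segmentation never
  # mistakes it for a dark blob; contrast, not darkness, is what NCC needs
  pmin(pmax(tex, 0.3), 1)
}

box_blur <- function(m, r) {
  k <- rep(1, 2 * r + 1) / (2 * r + 1)
  m <- t(apply(m, 1, function(v) stats::filter(v, k, circular = TRUE)))
  apply(m, 2, function(v) stats::filter(v, k, circular = TRUE))
}

#' Render one synthetic eye-camera frame
#'
#' Draws a dark elliptical pupil over an iris disc and sclera background,
#' textured inner and outer corner landmarks at the pose-shifted corner
#' position, optional bright-disc distractors, and additive Gaussian noise.
#' During a blink the eyelid (skin) occludes the eye region and the pupil is
#' not drawn.
#'
#' The frame is driven by one feature-level record, as produced by
#' [generate_gaze_session()]: the inner corner is drawn at `(m, n)` and the
#' pupil center at `(m + x, n + y)`. The returned ground truth always equals
#' the parameters actually used to draw.
#'
#' @param features A one-row data frame (or named list) with fields `x`, `y`,
#'   `m`, `n` and optionally `blink`.
#' @param config An [render_config()].
#' @return A list of class `eye_frame`: `image` (matrix `height x width`),
#'   and `truth` with `pupil` (`(px, py)` or `NULL` when blinking),
#'   `corner_inner`, `corner_outer`, `blink`.
#' @examples
#' fr <- render_eye_frame(list(x = -70, y = -45, m = 400, n = 300),
#'                        render_config(noise_sd = 0))
#' fr$truth$pupil
#' @export
render_eye_frame <- function(features, config = render_config()) {
  f <- as.list(features)
  blink <- isTRUE(as.logical(f$blink %||% FALSE))
  m <- as.numeric(f$m); n <- as.numeric(f$n)
  corner_inner <- c(m, n)
  corner_outer <- corner_inner + config$outer_offset
  w <- config$width; h <- config$height
  a <- config$pupil_axes[1]; b <- config$pupil_axes[2]

  px <- py <- NULL
  if (!blink) {
    px <- m + as.numeric(f$x); py <- n + as.numeric(f$y)
    if (is.na(px) || is.na(py)) {
      rlang::abort("Non-blink frame requires finite pupil features.")
    }
    if (px - a < 1 || px + a > w || py - b < 1 || py + b > h) {
      rlang::abort("Pupil ellipse must lie fully inside the frame unless blinking.")
    }
  }

  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), times = w), h, w)
  img <- matrix(config$sclera, h, w)
  img <- img - 0.03 * (Y / h)  # mild vertical shading

  if (!blink) {
    # iris disc with a 2 px soft edge
    r_iris <- sqrt((X - px)^2 + (Y - py)^2)
    wi <- pmin(pmax((config$iris_radius - r_iris) / 2 + 0.5, 0), 1)
    img <- img * (1 - wi) + config$iris * wi
    # pupil ellipse, soft edge ~1 px
    ca <- cos(config$pupil_angle); sa <- sin(config$pupil_angle)
    u <- ((X - px) * ca + (Y - py) * sa) / a
    v <- (-(X - px) * sa + (Y - py) * ca) / b
    q <- sqrt(u^2 + v^2)
    edge <- 1 / min(a, b)
    wp <- pmin(pmax((1 - q) / edge + 0.5, 0), 1)
    img <- img * (1 - wp) + config$pupil * wp
  } else {
    # eyelid: skin fills the frame down past the eye midline
    lid_y <- n + 20
    wlid <- pmin(pmax((lid_y - Y) / 3 + 0.5, 0), 1)
    lid_tex <- config$skin + 0.02 * sin(X / 17) * cos(Y / 23)
    img <- img * (1 - wlid) + lid_tex * wlid
  }

  img <- stamp_patch(img, config$corner_texture, corner_inner)
  img <- stamp_patch(img, config$corner_texture, corner_outer)

  if (!is.null(config$distractors) && !blink) {
    for (k in seq_len(nrow(config$distractors))) {
      d <- config$distractors[k, ]
      rd <- sqrt((X - d$x)^2 + (Y - d$y)^2)
      wd <- pmin(pmax((d$r - rd) / 1.5 + 0.5, 0), 1)
      img <- img * (1 - wd) + 0.97 * wd
    }
  }

  if (config$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(h * w, 0, config$noise_sd), h, w)
  }
  img <- pmin(pmax(img, 0), 1)

  structure(
    list(
      image = img,
      truth = list(
        pupil = if (blink) NULL else c(px = px, py = py),
        corner_inner = c(m = corner_inner[1], n = corner_inner[2]),
        corner_outer = c(m = corner_outer[1], n = corner_outer[2]),
        blink = blink
      )
    ),
    class = "eye_frame"
  )
}

# Alpha-blend a small texture patch centered at (possibly subpixel) `center`
# into `img`; bilinear resampling keeps the stamped position exact.
stamp_patch <- function(img, patch, center) {
  h <- nrow(img); w <- ncol(img)
  ps <- nrow(patch)
  half <- (ps - 1) / 2
  cx <- center[1]; cy <- center[2]
  x0 <- floor(cx - half); y0 <- floor(cy - half)
  fx <- cx - half - x0; fy <- cy - half - y0
  # bilinear shift of the patch by (fx, fy)
  pad <- matrix(mean(patch), ps + 1, ps + 1)
  pad[1:ps, 1:ps] <- patch
  p00 <- pad[1:ps, 1:ps]; p10 <- pad[2:(ps + 1), 1:ps]
  p01 <- pad[1:ps, 2:(ps + 1)]; p11 <- pad[2:(ps + 1), 2:(ps + 1)]
  shifted <- (1 - fy) * ((1 - fx) * p00 + fx * p01) +
    fy * ((1 - fx) * p10 + fx * p11)
  rows <- y0:(y0 + ps - 1); cols <- x0:(x0 + ps - 1)
  rok <- rows >= 1 & rows <= h; cok <- cols >= 1 & cols <= w
  if (!any(rok) || !any(cok)) return(img)
  img[rows[rok], cols[cok]] <- shifted[rok, cok]
  img
}

#' Generate a synthetic table-camera video with known translation
#'
#' Produces `n_frames` grayscale frames in which the textured region inside
#' (or outside) the mask translates by a fixed per-frame shift, with exact
#' sub-pixel (bilinear, periodic) interpolation. Ground-truth motion is
#' recorded per frame, giving the table-motion estimator a known answer.
#'
#' @param shift Per-frame translation `(dx, dy)`, pixels; must satisfy
#'   `|shift| < 10` per frame.
#' @param n_frames Number of frames.
#' @param width,height Frame size, pixels.
#' @param mask Logical matrix (`height x width`) marking the moving (table)
#'   region; default is a centered rectangle covering ~60% of the frame.
#' @param moving Which side of the mask moves: `"inside"` (default) or
#'   `"outside"` (used to verify the mask contract).
#' @param seed Texture seed.
#' @return A list of class `table_video`: `frames` (list of matrices),
#'   `mask`, `truth` (tibble `frame`, `dx`, `dy` — per-frame shift of the
#'   moving texture).
#' @export
generate_table_video <- function(shift = c(3, 0), n_frames = 30,
                                 width = 160, height = 120,
                                 mask = NULL, moving = c("inside", "outside"),
                                 seed = 1) {
  moving <- match.arg(moving)
  if (sqrt(sum(shift^2)) >= 10) {
    rlang::abort("Per-frame |shift| must be below 10 px.")
  }
  if (is.null(mask)) {
    mask <- matrix(FALSE, height, width)
    mask[round(height * 0.2):round(height * 0.8),
         round(width * 0.2):round(width * 0.8)] <- TRUE
  }
  stopifnot(nrow(mask) == height, ncol(mask) == width)
  if (!any(mask)) rlang::abort("Mask is empty; nothing to track.")

  tex <- withr::with_seed(seed, {
    matrix(stats::runif(height * width), height, width)
  })
  tex <- box_blur(box_blur(tex, 3), 3)
  tex <- (tex - min(tex)) / (max(tex) - min(tex))
  bg <- withr::with_seed(seed + 1L, {
    matrix(stats::runif(height * width), height, width)
  })
  bg <- box_blur(bg, 5)
  bg <- 0.3 + 0.4 * (bg - min(bg)) / (max(bg) - min(bg))

  frames <- purrr::map(seq_len(n_frames), function(k) {
    total <- (k - 1) * shift
    moved <- translate_periodic(tex, total[1], total[2])
    if (moving == "inside") {
      out <- bg
      out[mask] <- moved[mask]
    } else {
      out <- moved
      out[mask] <- bg[mask]
    }
    out
  })
  structure(
    list(
      frames = frames, mask = mask, shift = shift, moving = moving,
      truth = tibble::tibble(
        frame = seq_len(n_frames),
        dx = c(0, rep(shift[1], n_frames - 1)),
        dy = c(0, rep(shift[2], n_frames - 1))
      )
    ),
    class = "table_video"
  )
}

# Periodic bilinear translation: output(x, y) = input(x - dx, y - dy)
translate_periodic <- function(img, dx, dy) {
  h <- nrow(img); w <- ncol(img)
  xs <- ((seq_len(w) - 1 - dx) %% w)
  ys <- ((seq_len(h) - 1 - dy) %% h)
  x0 <- floor(xs); fx <- xs - x0
  y0 <- floor(ys); fy <- ys - y0
  x0 <- x0 %% w; x1 <- (x0 + 1) %% w
  y0 <- y0 %% h; y1 <- (y0 + 1) %% h
  A <- img[y0 + 1, x0 + 1, drop = FALSE]
  B <- img[y0 + 1, x1 + 1, drop = FALSE]
  C <- img[y1 + 1, x0 + 1, drop = FALSE]
  D <- img[y1 + 1, x1 + 1, drop = FALSE]
  FX <- matrix(rep(fx, each = h), h, w)
  FY <- matrix(rep(fy, times = w), h, w)
  (1 - FY) * ((1 - FX) * A + FX * B) + FY * ((1 - FX) * C + FX * D)
}
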