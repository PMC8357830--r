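#' Dense optical flow between two grayscale frames
#'
#' Coarse-to-fine iterative Lucas-Kanade dense flow: an image pyramid is
#' built by 2x2 mean pooling; at each level the current flow estimate warps
#' the second frame onto the first and a Gaussian-windowed least-squares
#' update is solved per pixel from the spatio-temporal image gradients.
#' This resolves translations of several pixels per frame, which covers the
#' patient-table speeds of interest.
#'
#' @param prev,cur Grayscale matrices of identical size, values in `[0, 1]`.
#' @param levels Pyramid levels (default 3).
#' @param iters Warp-and-update iterations per level.
#' @param sigma Gaussian window standard deviation, pixels.
#' @return A list with matrices `u` (x-flow) and `v` (y-flow), in pixels per
#'   frame, and `reliable` (logical: the local normal matrix was well
#'   conditioned). Sign convention follows the image axes: positive `u` is
#'   motion to the right, positive `v` downward.
#' @export
optical_flow_dense <- function(prev, cur, levels = 3, iters = 3, sigma = 3) {
  if (!all(dim(prev) == dim(cur))) {
    rlang::abort("Frames must have the same shape.")
  }
  pyr_prev <- build_pyramid(prev, levels)
  pyr_cur <- build_pyramid(cur, levels)
  u <- v <- NULL
  for (lv in rev(seq_len(length(pyr_prev)))) {
    P <- pyr_prev[[lv]]; C <- pyr_cur[[lv]]
    h <- nrow(P); w <- ncol(P)
    if (is.null(u)) {
      u <- matrix(0, h, w); v <- matrix(0, h, w)
    } else {
      u <- 2 * upsample_to(u, h, w)
      v <- 2 * upsample_to(v, h, w)
    }
    for (it in seq_len(iters)) {
      Cw <- warp_bilinear(C, u, v)
      Ix <- grad_x((P + Cw) / 2)
      Iy <- grad_y((P + Cw) / 2)
      It <- Cw - P
      Ixx <- gaussian_blur(Ix * Ix, sigma)
      Iyy <- gaussian_blur(Iy * Iy, sigma)
      Ixy <- gaussian_blur(Ix * Iy, sigma)
      Ixt <- gaussian_blur(Ix * It, sigma)
      Iyt <- gaussian_blur(Iy * It, sigma)
      det <- Ixx * Iyy - Ixy^2
      ok <- det > 1e-9
      du <- dv <- matrix(0, h, w)
      du[ok] <- (-Iyy[ok] * Ixt[ok] + Ixy[ok] * Iyt[ok]) / det[ok]
      dv[ok] <- (Ixy[ok] * Ixt[ok] - Ixx[ok] * Iyt[ok]) / det[ok]
      # clamp the per-iteration update for stability
      du <- pmin(pmax(du, -2), 2)
      dv <- pmin(pmax(dv, -2), 2)
      u <- u + du
      v <- v + dv
    }
  }
  det_full <- {
    Ix <- grad_x(prev); Iy <- grad_y(prev)
    Ixx <- gaussian_blur(Ix * Ix, sigma)
    Iyy <- gaussian_blur(Iy * Iy, sigma)
    Ixy <- gaussian_blur(Ix * Iy, sigma)
    Ixx * Iyy - Ixy^2
  }
  list(u = u, v = v, reliable = det_full > 1e-8)
}

build_pyramid <- function(img, levels) {
  out <- list(img)
  for (lv in seq_len(levels - 1)) {
    prev <- out[[lv]]
    if (min(dim(prev)) < 16) break
    out[[lv + 1]] <- downsample2(prev)
  }
  out
}

downsample2 <- function(img) {
  h <- 2 * (nrow(img) %/% 2); w <- 2 * (ncol(img) %/% 2)
  img <- img[1:h, 1:w]
  (img[seq(1, h, 2), seq(1, w, 2)] + img[seq(2, h, 2), seq(1, w, 2)] +
     img[seq(1, h, 2), seq(2, w, 2)] + img[seq(2, h, 2), seq(2, w, 2)]) / 4
}

upsample_to <- function(m, h, w) {
  ri <- pmin(nrow(m), pmax(1, ceiling(seq_len(h) / (h / nrow(m)))))
  ci <- pmin(ncol(m), pmax(1, ceiling(seq_len(w) / (w / ncol(m)))))
  m[ri, ci, drop = FALSE]
}

grad_x <- function(img) {
  w <- ncol(img)
  (img[, c(2:w, w)] - img[, c(1, 1:(w - 1))]) / 2
}

grad_y <- function(img) {
  h <- nrow(img)
  (img[c(2:h, h), ] - img[c(1, 1:(h - 1)), ]) / 2
}

# separable Gaussian blur via band-matrix multiplication (clamped borders)
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1, ceiling(2.5 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_1d(t(blur_1d(t(img), k)), k)
}

blur_1d <- function(img, k) {
  # convolve each column of img with kernel k, clamping at the borders
  h <- nrow(img)
  r <- (length(k) - 1) / 2
  idx <- outer(seq_len(h), -r:r, `+`)
  idx <- pmin(pmax(idx, 1), h)
  out <- matrix(0, h, ncol(img))
  for (j in seq_along(k)) {
    out <- out + k[j] * img[idx[, j], , drop = FALSE]
  }
  out
}

# output(y, x) = img(y + v, x + u), bilinear, clamped
warp_bilinear <- function(img, u, v) {
  h <- nrow(img); w <- ncol(img)
  X <- matrix(rep(seq_len(w), each = h), h, w) + u
  Y <- matrix(rep(seq_len(h), times = w), h, w) + v
  X <- pmin(pmax(X, 1), w)
  Y <- pmin(pmax(Y, 1), h)
  x0 <- floor(X); y0 <- floor(Y)
  x0 <- pmin(x0, w - 1); y0 <- pmin(y0, h - 1)
  fx <- X - x0; fy <- Y - y0
  i00 <- (x0 - 1) * h + y0
  i01 <- x0 * h + y0
  i10 <- (x0 - 1) * h + y0 + 1
  i11 <- x0 * h + y0 + 1
  out <- (1 - fy) * ((1 - fx) * img[i00] + fx * img[i01]) +
    fy * ((1 - fx) * img[i10] + fx * img[i11])
  matrix(out, h, w)
}

#' Estimate table motion between two frames by masked-mean optical flow
#'
#' Computes dense optical flow and averages the flow vectors over the masked
#' (patient-table) region, yielding a single 2D motion direction and speed
#' in pixels per frame.
#'
#' @param prev,cur Consecutive grayscale frames (same shape).
#' @param mask Logical matrix marking the table region; must be non-empty
#'   and match the frame shape.
#' @param ... Passed to [optical_flow_dense()].
#' @return A one-row tibble of class `table_motion_estimate`: `u`, `v`
#'   (mean flow, px/frame), `speed`, `n_pixels` (pixels averaged).
#' @export
estimate_table_motion <- function(prev, cur, mask, ...) {
  if (!all(dim(prev) == dim(cur))) {
    rlang::abort("Frames must have the same shape.")
  }
  if (is.null(mask) || !any(mask)) {
    rlang::abort("Mask is empty; no table region to average over.")
  }
  if (!all(dim(mask) == dim(prev))) {
    rlang::abort("Mask shape must match the frames.")
  }
  fl <- optical_flow_dense(prev, cur, ...)
  use <- mask & fl$reliable
  if (!any(use)) use <- mask
  out <- tibble::tibble(
    u = mean(fl$u[use]), v = mean(fl$v[use]),
    speed = NA_real_, n_pixels = sum(use)
  )
  out$speed <- sqrt(out$u^2 + out$v^2)
  class(out) <- c("table_motion_estimate", class(out))
  out
}

#' Track table motion over a frame sequence
#'
#' Runs [estimate_table_motion()] over consecutive frame pairs and applies
#' exponential-moving-average smoothing to the raw per-frame vectors before
#' downstream use.
#'
#' @param frames List of grayscale matrices (or a [generate_table_video()]
#'   result, whose mask is then used by default).
#' @param mask Logical matrix table mask.
#' @param alpha EMA smoothing factor in `(0, 1]` (default 0.3; 1 = no
#'   smoothing).
#' @param ... Passed to [optical_flow_dense()].
#' @return A tibble with one row per frame transition: `frame`, `u_raw`,
#'   `v_raw`, `u`, `v` (smoothed), `speed`, `n_pixels`.
#' @export
track_table_motion <- function(frames, mask = NULL, alpha = 0.3, ...) {
  if (inherits(frames, "table_video")) {
    mask <- mask %||% frames$mask
    frames <- frames$frames
  }
  stopifnot(length(frames) >= 2, !is.null(mask))
  rows <- vector("list", length(frames) - 1)
  u_s <- v_s <- 0
  for (i in 2:length(frames)) {
    est <- estimate_table_motion(frames[[i - 1]], frames[[i]], mask, ...)
    if (i == 2) {
      u_s <- est$u; v_s <- est$v
    } else {
      u_s <- alpha * est$u + (1 - alpha) * u_s
      v_s <- alpha * est$v + (1 - alpha) * v_s
    }
    rows[[i - 1]] <- tibble::tibble(
      frame = i, u_raw = est$u, v_raw = est$v,
      u = u_s, v = v_s, speed = sqrt(u_s^2 + v_s^2),
      n_pixels = est$n_pixels
    )
  }
  dplyr::bind_rows(rows)
}

#' Read / write a binary mask as PNG
#'
#' @param mask Logical matrix.
#' @param path PNG path.
#' @return `read_mask_png()` returns a logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}
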