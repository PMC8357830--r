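#' Ground-truth forward map from gaze and head pose to eye features
#'
#' The synthetic-data generator needs a ground-truth mapping from a true gaze
#' point `g = (gx, gy)` (normalized screen units) and a head-pose offset
#' `(dm, dn)` (camera pixels) to a noise-free feature vector `(x, y, m, n)`.
#'
#' The default map models the pupil-corner displacement as proportional to
#' the tangent of the gaze eccentricity about the camera axis, with two
#' head-pose couplings:
#' \deqn{x = x_0 + G_x (1 + \kappa_m \Delta m + \kappa_n \Delta n)
#'       [\tan(2\theta (g_x - 0.5) + a_x) - \tan(a_x)] + \beta_x \Delta m}
#' and analogously for `y` about the vertical screen center, while the corner
#' simply shifts with pose: `m = m0 + dm`, `n = n0 + dn`. The parallax term
#' `beta * pose` reflects that the eyeball sits at a different depth than the
#' eye corner, so a head translation moves the pupil image by a different
#' amount than the corner and the pupil-corner vector picks up a
#' pose-proportional offset — this is what linear corner terms in the
#' regression basis compensate, to first order. The camera-axis angle `a`
#' reflects that the eye cameras view the eye obliquely (they sit below the
#' display mirror), which makes the leading geometric distortion even
#' (quadratic-like) rather than odd. The `kappa` gain perturbation couples
#' pose to the pupil response multiplicatively, and the off-axis tangent
#' makes the map mildly non-quadratic, so no candidate polynomial family
#' reproduces the map exactly — small models are biased, large models can
#' overfit, which is precisely the regime in which model selection is
#' interesting.
#'
#' @param corner Resting inner-corner position `(m0, n0)` in pixels.
#' @param pupil_offset Resting pupil-minus-corner offset `(x0, y0)` in pixels
#'   (gaze at screen center, neutral pose).
#' @param gain Pupil displacement gains `(Gx, Gy)` in pixels.
#' @param half_angle Half the horizontal gaze eccentricity range, radians;
#'   one screen width spans `2 * half_angle` of visual angle.
#' @param pose_gain Gain perturbation per pixel of pose offset
#'   `(kappa_m, kappa_n)`.
#' @param pose_offset Parallax coupling `(beta_x, beta_y)`: pixels of
#'   pupil-corner shift per pixel of pose offset.
#' @param camera_angle Camera-axis offset angles `(a_x, a_y)`, radians: the
#'   oblique viewing angle of the eye camera relative to straight-ahead gaze.
#' @param screen A [screen_geometry()].
#' @return A function of class `gaze_forward_map`: `f(g, pose)` taking a
#'   data frame / vector of gaze points and pose offsets and returning a
#'   tibble `(x, y, m, n)`.
#' @examples
#' fm <- eye_forward_map()
#' fm(c(0.5, 0.375), c(0, 0))  # screen center, neutral pose
#' @export
eye_forward_map <- function(corner = c(400, 300),
                            pupil_offset = c(-70, -45),
                            gain = c(170, 170),
                            half_angle = 0.08,
                            pose_gain = c(0.002, 0.002),
                            pose_offset = c(0.5, 0.5),
                            camera_angle = c(0.1, 0.18),
                            screen = screen_geometry()) {
  force(corner); force(pupil_offset); force(gain)
  force(half_angle); force(pose_gain); force(pose_offset)
  force(camera_angle); force(screen)
  f <- function(g, pose = c(0, 0)) {
    g <- as_xy_matrix(g, c("gx", "gy"))
    pose <- as_xy_matrix(pose, c("dm", "dn"))
    if (nrow(pose) == 1 && nrow(g) > 1) {
      pose <- pose[rep(1, nrow(g)), , drop = FALSE]
    }
    theta_x <- 2 * half_angle * (g[, 1] - 0.5)
    theta_y <- 2 * half_angle * (g[, 2] - screen$height / 2)
    gfac <- 1 + pose_gain[1] * pose[, 1] + pose_gain[2] * pose[, 2]
    tibble::tibble(
      x = pupil_offset[1] + gain[1] * gfac *
        (tan(theta_x + camera_angle[1]) - tan(camera_angle[1])) +
        pose_offset[1] * pose[, 1],
      y = pupil_offset[2] + gain[2] * gfac *
        (tan(theta_y + camera_angle[2]) - tan(camera_angle[2])) +
        pose_offset[2] * pose[, 2],
      m = corner[1] + pose[, 1],
      n = corner[2] + pose[, 2]
    )
  }
  class(f) <- c("gaze_forward_map", class(f))
  f
}

#' A linear forward map inside the polynomial model family
#'
#' Useful for exactness tests: features are an affine function of `(gx, gy)`
#' plus a pure corner shift, so an 8-term model (indeed any spec containing
#' `x`, `y`, `m`, `n`, `1`) inverts it exactly from well-conditioned noise-free
#' samples.
#'
#' @inheritParams eye_forward_map
#' @return A `gaze_forward_map` function.
#' @export
linear_forward_map <- function(corner = c(400, 300),
                               pupil_offset = c(-70, -45),
                               gain = c(80, 80),
                               screen = screen_geometry()) {
  force(corner); force(pupil_offset); force(gain); force(screen)
  f <- function(g, pose = c(0, 0)) {
    g <- as_xy_matrix(g, c("gx", "gy"))
    pose <- as_xy_matrix(pose, c("dm", "dn"))
    if (nrow(pose) == 1 && nrow(g) > 1) {
      pose <- pose[rep(1, nrow(g)), , drop = FALSE]
    }
    tibble::tibble(
      x = pupil_offset[1] + gain[1] * (g[, 1] - 0.5),
      y = pupil_offset[2] + gain[2] * (g[, 2] - screen$height / 2),
      m = corner[1] + pose[, 1],
      n = corner[2] + pose[, 2]
    )
  }
  class(f) <- c("gaze_forward_map", class(f))
  f
}

as_xy_matrix <- function(v, nms) {
  if (is.data.frame(v)) {
    m <- as.matrix(v[, nms])
  } else {
    m <- matrix(as.numeric(v), ncol = 2,
                byrow = !is.matrix(v))
    if (is.matrix(v)) m <- v
  }
  unname(m)
}
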