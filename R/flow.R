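#' Scene depth models
#'
#' Two scene geometries are supported.  A *frontoparallel* plane sits at a
#' fixed depth `d` (m) in front of the observer, so every image point has
#' the same depth.  A *ground* plane lies at signed eye-relative height `h`
#' (m, negative below the eye) while the observer's gaze is pitched by
#' `alpha` degrees relative to the horizon (negative = downward); its depth
#' profile along the image `y` axis is `Z(y) = h f / (y cos(alpha) +
#' f sin(alpha))`.
#'
#' Image points whose rays never intersect the ground plane (at or above
#' the horizon) are assigned infinite depth: they image infinitely distant
#' points, so their translational flow is zero while rotational flow is
#' unaffected.
#'
#' @param d Depth of the frontoparallel plane in m (> 0).
#' @param h Eye-relative height of the ground plane in m (default -10,
#'   i.e. 10 m below the observer).
#' @param alpha Gaze pitch relative to the horizon in degrees (default
#'   -30, i.e. 30 degrees below the horizon).
#' @return An object of class `"scene_depth"`.
#' @examples
#' frontoparallel_scene(4)
#' ground_scene()
#' @export
frontoparallel_scene <- function(d) {
  if (!is.finite(d) || d <= 0) stop("invalid scene: frontoparallel depth must be positive")
  structure(list(kind = "frontoparallel", d = d), class = "scene_depth")
}

#' @rdname frontoparallel_scene
#' @export
ground_scene <- function(h = -10, alpha = -30) {
  structure(list(kind = "ground", h = h, alpha = alpha), class = "scene_depth")
}

#' @export
print.scene_depth <- function(x, ...) {
  if (x$kind == "frontoparallel") {
    cat(sprintf("Frontoparallel plane at %g m\n", x$d))
  } else {
    cat(sprintf("Ground plane: h = %g m, gaze offset %g deg\n", x$h, x$alpha))
  }
  invisible(x)
}

#' Per-pixel scene depth
#'
#' Evaluates the depth `Z(x, y)` (m) of the world point imaged at each
#' camera grid point.  Frontoparallel scenes are constant; ground-plane
#' depth depends only on the image `y` coordinate.  Ground rays at or
#' above the horizon receive `Inf` (see [ground_scene()]).  A ray exactly
#' parallel to the ground plane (zero denominator) is rejected, as is a
#' ground scene with no valid intersection anywhere on the grid.
#'
#' @param scene A [`scene_depth`][frontoparallel_scene] object.
#' @param camera A [camera_model()].
#' @return Numeric vector of length `grid_size^2` of depths (m), ordered
#'   as the camera grid.
#' @examples
#' all(depth_map(frontoparallel_scene(4), camera_model()) == 4)
#' @export
depth_map <- function(scene, camera = camera_model()) {
  stopifnot(inherits(scene, "scene_depth"))
  np <- length(camera$x)
  if (scene$kind == "frontoparallel") {
    return(rep(scene$d, np))
  }
  f <- camera$focal_length
  a <- scene$alpha * pi / 180
  den <- camera$y * cos(a) + f * sin(a)
  if (any(den == 0)) {
    stop("invalid scene: a grid ray is parallel to the ground plane (division by zero)")
  }
  Z <- scene$h * f / den
  Z[Z <= 0] <- Inf          # ray does not hit the plane: sky
  if (all(is.infinite(Z))) stop("invalid scene: ground plane not visible anywhere on the grid")
  Z
}

#' Instantaneous optic flow of combined translation and rotation
#'
#' Evaluates the instantaneous image-plane motion field produced when the
#' observer translates with velocity `trans` (m/s) and rotates with
#' angular velocity `rot` (deg/s), both expressed in the camera frame
#' (`x` right, `y` up, `z` forward).  At image point `(x, y)` with scene
#' depth `Z`:
#'
#' \deqn{\dot x = \frac{-f T_x + x T_z}{Z} + \frac{xy R_x - (f^2+x^2) R_y + f y R_z}{f}}
#' \deqn{\dot y = \frac{-f T_y + y T_z}{Z} + \frac{(f^2+y^2) R_x - xy R_y - f x R_z}{f}}
#'
#' with the rotation rates converted to rad/s.  The translational term is
#' scaled by inverse depth; the rotational term is depth-independent, so
#' the full field is exactly the sum of the pure-translation and
#' pure-rotation fields.
#'
#' @param trans Length-3 translation velocity (m/s).
#' @param rot Length-3 rotation velocity (deg/s): pitch (about `x`), yaw
#'   (about `y`), roll (about `z`).
#' @param scene A scene object, or a precomputed depth vector from
#'   [depth_map()].
#' @param camera A [camera_model()].
#' @return An object of class `"flow_field"`: list with `u`, `v` (numeric
#'   vectors, image-plane velocities in cm/s at each grid point), `trans`,
#'   `rot`, and `camera`.
#' @examples
#' ff <- optic_flow(c(0, 0, 1), c(0, 0, 0), frontoparallel_scene(4))
#' # focus of expansion at the image centre:
#' centre <- which(camera_model()$x == 0 & camera_model()$y == 0)
#' c(ff$u[centre], ff$v[centre])  # (0, 0)
#' @export
optic_flow <- function(trans, rot, scene, camera = camera_model()) {
  stopifnot(length(trans) == 3, length(rot) == 3)
  Z <- if (inherits(scene, "scene_depth")) depth_map(scene, camera) else scene
  if (length(Z) != length(camera$x)) stop("depth map does not match the camera grid")
  if (any(!is.nan(Z) & Z <= 0)) stop("invalid scene: non-positive depth")
  x <- camera$x; y <- camera$y; f <- camera$focal_length
  Rr <- rot * pi / 180
  u <- (-f * trans[1] + x * trans[3]) / Z +
    (x * y * Rr[1] - (f^2 + x^2) * Rr[2] + f * y * Rr[3]) / f
  v <- (-f * trans[2] + y * trans[3]) / Z +
    ((f^2 + y^2) * Rr[1] - x * y * Rr[2] - f * x * Rr[3]) / f
  if (any(!is.finite(u)) || any(!is.finite(v))) stop("non-finite flow field")
  structure(list(u = u, v = v, trans = trans, rot = rot, camera = camera),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  spd <- sqrt(x$u^2 + x$v^2)
  cat(sprintf("Optic flow field (%d x %d): |T| = %.3g m/s, |R| = %.3g deg/s, peak image speed %.3g cm/s\n",
              x$camera$grid_size, x$camera$grid_size,
              sqrt(sum(x$trans^2)), sqrt(sum(x$rot^2)), max(spd)))
  invisible(x)
}

#' @export
plot.flow_field <- function(x, length = 0.05, ...) {
  g <- x$camera
  spd <- sqrt(x$u^2 + x$v^2)
  sc <- if (max(spd) > 0) 0.4 * (g$x[2] - g$x[1]) / max(spd) else 1
  graphics::plot(g$x, g$y, type = "n", asp = 1, xlab = "x (cm)", ylab = "y (cm)", ...)
  nz <- spd > 0
  graphics::arrows(g$x[nz], g$y[nz], g$x[nz] + sc * x$u[nz], g$y[nz] + sc * x$v[nz],
                   length = length)
  graphics::points(g$x[!nz], g$y[!nz], pch = 16, cex = 0.3)
  invisible(x)
}
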