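#' Pinhole camera model
#'
#' Describes the simulated observer's eye: a pinhole camera with focal
#' length `f` (cm) imaging a 90 degree field of view onto a square sampling
#' grid.  Image-plane coordinates `x` and `y` both span `[-f, f]` (cm), the
#' central portion of the image plane that falls inside the field of view;
#' flow is evaluated on an evenly spaced `grid_size` x `grid_size` lattice
#' of points in that square.
#'
#' The camera frame is right-handed with `+x` rightward, `+y` upward and
#' `+z` along the optical axis (the direction of gaze).
#'
#' @param focal_length Focal length in cm. Default 1.
#' @param fov Field of view in degrees. Default 90.
#' @param grid_size Number of sample points per image axis. Default 15.
#'
#' @return An object of class `"camera_model"`: a list with elements
#'   `focal_length`, `fov`, `grid_size`, and `x`, `y` — vectors of length
#'   `grid_size^2` giving the image-plane coordinates of every grid point
#'   (`x` varies fastest, i.e. points are stored row-major in `y`).
#' @examples
#' cam <- camera_model()
#' range(cam$x)  # [-1, 1]
#' @export
camera_model <- function(focal_length = 1, fov = 90, grid_size = 15) {
  stopifnot(focal_length > 0, grid_size >= 2)
  ax <- seq(-focal_length, focal_length, length.out = grid_size)
  g <- expand.grid(x = ax, y = ax, KEEP.OUT.ATTRS = FALSE)
  structure(
    list(focal_length = focal_length, fov = fov, grid_size = grid_size,
         x = g$x, y = g$y),
    class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("Pinhole camera: f = %g cm, %g deg FOV, %d x %d grid\n",
              x$focal_length, x$fov, x$grid_size, x$grid_size))
  invisible(x)
}

#' Convert direction angles to 3D Cartesian unit vectors, and back
#'
#' Directions of translation and of rotation axes are reported as an
#' (azimuth, elevation) pair using the convention of the primate MSTd
#' literature: azimuth 0 and 180 degrees correspond to leftward and
#' rightward translation, 90 degrees to forward, and elevation -90 and +90
#' degrees to upward and downward.  Azimuth is circular on
#' `[-180, 180)`; elevation spans `[-90, 90]`.
#'
#' In the camera frame (`+x` right, `+y` up, `+z` forward) the unit vector
#' is `(-cos(el) cos(az), -sin(el), cos(el) sin(az))`.
#'
#' @param azimuth,elevation Angles in degrees (vectors recycled to a
#'   common length).
#' @return `sph_to_cart()`: an `n x 3` matrix of unit vectors.
#' @examples
#' sph_to_cart(0, 0)        # leftward: (-1, 0, 0)
#' sph_to_cart(90, 0)       # forward:  (0, 0, 1)
#' cart_to_sph(rbind(c(0, -1, 0)))  # straight down: elevation 90
#' @export
sph_to_cart <- function(azimuth, elevation) {
  n <- max(length(azimuth), length(elevation))
  az <- rep_len(azimuth, n) * pi / 180
  el <- rep_len(elevation, n) * pi / 180
  cbind(-cos(el) * cos(az), -sin(el), cos(el) * sin(az))
}

#' @rdname sph_to_cart
#' @param v An `n x 3` matrix (or length-3 vector) of Cartesian directions;
#'   rows need not be normalized.
#' @return `cart_to_sph()`: an `n x 2` matrix with columns `azimuth` and
#'   `elevation` in degrees.  At the poles (|elevation| = 90) azimuth is
#'   reported as 0 by convention.
#' @export
cart_to_sph <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm == 0)) stop("cannot convert a zero vector to direction angles")
  u <- v / nrm
  el <- asin(pmin(1, pmax(-1, -u[, 2]))) * 180 / pi
  az <- atan2(u[, 3], -u[, 1]) * 180 / pi
  az[abs(el) >= 90 - 1e-12] <- 0
  az[az >= 180] <- az[az >= 180] - 360
  cbind(azimuth = az, elevation = el)
}

#' Wrap angles to the circular interval [-180, 180)
#'
#' @param x Angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(x) {
  ((x + 180) %% 360) - 180
}

#' Angle between two sets of 3D directions
#'
#' Great-circle (angular) separation between paired rows of two direction
#' matrices, in degrees.
#'
#' @param a,b `n x 3` matrices (rows need not be unit length).
#' @return Vector of angles in `[0, 180]` degrees.
#' @export
angle_between <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  ua <- a / sqrt(rowSums(a^2))
  ub <- b / sqrt(rowSums(b^2))
  d <- pmin(1, pmax(-1, rowSums(ua * ub)))
  acos(d) * 180 / pi
}
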