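#' Parameters of the speed- and direction-tuned model MT population
#'
#' The model MT stage contains one unit per combination of grid position
#' (15 x 15), preferred direction (8 values, equally spaced) and
#' preferred speed (5 values), i.e. 8 x 5 x 225 = 9,000 units.  Direction
#' tuning follows a von Mises curve with concentration `sigma_theta`
#' (dimensionless; the default 3 gives roughly a 90 degree full width at
#' half maximum, as in macaque MT).  Speed tuning is log-normal with
#' bandwidth `sigma_nu` and offset `s0` (deg/s), the median values
#' reported for macaque MT.
#'
#' @param sigma_theta Direction-tuning concentration. Default 3.
#' @param sigma_nu Speed-tuning bandwidth. Default 1.16.
#' @param s0 Speed offset preventing the log singularity at 0 (deg/s).
#'   Default 0.33.
#' @param pref_speeds Preferred speeds in deg/s.
#' @param n_directions Number of equally spaced preferred directions.
#' @return An object of class `"mt_params"`.
#' @export
mt_params <- function(sigma_theta = 3, sigma_nu = 1.16, s0 = 0.33,
                      pref_speeds = c(2, 4, 8, 16, 32), n_directions = 8) {
  stopifnot(sigma_theta > 0, sigma_nu > 0, s0 > 0, all(pref_speeds > 0),
            n_directions >= 1)
  structure(list(sigma_theta = sigma_theta, sigma_nu = sigma_nu, s0 = s0,
                 pref_speeds = pref_speeds,
                 pref_directions = seq(0, 360, length.out = n_directions + 1)[seq_len(n_directions)]),
            class = "mt_params")
}

#' @export
print.mt_params <- function(x, ...) {
  cat(sprintf("MT population: %d directions x %d speeds per grid point (sigma_theta = %g, sigma_nu = %g, s0 = %g)\n",
              length(x$pref_directions), length(x$pref_speeds),
              x$sigma_theta, x$sigma_nu, x$s0))
  invisible(x)
}

#' MT direction and speed tuning curves
#'
#' `direction_tuning()` is the von Mises direction response
#' `exp(sigma_theta (cos(theta - theta_pref) - 1))`: 1 at the preferred
#' direction, periodic in 360 degrees.  `speed_tuning()` is the
#' log-normal speed response
#' `exp(-log((nu + s0) / (nu_pref + s0))^2 / (2 sigma_nu^2))`: 1 at the
#' preferred speed and strictly positive everywhere.
#'
#' @param theta,theta_pref Flow and preferred direction (deg).
#' @param nu,nu_pref Flow and preferred speed (deg/s); `nu` must be
#'   non-negative.
#' @param params An [mt_params()] object supplying the tuning constants.
#' @return Numeric response values in `(0, 1]`.
#' @examples
#' direction_tuning(45, 45)           # 1
#' direction_tuning(225, 45)          # exp(-6)
#' speed_tuning(8, 8)                 # 1
#' @export
direction_tuning <- function(theta, theta_pref, params = mt_params()) {
  exp(params$sigma_theta * (cos((theta - theta_pref) * pi / 180) - 1))
}

#' @rdname direction_tuning
#' @export
speed_tuning <- function(nu, nu_pref, params = mt_params()) {
  if (any(nu < 0)) stop("flow speed must be non-negative")
  exp(-log((nu + params$s0) / (nu_pref + params$s0))^2 / (2 * params$sigma_nu^2))
}

#' Unit index table of the MT population
#'
#' Deterministic mapping between the column index of an activation matrix
#' and the (grid position, preferred direction, preferred speed) of the
#' unit.  Column order: speed fastest, then direction, then grid position
#' (camera grid order, `x` varying fastest).
#'
#' @param params An [mt_params()].
#' @param camera A [camera_model()].
#' @return A data frame with columns `unit`, `grid_index`, `x`, `y`,
#'   `pref_direction`, `pref_speed`.
#' @export
mt_unit_table <- function(params = mt_params(), camera = camera_model()) {
  np <- length(camera$x)
  nd <- length(params$pref_directions)
  ns <- length(params$pref_speeds)
  g <- expand.grid(speed = seq_len(ns), dir = seq_len(nd), pos = seq_len(np),
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(unit = seq_len(np * nd * ns),
             grid_index = g$pos,
             x = camera$x[g$pos], y = camera$y[g$pos],
             pref_direction = params$pref_directions[g$dir],
             pref_speed = params$pref_speeds[g$speed])
}

#' MT population activations for a flow dataset
#'
#' Transforms each optic-flow field into the activation of every model MT
#' unit: the product of the unit's direction and speed tuning evaluated
#' at the flow vector of its grid position.  Image-plane velocities
#' (cm/s) are converted to retinal deg/s with the small-angle factor
#' `(180 / pi) / f`; with `f` = 1 cm this is a fixed scalar.  At a
#' zero-flow pixel the flow direction is taken as 0 degrees and the
#' activation is governed by the speed term.
#'
#' @param dataset A [flow_dataset()], or a list with `u`, `v` matrices.
#' @param params An [mt_params()].
#' @param camera A [camera_model()]; taken from the dataset if present.
#' @return An `n x 9000` matrix of activations in `[0, 1]` (for the
#'   default population size), of class `"mt_activations"` with the unit
#'   mapping of [mt_unit_table()] attached as attribute `"units"`.
#' @export
mt_activations <- function(dataset, params = mt_params(), camera = NULL) {
  u <- dataset$u; v <- dataset$v
  if (is.null(camera)) camera <- if (!is.null(dataset$camera)) dataset$camera else camera_model()
  if (any(!is.finite(u)) || any(!is.finite(v))) stop("non-finite flow input")
  n <- nrow(u)
  np <- length(camera$x)
  dirs <- params$pref_directions
  spds <- params$pref_speeds
  nd <- length(dirs); ns <- length(spds)
  A <- matrix(0, n, np * nd * ns)
  deg_per_cm <- (180 / pi) / camera$focal_length
  dir_rad <- dirs * pi / 180
  for (p in seq_len(np)) {
    up <- u[, p]; vp <- v[, p]
    theta <- atan2(vp, up)                       # rad; 0 for zero flow
    nu <- deg_per_cm * sqrt(up^2 + vp^2)
    D <- exp(params$sigma_theta * (cos(outer(theta, dir_rad, "-")) - 1))
    S <- exp(-log(outer(nu + params$s0, spds + params$s0, "/"))^2 /
               (2 * params$sigma_nu^2))
    base <- (p - 1) * nd * ns
    for (di in seq_len(nd)) {
      cols <- base + (di - 1) * ns + seq_len(ns)
      A[, cols] <- D[, di] * S
    }
  }
  structure(A, class = c("mt_activations", class(A)),
            units = mt_unit_table(params, camera))
}

#' @export
print.mt_activations <- function(x, ...) {
  cat(sprintf("MT activations: %d samples x %d units (range %.3g - %.3g)\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}
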