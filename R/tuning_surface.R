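## Tuning-surface analyses: RF interpolation, tuning width, peak heading
## discriminability.  All operate on responses to the 514-direction test
## protocol (32 azimuths x 16 elevations + 2 poles).

## Build a rectangular response grid from 514-protocol responses:
## rows = elevations (-90, ladder, +90), cols = the 32 azimuths.
## Pole rows are constant (the pole stimulus response).
protocol_grid <- function(responses, directions) {
  az <- sort(unique(directions[, 1][abs(directions[, 2]) < 90]))
  el <- sort(unique(directions[, 2]))            # includes -90, +90
  G <- matrix(NA_real_, length(el), length(az))
  for (i in seq_len(nrow(directions))) {
    a <- directions[i, 1]; e <- directions[i, 2]
    ri <- match(e, el)
    if (abs(e) == 90) G[ri, ] <- responses[i] else G[ri, match(a, az)] <- responses[i]
  }
  if (anyNA(G)) stop("responses do not cover the full protocol grid")
  list(az = az, el = el, values = G)
}

## Bilinear interpolation on the protocol grid, periodic in azimuth.
## Exact at grid nodes.
interp_bilinear <- function(grid, az_out, el_out) {
  az <- grid$az; el <- grid$el; G <- grid$values
  na <- length(az)
  azp <- c(az, az[1] + 360)                      # periodic continuation
  Gp <- cbind(G, G[, 1])
  q <- wrap_angle(az_out)
  q[q < azp[1]] <- q[q < azp[1]] + 360
  ia <- findInterval(q, azp, rightmost.closed = TRUE)
  ia[ia < 1] <- 1; ia[ia > na] <- na
  ta <- (q - azp[ia]) / (azp[ia + 1] - azp[ia])
  e <- pmin(pmax(el_out, el[1]), el[length(el)])
  ie <- findInterval(e, el, rightmost.closed = TRUE)
  ie[ie >= length(el)] <- length(el) - 1
  te <- (e - el[ie]) / (el[ie + 1] - el[ie])
  v00 <- Gp[cbind(ie, ia)]; v01 <- Gp[cbind(ie, ia + 1)]
  v10 <- Gp[cbind(ie + 1, ia)]; v11 <- Gp[cbind(ie + 1, ia + 1)]
  (1 - te) * ((1 - ta) * v00 + ta * v01) + te * ((1 - ta) * v10 + ta * v11)
}

#' Interpolated receptive-field surface of a model unit
#'
#' Interpolates a unit's responses to the 514-direction test protocol
#' onto a regular azimuth-elevation mesh (default 33 azimuths x 17
#' elevations = 561 points, 11.25 degree steps).  Interpolation is
#' bilinear in (azimuth, elevation) with periodic continuation in
#' azimuth, and is exact at protocol nodes.  The returned object carries
#' `lambert_y = sin(elevation)`, the vertical coordinate of the Lambert
#' cylindrical equal-area projection used for plotting.
#'
#' @param responses Vector of 514 protocol responses for one unit, or an
#'   `n_stimuli x n_units` matrix (a mean surface across units is then
#'   available via `composite = TRUE`).
#' @param directions The protocol's `n x 2` (azimuth, elevation) matrix;
#'   defaults to the standard 514-direction protocol.
#' @param mesh_az,mesh_el Output mesh (degrees).
#' @param composite If `responses` is a matrix, return the mean surface
#'   across units instead of per-unit surfaces.
#' @return A list of class `"rf_surface"`: `azimuth`, `elevation`,
#'   `lambert_y`, and `values` (matrix `length(mesh_el) x
#'   length(mesh_az)`, or a 3-d array for multi-unit input).
#' @export
interpolate_rf <- function(responses, directions = protocol_directions(),
                           mesh_az = seq(0, 360, by = 11.25),
                           mesh_el = seq(-90, 90, by = 11.25),
                           composite = FALSE) {
  mesh <- expand.grid(az = mesh_az, el = mesh_el, KEEP.OUT.ATTRS = FALSE)
  if (is.matrix(responses) && ncol(responses) > 1) {
    vals <- apply(responses, 2, function(r) {
      g <- protocol_grid(r, directions)
      interp_bilinear(g, mesh$az, mesh$el)
    })
    if (composite) {
      v <- matrix(rowMeans(vals), length(mesh_el), length(mesh_az), byrow = TRUE)
    } else {
      v <- array(vals, c(length(mesh_az), length(mesh_el), ncol(responses)))
      v <- aperm(v, c(2, 1, 3))
    }
  } else {
    g <- protocol_grid(drop(responses), directions)
    v <- matrix(interp_bilinear(g, mesh$az, mesh$el),
                length(mesh_el), length(mesh_az), byrow = TRUE)
  }
  structure(list(azimuth = mesh_az, elevation = mesh_el,
                 lambert_y = sin(mesh_el * pi / 180), values = v),
            class = "rf_surface")
}

#' @export
plot.rf_surface <- function(x, col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                            ...) {
  v <- if (length(dim(x$values)) == 3) apply(x$values, c(1, 2), mean) else x$values
  graphics::image(x$azimuth, x$lambert_y, t(v), col = col,
                  xlab = "azimuth (deg)", ylab = "sin(elevation)", ...)
  invisible(x)
}

#' Tuning width at half maximum
#'
#' Interpolates a unit's protocol responses on a fine mesh (100 azimuths
#' x 50 elevations, 3.6 degree increments) and returns the Euclidean
#' distance, in (azimuth, elevation) degree coordinates with azimuth
#' differences wrapped, between the mesh point of maximum activation and
#' the nearest mesh point whose value falls to half the maximum or
#' below.  Ties are broken toward smaller azimuth, then smaller
#' elevation.
#'
#' @inheritParams interpolate_rf
#' @return A list: `width` (deg), `peak` (azimuth, elevation of the
#'   maximum), and `flagged` (`TRUE` when the response never falls below
#'   half maximum, in which case `width` is the maximal mesh extent).
#' @export
tuning_width <- function(responses, directions = protocol_directions()) {
  mesh_az <- seq(0, 360 - 3.6, by = 3.6)
  mesh_el <- seq(-88.2, 88.2, by = 3.6)
  g <- protocol_grid(drop(responses), directions)
  mesh <- expand.grid(az = mesh_az, el = mesh_el, KEEP.OUT.ATTRS = FALSE)
  v <- interp_bilinear(g, mesh$az, mesh$el)
  mx <- max(v)
  if (mx <= 0) stop("unit has no positive response on the protocol")
  ipk <- which(v == mx)[1]
  pk <- c(mesh$az[ipk], mesh$el[ipk])
  below <- v <= mx / 2
  daz <- abs(wrap_angle(mesh$az - pk[1]))
  del <- mesh$el - pk[2]
  dist <- sqrt(daz^2 + del^2)
  if (!any(below)) {
    return(list(width = max(dist), peak = pk, flagged = TRUE))
  }
  cand <- which(below)
  ord <- order(dist[cand], mesh$az[cand], mesh$el[cand])
  list(width = dist[cand[ord[1]]], peak = pk, flagged = FALSE)
}

#' In-plane heading protocol for discriminability analysis
#'
#' 24 pure-translation stimuli with headings equally spaced over
#' 0-360 degrees (15 degree steps) in the horizontal plane (elevation
#' 0).
#'
#' @param t_speed Translation speed (m/s).
#' @param depth Frontoparallel scene depth (m).
#' @param step Heading step (deg).
#' @param camera A [camera_model()].
#' @return A [flow_dataset()] named `"HeadingCircle"`; the heading of
#'   each stimulus is its `t_azimuth` label.
#' @export
make_heading_protocol <- function(t_speed = 1, depth = 4, step = 15,
                                  camera = camera_model()) {
  az <- seq(0, 360 - step, by = step)
  n <- length(az)
  Tm <- sph_to_cart(az, 0) * t_speed
  Rm <- matrix(0, n, 3)
  depth_list <- rep(list(rep(depth, length(camera$x))), n)
  fl <- flow_matrix(Tm, Rm, depth_list, camera)
  flow_dataset("HeadingCircle", fl$u, fl$v,
               cbind(wrap_angle(az), 0, Rm), camera = camera,
               meta = list(step = step, t_speed = t_speed, depth = depth,
                           headings = az))
}

#' Peak heading discriminability
#'
#' Fits a cubic spline to a unit's responses to the 24 equally spaced
#' in-plane headings, padding each end with 20 further steps obtained by
#' circular continuation (headings reaching -300 and +660 degrees), and
#' evaluates the spline's analytic first derivative on 1000 equally
#' spaced points of the central 0-360 degree interval.  The heading with
#' the largest absolute derivative — where the response changes fastest,
#' hence where nearby headings are best discriminated — is returned.
#'
#' @param responses Vector of responses to the headings of
#'   [make_heading_protocol()] (in protocol order).
#' @param headings The protocol headings (deg, ascending from 0).
#' @param pad_steps Padding steps on each side.
#' @param n_eval Evaluation points over 0-360.
#' @return List: `heading` (deg of peak |derivative|), `max_slope`, and
#'   `flagged` (`TRUE` for constant responses, where the derivative is
#'   zero everywhere).
#' @export
peak_discriminability <- function(responses, headings = seq(0, 345, by = 15),
                                  pad_steps = 20, n_eval = 1000) {
  r <- drop(responses)
  stopifnot(length(r) == length(headings))
  step <- diff(headings)[1]
  idx <- seq(-pad_steps, length(headings) - 1 + pad_steps)
  ang <- idx * step
  rpad <- r[(idx %% length(headings)) + 1]
  sp <- stats::splinefun(ang, rpad, method = "fmm")
  xs <- seq(0, 360, length.out = n_eval)
  d1 <- sp(xs, deriv = 1)
  if (max(abs(d1)) < 1e-12) {
    return(list(heading = NA_real_, max_slope = 0, flagged = TRUE))
  }
  i <- which.max(abs(d1))
  list(heading = xs[i], max_slope = abs(d1[i]), flagged = FALSE)
}

#' Per-unit tuning summary over the diagnostic protocols
#'
#' Convenience wrapper that computes, for every responsive unit of a
#' model population, the translation and rotation preferences
#' (population vector), HTI and RTI, the translation tuning width, and
#' the translation-rotation preference difference.
#'
#' @param resp_t,resp_r `514 x n_units` response matrices to the T and R
#'   test protocols.
#' @param directions Protocol direction table.
#' @return A data frame with one row per unit (unresponsive units have
#'   `NA` entries and `responsive = FALSE`).
#' @export
tuning_summary <- function(resp_t, resp_r, directions = protocol_directions()) {
  resp_mask <- exclude_unresponsive(resp_t)$responsive &
    exclude_unresponsive(resp_r)$responsive
  pt <- population_vector_preference(resp_t, directions)
  pr <- population_vector_preference(resp_r, directions)
  hti <- tuning_index(resp_t, directions)
  rti <- tuning_index(resp_r, directions)
  width <- rep(NA_real_, ncol(resp_t))
  for (j in which(resp_mask)) {
    width[j] <- tuning_width(resp_t[, j], directions)$width
  }
  data.frame(unit = seq_len(ncol(resp_t)),
             responsive = resp_mask,
             t_azimuth = pt$azimuth, t_elevation = pt$elevation,
             r_azimuth = pr$azimuth, r_elevation = pr$elevation,
             hti = hti, rti = rti,
             tuning_width = width,
             pref_difference = preference_difference(pt, pr))
}
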