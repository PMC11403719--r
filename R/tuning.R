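#' Exclude unresponsive units
#'
#' A unit is *unresponsive* to a stimulus set when it produces zero
#' activation to every stimulus (the "dying rectifier" phenomenon in
#' trained networks).  Unresponsive units are excluded from all tuning
#' analyses.
#'
#' @param responses `n_stimuli x n_units` activation matrix.
#' @return List with `responsive` (logical mask over units) and
#'   `fraction_unresponsive`.
#' @export
exclude_unresponsive <- function(responses) {
  mx <- apply(responses, 2, max)
  responsive <- mx > 0
  list(responsive = responsive,
       fraction_unresponsive = mean(!responsive))
}

#' Population-vector direction preference
#'
#' Estimates each unit's preferred translation (or rotation) direction as
#' the direction of the response-weighted vector sum of the stimulus
#' directions: `sum_i r_ij e_i`, with `e_i` the 3D Cartesian unit vector
#' of stimulus `i`.
#'
#' @param responses `n_stimuli x n_units` non-negative activation matrix.
#' @param directions `n_stimuli x 3` matrix of stimulus direction unit
#'   vectors, or an `n x 2` matrix of (azimuth, elevation) pairs in
#'   degrees.
#' @return A data frame with one row per unit: `azimuth`, `elevation`
#'   (deg), the Cartesian preference vector `px, py, pz` (unnormalized),
#'   and `defined` (FALSE when the resultant is zero, e.g. perfect
#'   antipodal cancellation).
#' @export
population_vector_preference <- function(responses, directions) {
  E <- as_direction_matrix(directions)
  if (nrow(E) != nrow(responses)) stop("stimulus count mismatch")
  P <- crossprod(responses, E)                   # n_units x 3
  nrm <- sqrt(rowSums(P^2))
  defined <- nrm > 1e-12
  ang <- matrix(NA_real_, nrow(P), 2)
  if (any(defined)) ang[defined, ] <- cart_to_sph(P[defined, , drop = FALSE])
  data.frame(azimuth = ang[, 1], elevation = ang[, 2],
             px = P[, 1], py = P[, 2], pz = P[, 3], defined = defined)
}

as_direction_matrix <- function(directions) {
  directions <- as.matrix(directions)
  if (ncol(directions) == 2) {
    sph_to_cart(directions[, 1], directions[, 2])
  } else if (ncol(directions) == 3) {
    directions / sqrt(rowSums(directions^2))
  } else stop("directions must be n x 2 angles or n x 3 vectors")
}

#' Heading / rotation tuning index
#'
#' Strength of direction selectivity of each unit:
#' \deqn{\mathrm{TI}_j = \frac{\left| \sum_i r_{ij} \vec e_i \right|_2}
#'                            {\sum_i \left| r_{ij} \vec e_i \right|_2}}
#' which ranges from 0 (no directional tuning; e.g. equal responses to
#' antipodal stimuli cancel) to 1 (response to a single direction).
#' Computed on the translation protocol this is the heading tuning index
#' (HTI); with rotation-axis vectors it is the rotation tuning index
#' (RTI).  The index is invariant to rescaling a unit's responses.
#'
#' @inheritParams population_vector_preference
#' @return Numeric vector of indices in `[0, 1]`; `NA` for units with
#'   all-zero responses.
#' @export
tuning_index <- function(responses, directions) {
  E <- as_direction_matrix(directions)
  if (any(responses < 0)) stop("responses must be non-negative")
  num <- sqrt(rowSums(crossprod(responses, E)^2))
  den <- colSums(responses)                      # |r_i e_i| = r_i for unit e_i
  ifelse(den > 0, num / den, NA_real_)
}

#' Great-circle difference between two direction preferences
#'
#' Angle (deg, in `[0, 180]`) between paired translation and rotation
#' preference vectors, e.g. to ask whether units prefer orthogonal
#' translation and rotation directions.
#'
#' @param pref_t,pref_r Data frames from
#'   [population_vector_preference()], or `n x 3` matrices.
#' @return Numeric vector of angles; `NA` where either preference is
#'   undefined.
#' @export
preference_difference <- function(pref_t, pref_r) {
  vt <- pref_to_matrix(pref_t)
  vr <- pref_to_matrix(pref_r)
  ok <- rowSums(vt^2) > 0 & rowSums(vr^2) > 0 &
    stats::complete.cases(vt) & stats::complete.cases(vr)
  out <- rep(NA_real_, nrow(vt))
  out[ok] <- angle_between(vt[ok, , drop = FALSE], vr[ok, , drop = FALSE])
  out
}

pref_to_matrix <- function(p) {
  if (is.data.frame(p)) as.matrix(p[, c("px", "py", "pz")]) else as.matrix(p)
}

#' Axis-proximity census of direction preferences
#'
#' Counts the units whose preferred direction falls within `threshold`
#' degrees of the nearer pole of each cardinal axis.  For translation the
#' axes are lateral (leftward-rightward, the camera `x` axis), fore-aft
#' (forward-backward, `z`) and vertical (upward-downward, `y`); for
#' rotation they are pitch (`x`), yaw (`y`) and roll (`z`).
#'
#' @param preferences Data frame from [population_vector_preference()]
#'   (or `n x 3` matrix of preference vectors).
#' @param kind `"T"` (lateral / fore-aft / vertical) or `"R"`
#'   (yaw / pitch / roll).
#' @param threshold Proximity threshold in degrees. Default 30.
#' @return Data frame with one row per axis: `axis`, `count`, `n`,
#'   `percent`.  Units with undefined preferences are dropped from both
#'   numerator and denominator.
#' @export
axis_proximity_table <- function(preferences, kind = c("T", "R"), threshold = 30) {
  kind <- match.arg(kind)
  v <- pref_to_matrix(preferences)
  ok <- stats::complete.cases(v) & rowSums(v^2) > 0
  u <- v[ok, , drop = FALSE] / sqrt(rowSums(v[ok, , drop = FALSE]^2))
  n <- nrow(u)
  axes <- if (kind == "T") {
    list(lateral = 1, `fore-aft` = 3, vertical = 2)
  } else {
    list(yaw = 2, pitch = 1, roll = 3)
  }
  counts <- vapply(axes, function(j) {
    ang <- acos(pmin(1, abs(u[, j]))) * 180 / pi  # angle to the nearer pole
    sum(ang <= threshold)
  }, 0L)
  data.frame(axis = names(axes), count = counts, n = n,
             percent = 100 * counts / n, row.names = NULL)
}

#' Vinje-Gallant sparseness
#'
#' For a non-negative response vector `r` of length `N`:
#' \deqn{s = \left(1 - \frac{(\sum r_i)^2 / N}{\sum r_i^2}\right) \Big/ \left(1 - \frac 1 N\right)}
#' `s = 0` indicates a dense code (all entries equal and active) and
#' `s = 1` a local code (a single active entry).
#'
#' @param r Non-negative numeric vector with at least one non-zero entry.
#' @return Sparseness in `[0, 1]`; `NA` for an all-zero vector.
#' @export
sparseness <- function(r) {
  if (any(r < 0)) stop("responses must be non-negative")
  n <- length(r)
  s2 <- sum(r^2)
  if (s2 == 0) return(NA_real_)
  (1 - (sum(r)^2 / n) / s2) / (1 - 1 / n)
}

#' Population and lifetime sparseness of a model population
#'
#' *Population* sparseness applies [sparseness()] to the population
#' response to each stimulus (averaged over stimuli); *lifetime*
#' sparseness applies it to each unit's responses across stimuli
#' (averaged over units).  All-zero vectors are excluded from the
#' averages and counted.
#'
#' @param responses `n_stimuli x n_units` non-negative activation
#'   matrix.
#' @param conf Confidence level for the normal-approximation interval.
#' @return List of class `"sparseness_report"` with `population` and
#'   `lifetime` (each: `mean`, `ci`, `n_excluded`), and
#'   `fraction_unresponsive`.
#' @export
sparseness_report <- function(responses, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  summarize <- function(vals) {
    v <- vals[!is.na(vals)]
    m <- mean(v)
    se <- stats::sd(v) / sqrt(length(v))
    list(mean = m, ci = c(m - z * se, m + z * se),
         n_excluded = sum(is.na(vals)))
  }
  pop <- apply(responses, 1, sparseness)
  life <- apply(responses, 2, sparseness)
  structure(list(population = summarize(pop), lifetime = summarize(life),
                 fraction_unresponsive = exclude_unresponsive(responses)$fraction_unresponsive),
            class = "sparseness_report")
}

#' @export
print.sparseness_report <- function(x, ...) {
  cat(sprintf("Population sparseness: %.3f [%.3f, %.3f]\n",
              x$population$mean, x$population$ci[1], x$population$ci[2]))
  cat(sprintf("Lifetime sparseness:   %.3f [%.3f, %.3f]\n",
              x$lifetime$mean, x$lifetime$ci[1], x$lifetime$ci[2]))
  cat(sprintf("Unresponsive units:    %.1f%%\n", 100 * x$fraction_unresponsive))
  invisible(x)
}
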