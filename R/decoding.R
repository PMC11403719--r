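#' Self-motion estimation error metrics
#'
#' Per-label mean absolute error and mean squared error of predicted
#' against true self-motion labels, with aggregates over the two
#' translation labels (azimuth, elevation) and the three rotation rates
#' (pitch, yaw, roll).  Azimuth errors are computed on the circle:
#' differences are wrapped to `[-180, 180)` before taking absolute
#' values or squares, so a prediction of -179 degrees for a target of
#' 179 degrees scores a 2 degree error.
#'
#' @param truth,predicted `n x 5` label matrices (degrees and deg/s).
#' @return An object of class `"accuracy_report"`: list with `per_label`
#'   (data frame of MAE and MSE per label), `translation` and `rotation`
#'   (each `mae`, `mse` pooled over the group's labels), and `n`.
#' @export
error_metrics <- function(truth, predicted) {
  truth <- as.matrix(truth); predicted <- as.matrix(predicted)
  if (!all(dim(truth) == dim(predicted)) || ncol(truth) != 5)
    stop("truth and predicted must both be n x 5")
  err <- predicted - truth
  err[, 1] <- wrap_angle(err[, 1])
  mae <- colMeans(abs(err)); mse <- colMeans(err^2)
  lab <- c("t_azimuth", "t_elevation", "r_pitch", "r_yaw", "r_roll")
  structure(list(
    per_label = data.frame(label = lab, mae = mae, mse = mse, row.names = NULL),
    translation = list(mae = mean(abs(err[, 1:2])), mse = mean(err[, 1:2]^2)),
    rotation = list(mae = mean(abs(err[, 3:5])), mse = mean(err[, 3:5]^2)),
    n = nrow(truth)), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Self-motion accuracy (n = %d):\n", x$n))
  cat(sprintf("  translation: MAE %.2f deg,  MSE %.1f deg^2\n",
              x$translation$mae, x$translation$mse))
  cat(sprintf("  rotation:    MAE %.3f deg/s, MSE %.3f (deg/s)^2\n",
              x$rotation$mae, x$rotation$mse))
  invisible(x)
}

#' Cross-validated linear decoding from population activations
#'
#' Fits a separate ordinary-least-squares linear regression from unit
#' activations to each self-motion label and reports the mean validation
#' MAE over a k-fold cross-validation, with a normal-approximation 95%
#' confidence interval across folds.  Unresponsive units (zero
#' activation to every stimulus) are excluded first; from the responsive
#' units a random sample of `n_units` is drawn once (all responsive
#' units are used if fewer are available).
#'
#' @param activations `n x d` activation matrix.
#' @param labels `n x k` label matrix (one regression per column).
#' @param folds Number of CV folds. Default 10.
#' @param n_units Number of units to decode from. Default 144.
#' @param circular Logical vector (recycled over label columns): treat
#'   the label as circular (errors wrapped to `[-180, 180)`)?
#' @param conf Confidence level for the across-fold interval.
#' @param seed Integer RNG seed (fold assignment and unit sample).
#' @return List of class `"decode_cv"`: `mae` (mean across folds, per
#'   label), `ci` (2 x k matrix), `fold_mae` (folds x k), `overall`
#'   (mean MAE across labels), `units_used`.
#' @export
linear_decode_cv <- function(activations, labels, folds = 10, n_units = 144,
                             circular = FALSE, conf = 0.95, seed = 1) {
  activations <- as.matrix(activations)
  labels <- as.matrix(labels)
  n <- nrow(activations)
  if (n < folds) stop("fewer samples than folds")
  circular <- rep_len(circular, ncol(labels))
  set.seed(seed)
  resp <- which(exclude_unresponsive(activations)$responsive)
  units <- if (length(resp) > n_units) sort(sample(resp, n_units)) else resp
  x <- activations[, units, drop = FALSE]
  fold_id <- sample(rep_len(seq_len(folds), n))
  fold_mae <- matrix(NA_real_, folds, ncol(labels))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    xt <- cbind(1, x[tr, , drop = FALSE])
    xv <- cbind(1, x[!tr, , drop = FALSE])
    beta <- tryCatch(qr.coef(qr(xt), labels[tr, , drop = FALSE]),
                     error = function(e) NULL)
    if (is.null(beta)) stop("linear decode failed on fold ", f)
    beta[is.na(beta)] <- 0
    pred <- xv %*% beta
    err <- pred - labels[!tr, , drop = FALSE]
    for (j in seq_len(ncol(labels))) {
      e <- if (circular[j]) wrap_angle(err[, j]) else err[, j]
      fold_mae[f, j] <- mean(abs(e))
    }
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  m <- colMeans(fold_mae)
  se <- apply(fold_mae, 2, stats::sd) / sqrt(folds)
  structure(list(mae = m, ci = rbind(lower = m - z * se, upper = m + z * se),
                 fold_mae = fold_mae, overall = mean(m),
                 units_used = units),
            class = "decode_cv")
}

#' @export
print.decode_cv <- function(x, ...) {
  cat(sprintf("%d-fold linear decoding from %d units: mean MAE %.3f\n",
              nrow(x$fold_mae), length(x$units_used), x$overall))
  for (j in seq_along(x$mae)) {
    cat(sprintf("  label %d: %.3f [%.3f, %.3f]\n", j, x$mae[j],
                x$ci[1, j], x$ci[2, j]))
  }
  invisible(x)
}

#' Train/test linear decoding
#'
#' Fits one linear regression per label on training activations and
#' evaluates on held-out test activations — the protocol used for
#' whole-test-set accuracy (as opposed to the cross-validated protocol
#' of [linear_decode_cv()]).
#'
#' @param a_train,a_test Activation matrices.
#' @param y_train,y_test `n x 5` label matrices.
#' @return An [error_metrics()] report on the test set.
#' @export
linear_decode_eval <- function(a_train, y_train, a_test, y_test) {
  xt <- cbind(1, as.matrix(a_train))
  xv <- cbind(1, as.matrix(a_test))
  beta <- qr.coef(qr(xt), as.matrix(y_train))
  beta[is.na(beta)] <- 0
  error_metrics(y_test, xv %*% beta)
}

#' PCA baseline representation
#'
#' Projects MT activations onto their top principal components, the
#' non-negativity-free counterpart of the NNMF basis used to ask whether
#' dimensionality reduction alone explains decoding behaviour.
#' Components are fitted on the training activations (column-centred);
#' train and test sets are projected into the same space.  For wide
#' matrices the eigendecomposition is taken on whichever Gram matrix is
#' smaller.
#'
#' @param a_train,a_test MT activation matrices (`n x m`).
#' @param n_components Number of components. Default 64.
#' @return List with `train`, `test` (projected activations), `rotation`
#'   (`m x n_components`), `center`, and `sdev`.
#' @export
pca_baseline <- function(a_train, a_test = NULL, n_components = 64) {
  a_train <- as.matrix(a_train)
  n <- nrow(a_train); m <- ncol(a_train)
  if (n_components > min(n, m)) stop("more components than matrix rank")
  ctr <- colMeans(a_train)
  keep <- seq_len(n_components)
  if (n <= m) {
    ## centred Gram via rank-1 corrections; the centred matrix itself is
    ## never materialized (it would double the memory footprint)
    G <- tcrossprod(a_train)                  # n x n
    xm <- drop(a_train %*% ctr)
    ## sequential rank-1 corrections keep at most one n x n temporary alive
    G <- G - xm                               # column-wise recycling
    G <- sweep(G, 2, xm, "-")
    G <- G + sum(ctr^2)
    ev <- eigen(G, symmetric = TRUE)
    rm(G)
    lam <- pmax(ev$values[keep], 0)
    u <- ev$vectors[, keep, drop = FALSE]
    rot <- (crossprod(a_train, u) - outer(ctr, colSums(u))) %*%
      diag(1 / sqrt(pmax(lam, 1e-300)), n_components)
  } else {
    G <- crossprod(a_train)                   # m x m
    G <- G - n * outer(ctr, ctr)
    ev <- eigen(G, symmetric = TRUE)
    lam <- pmax(ev$values[keep], 0)
    rot <- ev$vectors[, keep, drop = FALSE]
  }
  project <- function(x) x %*% rot - rep(drop(crossprod(ctr, rot)), each = nrow(x))
  out <- list(train = project(a_train), rotation = rot, center = ctr,
              sdev = sqrt(lam / max(n - 1, 1)))
  if (!is.null(a_test)) out$test <- project(as.matrix(a_test))
  out
}
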