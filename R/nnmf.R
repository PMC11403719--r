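#' Random initialization of NNMF factors
#'
#' Both factors are drawn uniformly on `[0, sqrt(mean(A) / k)]`, the
#' convention of the scikit-learn NNMF implementation: the expected value
#' of an entry of `H W` then matches the mean of `A` up to a constant
#' factor, so the first iterations start at the right scale.  An all-zero
#' input yields all-zero factors.
#'
#' @param n,m Dimensions of the data matrix (samples x features).
#' @param k Number of basis vectors.
#' @param a The data matrix (only its mean is used).
#' @param seed Integer RNG seed.
#' @return List with `h` (`n x k`) and `w` (`k x m`), both non-negative.
#' @export
nnmf_init <- function(n, m, k, a, seed = 1) {
  set.seed(seed)
  b <- sqrt(mean(a) / k)
  list(h = matrix(stats::runif(n * k, 0, b), n, k),
       w = matrix(stats::runif(k * m, 0, b), k, m))
}

## Frobenius reconstruction MSE via the trace identity:
## ||A - HW||^2 = ||A||^2 - 2<H'A, W> + <H'H, WW'> -- avoids forming HW.
recon_mse <- function(norm_a2, hta, w, hth, n, m) {
  (norm_a2 - 2 * sum(hta * w) + sum(hth * tcrossprod(w))) / (n * m)
}

#' Fit a single non-negative matrix factorization
#'
#' Factors a non-negative matrix `A` (`n x m`) into `H W` with `H`
#' (`n x k`) and `W` (`k x m`) non-negative, minimizing the mean squared
#' reconstruction error `mean((A - HW)^2)`.
#'
#' Three fitting algorithms are available:
#' \describe{
#'   \item{`"mu"`}{Lee-Seung multiplicative updates (the default).  Each
#'     update rescales every entry by the ratio of the data-driven and
#'     reconstruction-driven terms, preserving non-negativity exactly.}
#'   \item{`"adam"`}{Projected stochastic gradient descent: Adam with
#'     mini-batches of `batch_size` samples, with both factors clamped at
#'     zero once per epoch.}
#'   \item{`"als"`}{Alternating least squares with clamping of negative
#'     entries after each exact solve.}
#' }
#'
#' All three stop when the change in the root-mean-square reconstruction
#' residual between successive epochs is at most `tol`, after at least
#' `min_iter` epochs (the warm-up guard avoids triggering on the early
#' optimizer plateau), or at `max_iter`.
#'
#' @param a Non-negative numeric matrix (`n x m`).
#' @param k Number of basis vectors.
#' @param algorithm `"mu"`, `"adam"` or `"als"`.
#' @param tol Stopping tolerance on the change in RMS residual.
#' @param min_iter,max_iter Iteration bounds.
#' @param learning_rate Adam step size (`"adam"` only).
#' @param batch_size Mini-batch size (`"adam"` only).
#' @param seed Integer RNG seed (initialization and batch order).
#' @return List with `h`, `w`, `loss` (per-epoch MSE trace), and
#'   `iterations`.
#' @examples
#' h <- matrix(runif(20), 10); w <- matrix(runif(30), 2)
#' fit <- nnmf_fit(h %*% w, k = 2, max_iter = 500, tol = 1e-8)
#' fit$loss[fit$iterations] < 1e-4
#' @export
nnmf_fit <- function(a, k, algorithm = c("mu", "adam", "als"),
                     tol = 1e-4, min_iter = 20, max_iter = 200,
                     learning_rate = 1e-3, batch_size = 64, seed = 1) {
  algorithm <- match.arg(algorithm)
  if (any(a < 0) || any(!is.finite(a))) stop("input matrix must be non-negative and finite")
  n <- nrow(a); m <- ncol(a)
  fac <- nnmf_init(n, m, k, a, seed)
  switch(algorithm,
         mu = nnmf_fit_mu(a, fac$h, fac$w, tol, min_iter, max_iter),
         als = nnmf_fit_als(a, fac$h, fac$w, tol, min_iter, max_iter),
         adam = nnmf_fit_adam(a, fac$h, fac$w, tol, min_iter, max_iter,
                              learning_rate, batch_size))
}

nnmf_fit_mu <- function(a, h, w, tol, min_iter, max_iter) {
  n <- nrow(a); m <- ncol(a); eps <- 1e-12
  norm_a2 <- sum(a^2)
  prev_rms <- Inf; loss <- numeric(0)
  for (it in seq_len(max_iter)) {
    h <- h * (a %*% t(w)) / (h %*% tcrossprod(w) + eps)
    hta <- crossprod(h, a)
    w <- w * hta / (crossprod(h) %*% w + eps)
    mse <- recon_mse(norm_a2, hta, w, crossprod(h), n, m)
    loss <- c(loss, mse)
    rms <- sqrt(max(mse, 0))
    if (it >= min_iter && abs(prev_rms - rms) <= tol) break
    prev_rms <- rms
  }
  list(h = h, w = w, loss = loss, iterations = it)
}

nnmf_fit_als <- function(a, h, w, tol, min_iter, max_iter) {
  n <- nrow(a); m <- ncol(a); k <- ncol(h)
  norm_a2 <- sum(a^2)
  ridge <- diag(1e-10, k)
  prev_rms <- Inf; loss <- numeric(0)
  for (it in seq_len(max_iter)) {
    h <- a %*% t(w) %*% solve(tcrossprod(w) + ridge)
    h[h < 0] <- 0
    hta <- crossprod(h, a)
    w <- solve(crossprod(h) + ridge) %*% hta
    w[w < 0] <- 0
    mse <- recon_mse(norm_a2, hta, w, crossprod(h), n, m)
    loss <- c(loss, mse)
    rms <- sqrt(max(mse, 0))
    if (it >= min_iter && abs(prev_rms - rms) <= tol) break
    prev_rms <- rms
  }
  list(h = h, w = w, loss = loss, iterations = it)
}

nnmf_fit_adam <- function(a, h, w, tol, min_iter, max_iter,
                          learning_rate, batch_size) {
  n <- nrow(a); m <- ncol(a); k <- ncol(h)
  norm_a2 <- sum(a^2)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-7
  mh <- vh <- h * 0; mw <- vw <- w * 0
  t_w <- 0; t_h <- integer(n)
  prev_rms <- Inf; loss <- numeric(0)
  for (ep in seq_len(max_iter)) {
    ord <- sample.int(n)
    for (s in seq(1, n, by = batch_size)) {
      ib <- ord[s:min(s + batch_size - 1, n)]
      hb <- h[ib, , drop = FALSE]
      res <- hb %*% w - a[ib, , drop = FALSE]
      nb <- length(ib)
      gh <- 2 / (nb * m) * (res %*% t(w))
      gw <- 2 / (nb * m) * crossprod(hb, res)
      t_w <- t_w + 1
      mw <- b1 * mw + (1 - b1) * gw
      vw <- b2 * vw + (1 - b2) * gw^2
      w <- w - learning_rate * (mw / (1 - b1^t_w)) / (sqrt(vw / (1 - b2^t_w)) + eps)
      t_h[ib] <- t_h[ib] + 1
      mh[ib, ] <- b1 * mh[ib, , drop = FALSE] + (1 - b1) * gh
      vh[ib, ] <- b2 * vh[ib, , drop = FALSE] + (1 - b2) * gh^2
      h[ib, ] <- hb - learning_rate *
        (mh[ib, , drop = FALSE] / (1 - b1^t_h[ib])) /
        (sqrt(vh[ib, , drop = FALSE] / (1 - b2^t_h[ib])) + eps)
    }
    h[h < 0] <- 0; w[w < 0] <- 0       # projection once per epoch
    hta <- crossprod(h, a)
    mse <- recon_mse(norm_a2, hta, w, crossprod(h), n, m)
    if (!is.finite(mse)) stop("NNMF fit diverged: non-finite loss")
    loss <- c(loss, mse)
    rms <- sqrt(max(mse, 0))
    if (ep >= min_iter && abs(prev_rms - rms) <= tol) break
    prev_rms <- rms
  }
  list(h = h, w = w, loss = loss, iterations = ep)
}

#' NNMF model of area MSTd
#'
#' Fits the non-negative matrix factorization model of dorsal MSTd to a
#' matrix of model MT activations.  The MT matrix `A` (`n` stimuli x `m`
#' units) is factored as `A ~ H W` with non-negative `H` (`n x k`,
#' interpreted as MSTd unit activations) and `W` (`k x m`, the MT-to-MSTd
#' connection weights).  The factorization is repeated `repeats` times
#' from independent random initializations and the basis vectors of all
#' fits are concatenated, giving a model population of `k * repeats`
#' units (896 at the defaults of `k = 64`, `repeats = 14`), which
#' incorporates the variability of the fitted bases.
#'
#' Responses of the fitted population to novel stimuli are computed with
#' [predict.mstd_nnmf()] (equivalently [mstd_responses()]): `H_test =
#' A_test W'`.
#'
#' @param a MT activation matrix (`n x m`), e.g. from
#'   [mt_activations()].
#' @param k Basis vectors per fit. Default 64.
#' @param repeats Number of independent fits concatenated. Default 14.
#' @param algorithm,tol,min_iter,max_iter,learning_rate,batch_size See
#'   [nnmf_fit()].
#' @param seed Integer base seed; fit `r` uses `seed + r - 1`.
#' @param verbose Print per-fit progress.
#' @return An object of class `"mstd_nnmf"` with components `w`
#'   (`k*repeats x m` basis matrix), `h` (`n x k*repeats` training
#'   coefficients), `fit_index` (which fit each unit came from), `loss`
#'   (list of per-fit loss traces), `config`, and `dims`.
#' @examples
#' a <- matrix(runif(50 * 40), 50, 40)
#' mod <- mstd_nnmf(a, k = 4, repeats = 2, max_iter = 50)
#' dim(coef(mod))       # 8 x 40
#' dim(predict(mod, a)) # 50 x 8
#' @export
mstd_nnmf <- function(a, k = 64, repeats = 14,
                      algorithm = c("mu", "adam", "als"),
                      tol = 1e-4, min_iter = 20, max_iter = 200,
                      learning_rate = 1e-3, batch_size = 64,
                      seed = 1, verbose = FALSE) {
  algorithm <- match.arg(algorithm)
  cl <- match.call()
  n <- nrow(a); m <- ncol(a)
  w <- matrix(0, k * repeats, m)
  h <- matrix(0, n, k * repeats)
  loss <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fit <- nnmf_fit(a, k, algorithm = algorithm, tol = tol,
                    min_iter = min_iter, max_iter = max_iter,
                    learning_rate = learning_rate, batch_size = batch_size,
                    seed = seed + r - 1)
    rows <- (r - 1) * k + seq_len(k)
    w[rows, ] <- fit$w
    h[, rows] <- fit$h
    loss[[r]] <- fit$loss
    if (verbose)
      message(sprintf("fit %d/%d: %d iterations, loss %.4g",
                      r, repeats, fit$iterations, fit$loss[fit$iterations]))
  }
  structure(list(w = w, h = h,
                 fit_index = rep(seq_len(repeats), each = k),
                 loss = loss,
                 config = list(k = k, repeats = repeats, algorithm = algorithm,
                               tol = tol, min_iter = min_iter,
                               max_iter = max_iter,
                               learning_rate = learning_rate,
                               batch_size = batch_size, seed = seed),
                 dims = c(n = n, m = m),
                 call = cl),
            class = "mstd_nnmf")
}

#' @export
print.mstd_nnmf <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("NNMF model of MSTd: %d units (%d fits x %d basis vectors) over %d MT units\n",
              nrow(x$w), cfg$repeats, cfg$k, x$dims["m"]))
  cat(sprintf("  algorithm: %s; final reconstruction MSE %.4g - %.4g\n",
              cfg$algorithm,
              min(vapply(x$loss, function(l) l[length(l)], 0)),
              max(vapply(x$loss, function(l) l[length(l)], 0))))
  invisible(x)
}

#' @export
summary.mstd_nnmf <- function(object, ...) {
  fin <- vapply(object$loss, function(l) l[length(l)], 0)
  its <- vapply(object$loss, length, 0L)
  out <- list(config = object$config, dims = object$dims,
              final_loss = fin, iterations = its,
              w_sparsity = mean(object$w < 1e-8),
              n_units = nrow(object$w))
  class(out) <- "summary.mstd_nnmf"
  out
}

#' @export
print.summary.mstd_nnmf <- function(x, ...) {
  cat(sprintf("NNMF MSTd model: %d units, fitted on %d samples x %d MT units\n",
              x$n_units, x$dims["n"], x$dims["m"]))
  cat(sprintf("  %d fits (algorithm '%s'), iterations %s, final MSE %.4g (mean)\n",
              x$config$repeats, x$config$algorithm,
              paste(range(x$iterations), collapse = "-"), mean(x$final_loss)))
  cat(sprintf("  fraction of near-zero basis weights: %.3f\n", x$w_sparsity))
  invisible(x)
}

#' @export
coef.mstd_nnmf <- function(object, ...) object$w

#' MSTd responses to novel stimuli
#'
#' Computes the model MSTd activations to stimuli that were not used in
#' fitting: `H_test = A_test W'`, where `A_test` holds the MT activations
#' of the novel stimuli.
#'
#' @param object A fitted [mstd_nnmf()] model (or a basis matrix `W`).
#' @param a_test MT activation matrix (`n_test x m`).
#' @return `n_test x k_total` non-negative response matrix.
#' @export
mstd_responses <- function(object, a_test) {
  w <- if (inherits(object, "mstd_nnmf")) object$w else object
  if (ncol(a_test) != ncol(w)) stop("MT unit count mismatch between model and stimuli")
  if (any(a_test < 0)) stop("MT activations must be non-negative")
  a_test %*% t(w)
}

#' @rdname mstd_responses
#' @param newdata MT activation matrix, or a [flow_dataset()] (converted
#'   with [mt_activations()] first).
#' @param ... Unused.
#' @export
predict.mstd_nnmf <- function(object, newdata, ...) {
  if (inherits(newdata, "flow_dataset")) newdata <- mt_activations(newdata)
  mstd_responses(object, newdata)
}

#' @export
fitted.mstd_nnmf <- function(object, fit = 1, ...) {
  rows <- which(object$fit_index == fit)
  object$h[, rows, drop = FALSE] %*% object$w[rows, , drop = FALSE]
}

#' @export
residuals.mstd_nnmf <- function(object, a, fit = 1, ...) {
  a - fitted(object, fit = fit)
}

#' @export
plot.mstd_nnmf <- function(x, ...) {
  its <- max(vapply(x$loss, length, 0L))
  fin <- vapply(x$loss, function(l) l[length(l)], 0)
  graphics::plot(NA, xlim = c(1, its), ylim = range(unlist(x$loss)),
                 log = "y", xlab = "iteration", ylab = "reconstruction MSE", ...)
  for (l in x$loss) graphics::lines(seq_along(l), l, col = "#00000055")
  graphics::abline(h = mean(fin), lty = 3)
  invisible(x)
}
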