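## Accuracy-optimized feedforward networks for self-motion estimation.
##
## Networks map a 15 x 15 x 2 optic-flow field (or the 9,000-unit MT
## representation) to the 5 self-motion labels.  The architecture is
## conv/ReLU/max-pool stacks followed by dense ReLU layers and a 5-unit
## linear regression head; MLP variants omit the conv/pool stacks.
## Activation matrices are batch x (pixels * channels), channel-major
## blocks with pixel varying fastest.

#' Network architecture specification
#'
#' @param conv List of conv/pool stacks, each a list with `filters`,
#'   `size` (square filter side), `pool_window`, `pool_stride`.  Empty
#'   list for MLP variants.
#' @param dense Integer vector of dense-layer widths (at least one).
#' @param l1 L1 regularization strength per weight layer (recycled), as
#'   in LASSO-style sparsity pressure on the weights.
#' @param nonneg Constrain weights to be non-negative?  The first hidden
#'   layer and the output layer are exempt from the constraint.
#' @param input `"flow"` (15 x 15 x 2 optic flow) or `"mt"` (9,000 MT
#'   activations; forces an MLP).
#' @param grid_size Input grid side for flow input.
#' @return An object of class `"flownet_spec"`.
#' @examples
#' flownet_spec(conv = list(list(filters = 16, size = 2,
#'                               pool_window = 2, pool_stride = 2)),
#'              dense = c(64, 32))
#' @export
flownet_spec <- function(conv = list(), dense = c(128), l1 = 0,
                         nonneg = FALSE, input = c("flow", "mt"),
                         grid_size = 15) {
  input <- match.arg(input)
  if (input == "mt" && length(conv) > 0) stop("MT input supports dense layers only")
  for (st in conv) {
    stopifnot(st$filters >= 1, st$size >= 1, st$pool_window >= 1, st$pool_stride >= 1)
  }
  stopifnot(length(dense) >= 1, all(dense >= 1))
  n_weight_layers <- length(conv) + length(dense) + 1
  structure(list(conv = conv, dense = as.integer(dense),
                 l1 = rep_len(l1, n_weight_layers),
                 nonneg = nonneg, input = input,
                 grid_size = as.integer(grid_size)),
            class = "flownet_spec")
}

#' @export
print.flownet_spec <- function(x, ...) {
  cat(sprintf("Network spec (%s input): %d conv stack(s), dense [%s], %s\n",
              x$input, length(x$conv), paste(x$dense, collapse = ", "),
              if (x$nonneg) "non-negative weights" else "unconstrained weights"))
  invisible(x)
}

#' Glorot-uniform weight initialization
#'
#' Weights are drawn from `U[-b, b]` with `b = sqrt(6 / (f_in + f_out))`.
#' For networks with the non-negative weight constraint the absolute
#' value of the draw is used, so constrained layers start at non-zero
#' non-negative values.
#'
#' @param f_in,f_out Fan-in and fan-out of the layer.
#' @param n Number of draws.
#' @param nonneg Take absolute values?
#' @return Numeric vector of `n` draws.
#' @export
glorot_init <- function(f_in, f_out, n = f_in * f_out, nonneg = FALSE) {
  b <- sqrt(6 / (f_in + f_out))
  w <- stats::runif(n, -b, b)
  if (nonneg) abs(w) else w
}

## ---- geometry helpers for conv / pool index maps -------------------------

## 'same' conv gather map: for each of k^2*C (offset, channel) pairs, the
## source column in the padded input (0 = zero pad).
conv_index <- function(hw_side, k, n_chan) {
  hw <- hw_side^2
  px <- rep(seq_len(hw_side), times = hw_side)   # x fastest
  py <- rep(seq_len(hw_side), each = hw_side)
  lo <- -((k - 1) %/% 2)
  offs <- expand.grid(dx = lo:(lo + k - 1), dy = lo:(lo + k - 1),
                      KEEP.OUT.ATTRS = FALSE)
  idx <- matrix(0L, hw, k * k * n_chan)
  j <- 0L
  for (c in seq_len(n_chan)) {
    for (o in seq_len(nrow(offs))) {
      j <- j + 1L
      sx <- px + offs$dx[o]; sy <- py + offs$dy[o]
      ok <- sx >= 1 & sx <= hw_side & sy >= 1 & sy <= hw_side
      src <- ifelse(ok, (sy - 1) * hw_side + sx + (c - 1) * hw, 0L)
      idx[, j] <- src
    }
  }
  idx
}

## valid max-pool source map: out position -> source pixel per window offset
pool_index <- function(hw_side, w, s) {
  n_out <- (hw_side - w) %/% s + 1
  if (n_out < 1) stop("pool window larger than the feature map")
  ox <- rep(seq_len(n_out), times = n_out)
  oy <- rep(seq_len(n_out), each = n_out)
  offs <- expand.grid(a = 0:(w - 1), b = 0:(w - 1), KEEP.OUT.ATTRS = FALSE)
  idx <- matrix(0L, n_out^2, nrow(offs))
  for (o in seq_len(nrow(offs))) {
    sx <- (ox - 1) * s + 1 + offs$a[o]
    sy <- (oy - 1) * s + 1 + offs$b[o]
    idx[, o] <- (sy - 1) * hw_side + sx
  }
  list(idx = idx, n_out = n_out)
}

## ---- network construction -------------------------------------------------

#' Build an untrained network from a specification
#'
#' Assembles the layer stack and initializes all weights with
#' [glorot_init()].  Layers under the non-negative constraint (all but
#' the first hidden layer and the output layer when `spec$nonneg`) are
#' initialized from the absolute-value draw.
#'
#' @param spec A [flownet_spec()].
#' @param seed Integer RNG seed for the initialization.
#' @return An object of class `"flownet"`.
#' @export
build_network <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "flownet_spec"))
  set.seed(seed)
  layers <- list()
  side <- spec$grid_size
  n_chan <- 2
  n_weight <- 0
  total_weight_layers <- length(spec$conv) + length(spec$dense) + 1
  constrained <- function(i) spec$nonneg && i > 1 && i < total_weight_layers
  for (st in spec$conv) {
    n_weight <- n_weight + 1
    fin <- st$size^2 * n_chan; fout <- st$filters
    cons <- constrained(n_weight)
    layers[[length(layers) + 1]] <- list(
      type = "conv", k = st$size, filters = st$filters,
      side = side, chan = n_chan,
      idx = conv_index(side, st$size, n_chan),
      w = matrix(glorot_init(fin, fout, nonneg = cons), fin, fout),
      b = numeric(fout),
      l1 = spec$l1[n_weight], constrained = cons)
    layers[[length(layers) + 1]] <- list(type = "relu")
    pl <- pool_index(side, st$pool_window, st$pool_stride)
    layers[[length(layers) + 1]] <- list(type = "pool", side = side,
                                         chan = st$filters,
                                         idx = pl$idx, n_out = pl$n_out)
    side <- pl$n_out
    n_chan <- st$filters
  }
  width <- if (spec$input == "mt") 9000L else side^2 * n_chan
  for (d in spec$dense) {
    n_weight <- n_weight + 1
    cons <- constrained(n_weight)
    layers[[length(layers) + 1]] <- list(
      type = "dense",
      w = matrix(glorot_init(width, d, nonneg = cons), width, d),
      b = numeric(d), l1 = spec$l1[n_weight], constrained = cons)
    layers[[length(layers) + 1]] <- list(type = "relu")
    width <- d
  }
  n_weight <- n_weight + 1
  layers[[length(layers) + 1]] <- list(
    type = "dense",
    w = matrix(glorot_init(width, 5, nonneg = constrained(n_weight)), width, 5),
    b = numeric(5), l1 = spec$l1[n_weight], constrained = constrained(n_weight))
  structure(list(spec = spec, layers = layers, trained = FALSE,
                 history = NULL, seed = seed),
            class = "flownet")
}

#' @export
print.flownet <- function(x, ...) {
  nw <- sum(vapply(x$layers, function(l)
    if (!is.null(l$w)) length(l$w) + length(l$b) else 0L, 0))
  cat(sprintf("%s network (%s input, %d parameters)%s\n",
              if (length(x$spec$conv)) "Convolutional" else "Dense",
              x$spec$input, nw,
              if (x$trained) ", trained" else ", untrained"))
  invisible(x)
}

#' Number of trainable parameters
#' @param net A [build_network()] result.
#' @return Integer count.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$layers, function(l)
    if (!is.null(l$w)) length(l$w) + length(l$b) else 0L, 0))
}

## ---- forward / backward ---------------------------------------------------

## forward pass; returns list(out, cache) when training = TRUE
net_forward <- function(net, x, training = FALSE) {
  cache <- if (training) vector("list", length(net$layers))
  a <- x
  B <- nrow(a)
  for (li in seq_along(net$layers)) {
    l <- net$layers[[li]]
    if (l$type == "conv") {
      hw <- l$side^2
      ap <- cbind(a, 0)
      pad_col <- ncol(ap)
      ii <- ifelse(l$idx == 0L, pad_col, l$idx)
      xc <- ap[, as.vector(ii), drop = FALSE]
      dim(xc) <- c(B * hw, ncol(l$idx))
      z <- xc %*% l$w
      z <- sweep_add(z, l$b)
      if (training) cache[[li]] <- list(xcol = xc, in_cols = ncol(a))
      dim(z) <- c(B, hw * l$filters)
      a <- z
    } else if (l$type == "relu") {
      if (training) cache[[li]] <- a > 0
      a <- pmax(a, 0)
    } else if (l$type == "pool") {
      hw_out <- l$n_out^2
      n_off <- ncol(l$idx)
      best <- matrix(-Inf, B, hw_out * l$chan)
      arg <- matrix(1L, B, hw_out * l$chan)
      for (o in seq_len(n_off)) {
        cols <- rep((seq_len(l$chan) - 1) * l$side^2, each = hw_out) +
          rep(l$idx[, o], l$chan)
        cand <- a[, cols, drop = FALSE]
        upd <- cand > best
        best[upd] <- cand[upd]
        arg[upd] <- o
      }
      if (training) cache[[li]] <- list(arg = arg, in_cols = ncol(a))
      a <- best
    } else if (l$type == "dense") {
      if (training) cache[[li]] <- a
      a <- sweep_add(a %*% l$w, l$b)
    }
  }
  if (training) list(out = a, cache = cache) else a
}

sweep_add <- function(m, b) {
  m + rep(b, each = nrow(m))
}

## backward pass; returns gradients per layer
net_backward <- function(net, cache, dout, B) {
  grads <- vector("list", length(net$layers))
  g <- dout
  for (li in rev(seq_along(net$layers))) {
    l <- net$layers[[li]]
    if (l$type == "dense") {
      a_in <- cache[[li]]
      grads[[li]] <- list(dw = crossprod(a_in, g), db = colSums(g))
      g <- g %*% t(l$w)
    } else if (l$type == "relu") {
      g <- g * cache[[li]]
    } else if (l$type == "pool") {
      hw_out <- l$n_out^2
      arg <- cache[[li]]$arg
      gin <- matrix(0, B, cache[[li]]$in_cols)
      for (o in seq_len(ncol(l$idx))) {
        sel <- arg == o
        if (!any(sel)) next
        cols <- rep((seq_len(l$chan) - 1) * l$side^2, each = hw_out) +
          rep(l$idx[, o], l$chan)
        tgt <- gin[, cols, drop = FALSE]
        tgt[sel] <- tgt[sel] + g[sel]
        gin[, cols] <- tgt
      }
      g <- gin
    } else if (l$type == "conv") {
      hw <- l$side^2
      gm <- g
      dim(gm) <- c(B * hw, l$filters)
      xc <- cache[[li]]$xcol
      grads[[li]] <- list(dw = crossprod(xc, gm), db = colSums(gm))
      dxc <- gm %*% t(l$w)
      gin <- matrix(0, B, cache[[li]]$in_cols)
      for (j in seq_len(ncol(l$idx))) {
        src <- l$idx[, j]
        ok <- src > 0L
        if (!any(ok)) next
        contrib <- matrix(dxc[, j], B, hw)
        gin[, src[ok]] <- gin[, src[ok]] + contrib[, ok, drop = FALSE]
      }
      g <- gin
    }
  }
  grads
}

## ---- loss -----------------------------------------------------------------

#' Circular regression loss for the heading azimuth
#'
#' On the normalized label scale (a full circle spans 1), the loss for a
#' prediction error `e = y - yhat` is `(1 - cos(2 pi e)) / 2`: zero at
#' zero error and at full-circle offsets, and maximal (1) at a
#' half-circle (180 degree) error.  Errors that differ by whole turns
#' are not penalized.
#'
#' @param y,yhat Normalized azimuth labels and predictions.
#' @return Mean loss (scalar).
#' @examples
#' circular_loss(0.5, 0)   # 180 deg error -> 1
#' circular_loss(1, 0)     # 360 deg error -> 0
#' @export
circular_loss <- function(y, yhat) {
  mean((1 - cos(2 * pi * (y - yhat))) / 2)
}

## total task loss and output gradient on normalized labels
task_loss <- function(y, yhat) {
  e1 <- y[, 1] - yhat[, 1]
  l <- circular_loss(y[, 1], yhat[, 1]) +
    sum(colMeans((y[, -1, drop = FALSE] - yhat[, -1, drop = FALSE])^2))
  B <- nrow(y)
  g <- matrix(0, B, 5)
  g[, 1] <- -pi * sin(2 * pi * e1) / B
  g[, -1] <- -2 * (y[, -1, drop = FALSE] - yhat[, -1, drop = FALSE]) / B
  list(loss = l, grad = g)
}

## ---- label normalization --------------------------------------------------

label_spans <- c(t_azimuth = 360, t_elevation = 180,
                 r_pitch = 20, r_yaw = 20, r_roll = 20)

#' Normalize / denormalize self-motion labels
#'
#' Each label is scaled by its full range so that it spans
#' `[-0.5, 0.5]`: azimuth by 360 deg, elevation by 180 deg, the three
#' rotation rates by 20 deg/s.  `denormalize_labels()` inverts the
#' scaling and wraps azimuth back to `[-180, 180)`.
#'
#' @param y `n x 5` label matrix.
#' @return Matrix of the same shape.
#' @export
normalize_labels <- function(y) {
  sweep(y, 2, label_spans, "/")
}

#' @rdname normalize_labels
#' @export
denormalize_labels <- function(y) {
  out <- sweep(y, 2, label_spans, "*")
  out[, 1] <- wrap_angle(out[, 1])
  colnames(out) <- names(label_spans)
  out
}

## ---- training -------------------------------------------------------------

net_input <- function(net, dataset) {
  if (inherits(dataset, "flow_dataset")) {
    if (net$spec$input == "mt") unclass(mt_activations(dataset))
    else cbind(dataset$u, dataset$v)
  } else as.matrix(dataset)
}

#' Train a network on an optic-flow dataset
#'
#' Minimizes the joint loss over the five self-motion outputs — the
#' circular loss for translation azimuth plus squared error for the
#' other four — with mini-batch Adam.  Labels are normalized to
#' `[-0.5, 0.5]` per label.  Early stopping monitors the validation
#' loss with the given patience and restores the earliest best weights.
#' With the non-negative constraint, constrained layers are projected to
#' `>= 0` after every update.  Training is deterministic given `seed`.
#'
#' @param net A [build_network()] result.
#' @param dataset A [flow_dataset()] with `"train"`/`"validation"`
#'   split tags, or a list with `x_train`, `y_train`, `x_val`, `y_val`
#'   (labels unnormalized).
#' @param epochs Maximum epochs.
#' @param batch_size Mini-batch size. Default 64.
#' @param learning_rate Adam step size.
#' @param patience Early-stopping patience in epochs.
#' @param seed Integer RNG seed for batch shuffling.
#' @param verbose Print per-epoch losses.
#' @return The trained `"flownet"`, with `history` (data frame of
#'   training and validation loss per epoch) and `best_epoch`.
#' @export
train_network <- function(net, dataset, epochs = 30, batch_size = 64,
                          learning_rate = 1e-3, patience = 60,
                          seed = 1, verbose = FALSE) {
  stopifnot(inherits(net, "flownet"))
  if (inherits(dataset, "flow_dataset")) {
    tr <- dataset["train"]; va <- dataset["validation"]
    x_tr <- net_input(net, tr); y_tr <- normalize_labels(tr$labels)
    x_va <- net_input(net, va); y_va <- normalize_labels(va$labels)
  } else {
    x_tr <- as.matrix(dataset$x_train); y_tr <- normalize_labels(dataset$y_train)
    x_va <- as.matrix(dataset$x_val);  y_va <- normalize_labels(dataset$y_val)
  }
  n <- nrow(x_tr)
  adam <- init_adam(net)
  set.seed(seed)
  best_loss <- Inf; best_layers <- NULL; best_epoch <- 0L; wait <- 0L
  hist <- data.frame(epoch = integer(0), train = numeric(0), val = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tr_loss <- 0; nb <- 0
    for (s in seq(1, n, by = batch_size)) {
      ib <- ord[s:min(s + batch_size - 1, n)]
      fw <- net_forward(net, x_tr[ib, , drop = FALSE], training = TRUE)
      tl <- task_loss(y_tr[ib, , drop = FALSE], fw$out)
      if (!is.finite(tl$loss)) stop("training diverged: non-finite loss")
      grads <- net_backward(net, fw$cache, tl$grad, length(ib))
      upd <- adam_step(net, grads, adam, learning_rate)
      net <- upd$net; adam <- upd$adam
      tr_loss <- tr_loss + tl$loss; nb <- nb + 1
    }
    val_out <- net_forward(net, x_va)
    vl <- task_loss(y_va, val_out)$loss
    hist <- rbind(hist, data.frame(epoch = ep, train = tr_loss / nb, val = vl))
    if (verbose) message(sprintf("epoch %d: train %.4f val %.4f", ep, tr_loss / nb, vl))
    if (vl < best_loss) {           # strict '<': ties keep the earliest best
      best_loss <- vl; best_layers <- net$layers; best_epoch <- ep; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  net$layers <- best_layers
  net$trained <- TRUE
  net$history <- hist
  net$best_epoch <- best_epoch
  net
}

init_adam <- function(net) {
  lapply(net$layers, function(l) {
    if (is.null(l$w)) NULL
    else list(mw = l$w * 0, vw = l$w * 0, mb = l$b * 0, vb = l$b * 0, t = 0L)
  })
}

adam_step <- function(net, grads, adam, lr, b1 = 0.9, b2 = 0.999, eps = 1e-7) {
  for (li in seq_along(net$layers)) {
    l <- net$layers[[li]]
    if (is.null(l$w)) next
    g <- grads[[li]]
    if (l$l1 > 0) g$dw <- g$dw + l$l1 * sign(l$w)
    st <- adam[[li]]
    st$t <- st$t + 1L
    st$mw <- b1 * st$mw + (1 - b1) * g$dw
    st$vw <- b2 * st$vw + (1 - b2) * g$dw^2
    st$mb <- b1 * st$mb + (1 - b1) * g$db
    st$vb <- b2 * st$vb + (1 - b2) * g$db^2
    c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
    l$w <- l$w - lr * (st$mw / c1) / (sqrt(st$vw / c2) + eps)
    l$b <- l$b - lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
    if (isTRUE(l$constrained)) l$w[l$w < 0] <- 0
    net$layers[[li]] <- l
    adam[[li]] <- st
  }
  list(net = net, adam = adam)
}

#' Predict self-motion labels with a trained network
#'
#' @param object A trained `"flownet"`.
#' @param newdata A [flow_dataset()] or input matrix.
#' @param ... Unused.
#' @return `n x 5` matrix of denormalized label estimates; translation
#'   azimuth wrapped to `[-180, 180)`.
#' @export
predict.flownet <- function(object, newdata, ...) {
  x <- net_input(object, newdata)
  denormalize_labels(net_forward(object, x))
}

#' Activations of the last hidden layer
#'
#' "Lesions" the output head: runs the forward pass up to (and
#' including) the final hidden rectifier and returns those activations,
#' e.g. for fitting linear decoders to the learned representation.
#'
#' @param net A trained `"flownet"`.
#' @param newdata A [flow_dataset()] or input matrix.
#' @return `n x d` non-negative activation matrix, `d` the last dense
#'   width.
#' @export
lesioned_readout <- function(net, newdata) {
  x <- net_input(net, newdata)
  last_hidden <- max(which(vapply(net$layers, function(l) l$type == "relu", TRUE)))
  sub <- net
  sub$layers <- net$layers[seq_len(last_hidden)]
  net_forward(sub, x)
}

## ---- random hyperparameter search ----------------------------------------

#' Random search over network hyperparameters
#'
#' Samples `budget` candidate architectures uniformly from the given
#' ranges, trains each briefly, and returns the candidate with the
#' lowest validation loss (summed over the five outputs).  When the
#' winning candidate lies on the upper limit of a range the
#' corresponding name is reported in `boundary`, signalling that the
#' range should be expanded and the search restarted.
#'
#' @param dataset Training data (as in [train_network()]).
#' @param budget Number of candidates.
#' @param ranges List of sampling ranges: `conv_stacks`, `dense_layers`,
#'   `filters`, `dense_units`, `filter_size`, `pool_window`,
#'   `pool_stride` (each `c(min, max)`), `l1` (choice set) and
#'   `learning_rate` (choice set).
#' @param epochs Training epochs per candidate.
#' @param nonneg,input Passed to [flownet_spec()].
#' @param seed Integer RNG seed.
#' @return List with `spec` (best [flownet_spec()]), `learning_rate`,
#'   `val_loss`, `boundary` (character vector of ranges hit at the upper
#'   limit), and `candidates` (data frame of all sampled candidates).
#' @export
hyperparameter_search <- function(dataset, budget = 5,
                                  ranges = list(
                                    conv_stacks = c(1, 3),
                                    dense_layers = c(1, 6),
                                    filters = c(2, 300),
                                    dense_units = c(2, 10000),
                                    filter_size = c(2, 15),
                                    pool_window = c(2, 4),
                                    pool_stride = c(1, 3),
                                    l1 = c(0, 1e-5, 1e-4, 1e-3, 1e-2, 1e-1, 1, 2),
                                    learning_rate = c(1e-5, 1e-4, 1e-3, 1e-2)),
                                  epochs = 3, nonneg = FALSE,
                                  input = "flow", seed = 1) {
  stopifnot(budget >= 1)
  set.seed(seed)
  ri <- function(r) sample(r[1]:r[2], 1)
  best <- NULL
  cand <- list()
  for (i in seq_len(budget)) {
    n_conv <- if (input == "mt") 0 else ri(ranges$conv_stacks)
    conv <- list()
    side <- 15
    for (s in seq_len(n_conv)) {
      pw <- ri(ranges$pool_window); ps <- ri(ranges$pool_stride)
      if (side < pw) break
      conv[[length(conv) + 1]] <- list(filters = ri(ranges$filters),
                                       size = min(ri(ranges$filter_size), side),
                                       pool_window = pw, pool_stride = ps)
      side <- (side - pw) %/% ps + 1
    }
    nd <- ri(ranges$dense_layers)
    dense <- replicate(nd, ri(ranges$dense_units))
    l1 <- sample(ranges$l1, length(conv) + nd + 1, replace = TRUE)
    lr <- sample(ranges$learning_rate, 1)
    spec <- flownet_spec(conv = conv, dense = dense, l1 = l1,
                         nonneg = nonneg, input = input)
    net <- build_network(spec, seed = seed + i)
    net <- train_network(net, dataset, epochs = epochs,
                         learning_rate = lr, seed = seed + i)
    vl <- min(net$history$val)
    cand[[i]] <- data.frame(candidate = i, conv_stacks = length(conv),
                            dense_layers = nd, learning_rate = lr,
                            val_loss = vl)
    if (is.null(best) || vl < best$val_loss) {
      best <- list(spec = spec, learning_rate = lr, val_loss = vl)
    }
  }
  boundary <- character(0)
  if (length(best$spec$conv) > 0) {
    fl <- vapply(best$spec$conv, `[[`, 0, "filters")
    if (any(fl == ranges$filters[2])) boundary <- c(boundary, "filters")
    if (length(best$spec$conv) == ranges$conv_stacks[2]) boundary <- c(boundary, "conv_stacks")
  }
  if (any(best$spec$dense == ranges$dense_units[2])) boundary <- c(boundary, "dense_units")
  if (length(best$spec$dense) == ranges$dense_layers[2]) boundary <- c(boundary, "dense_layers")
  best$boundary <- boundary
  best$candidates <- do.call(rbind, cand)
  best
}

#' Published network architectures
#'
#' The six accuracy-optimized architectures (conv/pool geometry, dense
#' widths, per-layer L1 strengths, weight constraints and learning
#' rates) found by the two-stage random search, as full-replication
#' configurations, plus reduced desk-scale counterparts (`scale =
#' "desk"`, dense widths capped at 512) for CPU-sized runs.
#'
#' @param model One of `"CNN"`, `"MLP"`, `"MLP_MT_PRE"`, `"CNN_L1"`,
#'   `"CNN_++"`, `"CNN_L1++"`.
#' @param scale `"full"` or `"desk"`.
#' @return List with `spec` ([flownet_spec()]) and `learning_rate`.
#' @export
published_architecture <- function(model = c("CNN", "MLP", "MLP_MT_PRE",
                                             "CNN_L1", "CNN_++", "CNN_L1++"),
                                   scale = c("full", "desk")) {
  model <- match.arg(model)
  scale <- match.arg(scale)
  full <- list(
    "CNN" = list(conv = list(list(filters = 157, size = 2, pool_window = 2, pool_stride = 3)),
                 dense = c(2997, 7566, 5979, 6709, 2631), l1 = 0, nonneg = FALSE,
                 input = "flow", lr = 1e-3),
    "MLP" = list(conv = list(), dense = c(2958, 6244, 3234, 5067, 2651),
                 l1 = 0, nonneg = FALSE, input = "flow", lr = 1e-3),
    "MLP_MT_PRE" = list(conv = list(), dense = c(3536, 2367, 141, 5108, 408),
                        l1 = 0, nonneg = FALSE, input = "mt", lr = 1e-3),
    "CNN_L1" = list(conv = list(list(filters = 188, size = 2, pool_window = 4, pool_stride = 1)),
                    dense = c(5484, 7352, 9770),
                    l1 = c(1e-5, 0, 1e-5, 1e-3, 0), nonneg = FALSE,
                    input = "flow", lr = 1e-4),
    "CNN_++" = list(conv = list(list(filters = 162, size = 2, pool_window = 2, pool_stride = 1)),
                    dense = c(3145, 2529), l1 = 0, nonneg = TRUE,
                    input = "flow", lr = 1e-3),
    "CNN_L1++" = list(conv = list(list(filters = 103, size = 2, pool_window = 2, pool_stride = 2)),
                      dense = c(7281, 5741), l1 = c(0, 1e-4, 1e-5, 1e-3),
                      nonneg = TRUE, input = "flow", lr = 1e-3))
  cfg <- full[[model]]
  if (scale == "desk") {
    ## reduced configs: Table-geometry conv stack with capped filter counts,
    ## dense stack truncated to two capped layers
    cfg$dense <- pmin(cfg$dense[seq_len(min(2, length(cfg$dense)))], c(256L, 128L))
    cfg$l1 <- cfg$l1[seq_len(min(length(cfg$l1), length(cfg$conv) + length(cfg$dense) + 1))]
    if (length(cfg$conv)) {
      ## filter cap is tighter for unit-stride pooling, whose feature maps
      ## (and hence the first dense layer) would otherwise dominate runtime
      cfg$conv <- lapply(cfg$conv, function(st) {
        st$filters <- min(st$filters, if (st$pool_stride == 1) 32L else 64L)
        st
      })
    }
  }
  list(spec = flownet_spec(conv = cfg$conv, dense = cfg$dense, l1 = cfg$l1,
                           nonneg = cfg$nonneg, input = cfg$input),
       learning_rate = cfg$lr)
}
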