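test_that("Glorot bounds are symmetric and the non-negative variant folds them", {
  expect_equal(sqrt(6 / (3 + 3)), 1)           # F_in = F_out = 3 -> bound 1
  set.seed(41)
  w <- glorot_init(3, 3, n = 1e5)
  expect_true(all(abs(w) <= 1))
  expect_gt(max(w), 0.99)                       # draws fill the range
  expect_lt(min(w), -0.99)
  wn <- glorot_init(3, 3, n = 1e4, nonneg = TRUE)
  expect_true(all(wn >= 0 & wn <= 1))
})

test_that("circular loss is 0 at 0/360 degree errors and 1 at 180", {
  ## normalized scale: a full circle spans 1
  expect_equal(circular_loss(0.2, 0.2), 0)
  expect_equal(circular_loss(0.5, 0), 1)        # 180 deg error
  expect_equal(circular_loss(1, 0), 0, tolerance = 1e-12)  # 360 deg offset
  expect_equal(circular_loss(0.25, 0), 0.5)     # 90 deg error
})

test_that("published architectures build with the stated geometry", {
  cnn <- published_architecture("CNN", "full")
  expect_length(cnn$spec$conv, 1)
  expect_equal(cnn$spec$conv[[1]]$filters, 157)
  expect_equal(cnn$spec$conv[[1]]$size, 2)
  expect_equal(cnn$spec$dense, c(2997, 7566, 5979, 6709, 2631))
  mlp <- published_architecture("MLP", "full")
  expect_length(mlp$spec$conv, 0)
  desk <- published_architecture("CNN", "desk")
  expect_true(all(desk$spec$dense <= 512))
})

test_that("parameter count of a toy network matches the hand count", {
  spec <- flownet_spec(conv = list(list(filters = 4, size = 2,
                                        pool_window = 2, pool_stride = 2)),
                       dense = c(10))
  net <- build_network(spec, seed = 1)
  ## conv: 2*2*2*4 + 4; pool out 7x7x4 = 196; dense: 196*10 + 10; head: 10*5 + 5
  expect_equal(n_parameters(net), (2 * 2 * 2 * 4 + 4) + (196 * 10 + 10) + (10 * 5 + 5))
})

test_that("backpropagation matches numeric gradients", {
  set.seed(42)
  x <- matrix(runif(6 * 450, -1, 1), 6)
  y <- matrix(runif(30, -0.4, 0.4), 6)
  for (spec in list(flownet_spec(dense = c(8, 6)),
                    flownet_spec(conv = list(list(filters = 3, size = 3,
                                                  pool_window = 2, pool_stride = 2)),
                                 dense = c(7)))) {
    net <- build_network(spec, seed = 2)
    fw <- mstdflow:::net_forward(net, x, training = TRUE)
    tl <- mstdflow:::task_loss(y, fw$out)
    gr <- mstdflow:::net_backward(net, fw$cache, tl$grad, nrow(x))
    for (li in which(!vapply(gr, is.null, TRUE))) {
      for (i in sample(length(net$layers[[li]]$w), 3)) {
        eps <- 1e-6
        net2 <- net
        net2$layers[[li]]$w[i] <- net$layers[[li]]$w[i] + eps
        lp <- mstdflow:::task_loss(y, mstdflow:::net_forward(net2, x))$loss
        net2$layers[[li]]$w[i] <- net$layers[[li]]$w[i] - eps
        lm <- mstdflow:::task_loss(y, mstdflow:::net_forward(net2, x))$loss
        expect_equal(gr[[li]]$dw[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
      }
    }
  }
})

test_that("training learns a realizable linear problem and is seed-deterministic", {
  set.seed(43)
  n <- 400
  x <- matrix(runif(n * 450, -1, 1), n)
  B <- matrix(rnorm(450 * 5, 0, 1 / sqrt(450)), 450)
  y <- denormalize_labels(x %*% B * 0.2)
  dsn <- list(x_train = x[1:320, ], y_train = y[1:320, ],
              x_val = x[321:400, ], y_val = y[321:400, ])
  net <- build_network(flownet_spec(dense = c(32)), seed = 3)
  tr1 <- train_network(net, dsn, epochs = 80, learning_rate = 1e-2, seed = 4)
  expect_lt(min(tr1$history$val), 0.5 * tr1$history$val[1])
  tr2 <- train_network(build_network(flownet_spec(dense = c(32)), seed = 3),
                       dsn, epochs = 80, learning_rate = 1e-2, seed = 4)
  expect_identical(tr1$history, tr2$history)     # deterministic given seeds
  pr <- predict(tr1, x[321:400, ])
  expect_true(all(is.finite(pr)))
  expect_true(all(pr[, 1] >= -180 & pr[, 1] < 180))
})

test_that("the non-negative constraint holds after training, with exemptions", {
  set.seed(44)
  x <- matrix(runif(200 * 450, -1, 1), 200)
  y <- denormalize_labels(matrix(runif(200 * 5, -0.3, 0.3), 200))
  dsn <- list(x_train = x[1:160, ], y_train = y[1:160, ],
              x_val = x[161:200, ], y_val = y[161:200, ])
  spec <- flownet_spec(dense = c(12, 9, 7), nonneg = TRUE)
  net <- train_network(build_network(spec, seed = 5), dsn, epochs = 5, seed = 6)
  wl <- Filter(function(l) !is.null(l$w), net$layers)
  expect_false(wl[[1]]$constrained)              # first hidden layer exempt
  expect_false(wl[[length(wl)]]$constrained)     # output layer exempt
  expect_true(wl[[2]]$constrained && wl[[3]]$constrained)
  expect_true(all(wl[[2]]$w >= 0) && all(wl[[3]]$w >= 0))
})

test_that("L1 regularization produces at least as many near-zero weights", {
  set.seed(45)
  x <- matrix(runif(200 * 450, -1, 1), 200)
  y <- denormalize_labels(matrix(runif(200 * 5, -0.3, 0.3), 200))
  dsn <- list(x_train = x[1:160, ], y_train = y[1:160, ],
              x_val = x[161:200, ], y_val = y[161:200, ])
  nz <- sapply(c(0, 1e-2), function(l1) {
    spec <- flownet_spec(dense = c(16), l1 = l1)
    net <- train_network(build_network(spec, seed = 7), dsn, epochs = 12, seed = 8)
    sum(abs(net$layers[[1]]$w) < 1e-4)
  })
  expect_gte(nz[2], nz[1])
})

test_that("the lesioned readout equals the truncated forward pass and is non-negative", {
  ds <- tiny_tr360()
  spec <- flownet_spec(conv = list(list(filters = 4, size = 2,
                                        pool_window = 2, pool_stride = 2)),
                       dense = c(11, 6))
  net <- train_network(build_network(spec, seed = 9), ds, epochs = 2, seed = 10)
  act <- lesioned_readout(net, ds["test"])
  expect_equal(ncol(act), 6)                     # last dense width
  expect_true(all(act >= 0))
  ## oracle: manual forward through all but the output layer
  x <- cbind(ds["test"]$u, ds["test"]$v)
  sub <- net; sub$layers <- net$layers[seq_len(length(net$layers) - 1)]
  expect_equal(act, mstdflow:::net_forward(sub, x))
})

test_that("random search returns in-range specs and flags boundary optima", {
  ds <- tiny_tr360()
  small_ranges <- list(conv_stacks = c(1, 2), dense_layers = c(1, 3),
                       filters = c(2, 12), dense_units = c(2, 48),
                       filter_size = c(2, 5), pool_window = c(2, 4),
                       pool_stride = c(1, 3),
                       l1 = c(0, 1e-4), learning_rate = c(1e-4, 1e-3))
  res <- hyperparameter_search(ds, budget = 2, epochs = 1, seed = 11,
                               ranges = small_ranges)
  expect_s3_class(res$spec, "flownet_spec")
  expect_equal(nrow(res$candidates), 2)
  expect_true(all(res$spec$dense >= 2 & res$spec$dense <= 48))
  if (length(res$spec$conv)) {
    expect_true(all(vapply(res$spec$conv, `[[`, 0, "filters") <= 12))
  }
  ## rigged ranges: the only admissible dense width is the upper limit
  res2 <- hyperparameter_search(ds, budget = 1, epochs = 1, seed = 12,
                                ranges = list(conv_stacks = c(0, 0),
                                              dense_layers = c(1, 1),
                                              filters = c(2, 2),
                                              dense_units = c(4, 4),
                                              filter_size = c(2, 2),
                                              pool_window = c(2, 2),
                                              pool_stride = c(1, 1),
                                              l1 = 0, learning_rate = 1e-3))
  expect_true("dense_units" %in% res2$boundary)
})
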