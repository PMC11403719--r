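test_that("factor initialization is bounded, seeded, and zero for zero input", {
  a <- matrix(runif(200), 20, 10)
  f1 <- nnmf_init(20, 10, 4, a, seed = 5)
  f2 <- nnmf_init(20, 10, 4, a, seed = 5)
  expect_identical(f1, f2)
  b <- sqrt(mean(a) / 4)
  expect_true(all(f1$h >= 0 & f1$h <= b))
  expect_true(all(f1$w >= 0 & f1$w <= b))
  f0 <- nnmf_init(20, 10, 4, matrix(0, 20, 10))
  expect_true(all(f0$h == 0) && all(f0$w == 0))
})

test_that("an exact rank-1 non-negative factorization is recovered by all fitters", {
  set.seed(31)
  h <- matrix(runif(30, 0.2, 1), 30)
  w <- matrix(runif(50, 0.2, 1), 1)
  a <- h %*% w
  for (alg in c("mu", "als", "adam")) {
    fit <- nnmf_fit(a, k = 1, algorithm = alg, tol = 1e-9,
                    max_iter = if (alg == "adam") 2000 else 1000, seed = 2)
    expect_lt(fit$loss[fit$iterations], 1e-4)
    expect_true(all(fit$h >= 0) && all(fit$w >= 0))
  }
})

test_that("a zero matrix yields a zero factorization at zero loss", {
  fit <- nnmf_fit(matrix(0, 10, 8), k = 2, max_iter = 25)
  expect_equal(fit$loss[fit$iterations], 0)
  expect_true(all(fit$h == 0) && all(fit$w == 0))
})

test_that("fitting decreases the reconstruction loss below its initial value", {
  set.seed(32)
  a <- matrix(runif(100 * 200), 100, 200)
  init <- nnmf_init(100, 200, 8, a, seed = 3)
  init_loss <- mean((init$h %*% init$w - a)^2)
  for (alg in c("mu", "als", "adam")) {
    fit <- nnmf_fit(a, k = 8, algorithm = alg, seed = 3, max_iter = 60)
    expect_lt(fit$loss[fit$iterations], init_loss)
    expect_true(all(fit$h >= 0) && all(fit$w >= 0))
  }
})

test_that("multiplicative-update loss trace is monotone non-increasing", {
  set.seed(33)
  a <- matrix(runif(60 * 80), 60, 80)
  fit <- nnmf_fit(a, k = 5, algorithm = "mu", tol = 0, max_iter = 80)
  expect_true(all(diff(fit$loss) <= 1e-10))
})

test_that("the three fitters agree on an easy low-rank problem", {
  set.seed(34)
  h <- matrix(runif(40 * 3), 40); w <- matrix(runif(3 * 60), 3)
  a <- h %*% w
  loss <- sapply(c("mu", "als"), function(alg) {
    f <- nnmf_fit(a, k = 3, algorithm = alg, tol = 1e-10, max_iter = 2000, seed = 4)
    f$loss[f$iterations]
  })
  expect_true(all(loss < 1e-4))
})

test_that("negative or non-finite input is rejected", {
  expect_error(nnmf_fit(matrix(-1, 3, 3), k = 1), "non-negative")
  expect_error(nnmf_fit(matrix(c(1, NA, 1, 1), 2), k = 1), "non-negative")
})

test_that("the population model concatenates independent fits", {
  set.seed(35)
  a <- matrix(runif(50 * 40), 50, 40)
  mod <- mstd_nnmf(a, k = 4, repeats = 2, max_iter = 40, seed = 9)
  expect_s3_class(mod, "mstd_nnmf")
  expect_equal(dim(mod$w), c(8, 40))
  expect_equal(dim(mod$h), c(50, 8))
  expect_equal(mod$fit_index, rep(1:2, each = 4))
  ## different repeats start from different seeds, so units differ
  expect_false(isTRUE(all.equal(mod$w[1:4, ], mod$w[5:8, ])))
  ## methods
  expect_equal(coef(mod), mod$w)
  expect_equal(dim(fitted(mod, fit = 2)), c(50, 40))
  expect_equal(residuals(mod, a, fit = 1), a - fitted(mod, fit = 1))
  s <- summary(mod)
  expect_length(s$final_loss, 2)
})

test_that("novel-stimulus responses equal A_test W^T and its brute force", {
  set.seed(36)
  a <- matrix(runif(30 * 25), 30, 25)
  mod <- mstd_nnmf(a, k = 3, repeats = 2, max_iter = 30, seed = 2)
  a_test <- matrix(runif(3 * 25), 3, 25)
  h_test <- mstd_responses(mod, a_test)
  expect_true(all(h_test >= 0))
  expect_equal(dim(h_test), c(3, 6))
  brute <- matrix(0, 3, 6)
  for (i in 1:3) for (k in 1:6) brute[i, k] <- sum(a_test[i, ] * mod$w[k, ])
  expect_equal(h_test, brute, tolerance = 1e-12)
  ## zero stimuli give zero responses; a basis-vector stimulus returns |w_k|^2
  expect_true(all(mstd_responses(mod, matrix(0, 2, 25)) == 0))
  expect_equal(mstd_responses(mod, mod$w[4, , drop = FALSE])[1, 4],
               sum(mod$w[4, ]^2))
  expect_error(mstd_responses(mod, matrix(1, 2, 11)), "mismatch")
})

test_that("prediction accepts a flow dataset and routes through MT activations", {
  ds <- tiny_tr360()[1:4]
  a <- unclass(mt_activations(ds))
  mod <- mstd_nnmf(a, k = 2, repeats = 1, max_iter = 25, seed = 5)
  expect_equal(predict(mod, ds), mstd_responses(mod, a))
})
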