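## Shared fixtures, built once per test run and cached.
## Heavier objects (full datasets, MT activations, fitted populations) are
## memoised here so that structural, decoding and tuning tests can share them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

## small TR360-style dataset (540 samples) for fast unit tests
tiny_tr360 <- function() {
  fixture("tiny_tr360", function() {
    make_tr360(seed = 42, n_frontoparallel = 450, n_ground = 90)
  })
}

## the deterministic diagnostic protocols and their MT activations
protocol_t <- function() fixture("protocol_t", function() make_test_protocol("T"))
protocol_r <- function() fixture("protocol_r", function() make_test_protocol("R"))
protocol_dirs <- function() {
  fixture("protocol_dirs", function() protocol_t()$meta$directions)
}
protocol_mt_t <- function() fixture("protocol_mt_t", function() mt_activations(protocol_t()))
protocol_mt_r <- function() fixture("protocol_mt_r", function() mt_activations(protocol_r()))

## full-size TR360 and its MT activations (shared by the acceptance tests)
full_tr360 <- function() fixture("full_tr360", function() make_tr360(seed = 7))

## heavy shared products of the full-size MT activations: the desk-scale
## NNMF population (full 14 x 64 architecture, fitted to a subsample of
## the training split — tuning statistics are stable in the subsample
## size), its responses to the TR360 train/test splits, the PCA-64
## scores, and the unresponsive census on test stimuli.  The two large
## MT matrices (6,030 x 9,000 and 3,015 x 9,000) are released once these
## products exist, which keeps the suite's resident footprint modest.
heavy_products <- function() {
  fixture("heavy_products", function() {
    ds <- full_tr360()
    mt_tr <- unclass(mt_activations(ds["train"]))
    set.seed(123)
    idx <- sample(nrow(mt_tr), 1250)
    mod <- mstd_nnmf(mt_tr[idx, ], k = 64, repeats = 14, seed = 1000)
    h_tr <- mstd_responses(mod, mt_tr)
    pca <- pca_baseline(mt_tr, n_components = 64)
    rot <- pca$rotation; ctr <- pca$center
    pca_tr <- pca$train
    rm(pca); gc()
    mt_te <- unclass(mt_activations(ds["test"]))
    h_te <- mstd_responses(mod, mt_te)
    pca_te <- mt_te %*% rot - rep(drop(crossprod(ctr, rot)), each = nrow(mt_te))
    unresp_te <- exclude_unresponsive(h_te)$fraction_unresponsive
    rm(mt_tr, mt_te); gc()
    list(model = mod, h_train = h_tr, h_test = h_te,
         pca_train = pca_tr, pca_test = pca_te,
         unresponsive_test = unresp_te)
  })
}

desk_nnmf <- function() heavy_products()$model

## responses of that population to the diagnostic protocols
desk_nnmf_resp_t <- function() {
  fixture("desk_nnmf_resp_t", function() mstd_responses(desk_nnmf(), protocol_mt_t()))
}
desk_nnmf_resp_r <- function() {
  fixture("desk_nnmf_resp_r", function() mstd_responses(desk_nnmf(), protocol_mt_r()))
}

## desk-scale trained networks (reduced CNN and CNN_++), shared between
## the decoding-pattern and network-accuracy tests
## desk networks train at learning rate 1.5e-3 (selected by a small sweep
## over the reduced configurations; the published rates belong to the
## full-size networks)
desk_cnn <- function() {
  fixture("desk_cnn", function() {
    cfg <- published_architecture("CNN", "desk")
    net <- build_network(cfg$spec, seed = 21)
    train_network(net, full_tr360(), epochs = 30,
                  learning_rate = 1.5e-3, seed = 22)
  })
}
desk_cnn_pp <- function() {
  fixture("desk_cnn_pp", function() {
    cfg <- published_architecture("CNN_++", "desk")
    net <- build_network(cfg$spec, seed = 23)
    train_network(net, full_tr360(), epochs = 30,
                  learning_rate = 1.5e-3, seed = 24)
  })
}

## brute-force MT activation oracle: explicit loop over every unit
mt_oracle <- function(ds, params = mt_params()) {
  cam <- ds$camera
  tab <- mt_unit_table(params, cam)
  n <- nrow(ds$u)
  a <- matrix(0, n, nrow(tab))
  deg <- (180 / pi) / cam$focal_length
  for (j in seq_len(nrow(tab))) {
    p <- tab$grid_index[j]
    u <- ds$u[, p]; v <- ds$v[, p]
    th <- atan2(v, u) * 180 / pi
    nu <- deg * sqrt(u^2 + v^2)
    a[, j] <- direction_tuning(th, tab$pref_direction[j], params) *
      speed_tuning(nu, tab$pref_speed[j], params)
  }
  a
}
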