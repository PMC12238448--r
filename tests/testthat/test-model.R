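tiny_cfg <- function(seed = 1, ...) {
  gvt_config(blocks = 2, hidden = 16, heads = 2, tokens = 16, pool_to = 0,
             classes = 4, image_size = 32, seed = seed, ...)
}

test_that("configuration validates and round-trips through YAML", {
  expect_error(gvt_config(hidden = 10, heads = 4), "divide")
  expect_error(gvt_config(tokens = 60), "perfect square")
  expect_error(gvt_config(pool_to = 64, tokens = 64), "smaller")
  cfg <- gvt_config(blocks = 3, hidden = 32, heads = 4, tokens = 16, pool_to = 4,
                    pool_after_block = 2, classes = 7, ablation = "dense_talking",
                    semantic_weighting = "similarity", seed = 42)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2, cfg)
})

test_that("same config and seed give identical initial parameters", {
  m1 <- build_model(tiny_cfg())
  m2 <- build_model(tiny_cfg())
  expect_identical(m1$params, m2$params)
  m3 <- build_model(tiny_cfg(seed = 2))
  expect_false(identical(m1$params, m3$params))
})

test_that("parameter report accounts for every tensor", {
  m <- build_model(gvt_config(seed = 1))
  rep_ <- m$param_report
  expect_equal(rep_$total, sum(unlist(rep_$breakdown)))
  expect_equal(rep_$total, sum(vapply(m$params, length, 1L)))
})

test_that("checkpoints round-trip to bit-identical forward passes", {
  m <- build_model(tiny_cfg())
  set.seed(7)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  logits0 <- forward_image(m, img)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path, epoch = 3L, metrics = list(eval_accuracy = 0.5))
  ck <- load_checkpoint(path)
  expect_identical(ck$model$params, m$params)
  expect_equal(ck$epoch, 3L)
  expect_identical(forward_image(ck$model, img), logits0)
})

test_that("batches are processed image-independently", {
  m <- build_model(tiny_cfg())
  set.seed(8)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  logits <- forward_image(m, list(img, img))
  expect_equal(dim(logits), c(2L, 4L))
  expect_equal(logits[1, ], logits[2, ])
  expect_true(all(is.finite(logits)))
  expect_error(forward_image(m, array(0, c(16, 16, 3))), "image_size")
})

test_that("ablation wiring: no_talking makes the relation equal the scores", {
  m <- build_model(tiny_cfg(ablation = "no_talking"))
  set.seed(9)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  tr <- forward_image(m, img, trace = TRUE)
  for (st in tr$states) expect_identical(st$relation, st$scores)
  # full model mixes, so relation differs from raw scores once gates act
  mf <- build_model(tiny_cfg())
  trf <- forward_image(mf, img, trace = TRUE)
  expect_false(identical(trf$states[[1]]$relation, trf$states[[1]]$scores))
})

test_that("ablation wiring: no_residual removes both residual paths", {
  m <- build_model(tiny_cfg(ablation = "no_residual"))
  for (nm in grep("Wv", names(m$params), value = TRUE)) {
    m$params[[nm]] <- m$params[[nm]] * 0
  }
  set.seed(10)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  logits <- forward_image(m, img)
  # with zero value weights and no residual the blocks output zero, so the
  # head sees the zero token map: logits reduce to the (zero) head bias
  expect_equal(as.vector(logits), rep(0, 4))
  m2 <- build_model(tiny_cfg())
  for (nm in grep("Wv", names(m2$params), value = TRUE)) {
    m2$params[[nm]] <- m2$params[[nm]] * 0
  }
  expect_false(all(forward_image(m2, img) == 0))
})

test_that("graph mode runs the block stack over an edge-list prior", {
  ds <- make_citation_dataset(nodes = 60, classes = 3, feature_dim = 8,
                              homophily = 0.9, mean_degree = 4, label_rate = 0.2,
                              seed = 5)
  cfg <- gvt_config(blocks = 2, hidden = 8, heads = 2, tokens = 60, pool_to = 0,
                    classes = 3, mode = "graph", feature_dim = 8, seed = 1)
  m <- build_model(cfg)
  logits <- forward_nodes(m, ds$features, ds$edges)
  expect_equal(dim(logits), c(60L, 3L))
  expect_true(all(is.finite(logits)))
  # duplicated edges binarize to the same adjacency
  logits2 <- forward_nodes(m, ds$features, rbind(ds$edges, ds$edges))
  expect_identical(logits2, logits)
  # an empty edge list leaves nodes mixing only through the self loop
  logits0 <- forward_nodes(m, ds$features, matrix(integer(), 0, 2))
  expect_true(all(is.finite(logits0)))
  expect_error(forward_nodes(m, ds$features, rbind(c(1L, 61L))), "out of range")
})

test_that("one tape block equals the composition of the exported operations", {
  cfg <- gvt_config(blocks = 1, hidden = 16, heads = 2, tokens = 16, pool_to = 0,
                    classes = 4, image_size = 32, prenorm = FALSE, seed = 6)
  m <- build_model(cfg)
  set.seed(11)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  tr <- forward_image(m, img, trace = TRUE)
  X <- embed_image(img, m)$features
  expect_equal(tr$states[[1]]$tokens_in, X, tolerance = 1e-12)

  bund <- adjacency_bundle(X, grid = c(4, 4))
  expect_equal(tr$states[[1]]$adjacency, bund$combined, tolerance = 1e-10)
  expect_equal(tr$states[[1]]$normalized, bund$normalized, tolerance = 1e-10)

  p <- m$params
  qk <- project_qk(X, bund$normalized, list(p$blk1_Wq1, p$blk1_Wq2),
                   list(p$blk1_Wk1, p$blk1_Wk2))
  S <- scaled_attention(qk$q, qk$k)
  expect_equal(tr$states[[1]]$scores, S, tolerance = 1e-10)

  F_ <- head_features(qk$q, qk$k, p$blk1_Wh)
  g <- shrinkage_gate(bilinear_pool(F_), p$blk1_Wc, as.vector(p$blk1_u))
  expect_equal(tr$states[[1]]$gates, g$Z, tolerance = 1e-10)
  R <- talk_heads(sparse_select(S, g$M), p$blk1_Phi)
  expect_equal(tr$states[[1]]$relation, R, tolerance = 1e-10)

  vc <- value_graph_conv(X, R, list(p$blk1_Wv1, p$blk1_Wv2))
  out <- vc$merged + X
  # head: final layer norm (unit affine at init), token mean pool, linear
  mu <- rowMeans(out)
  xc <- out - mu
  xhat <- xc / sqrt(rowMeans(xc^2) + 1e-5)
  logits <- matrix(colMeans(xhat), 1) %*% p$head_W
  logits <- logits + matrix(p$head_b, 1, 4)
  expect_equal(tr$logits, logits, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("200 optimizer steps halve the loss on a separable toy problem", {
  ds <- make_citation_dataset(nodes = 60, classes = 2, feature_dim = 4,
                              homophily = 0.9, mean_degree = 5, label_rate = 0.5,
                              feature_noise_sd = 0.3, seed = 2)
  cfg <- gvt_config(blocks = 2, hidden = 8, heads = 2, tokens = 60, pool_to = 0,
                    classes = 2, mode = "graph", feature_dim = 4, seed = 1)
  tc <- train_config(epochs = 200, schedule = "constant", seed = 1)
  out <- gvt_train(cfg, tc, ds)
  expect_lt(out$history$train_loss[200], 0.5 * out$history$train_loss[1])
})
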