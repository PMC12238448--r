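test_that("graph-convolutional q/k projection propagates identity and zeros", {
  set.seed(1)
  X <- matrix(rnorm(4 * 4), 4, 4)
  I4 <- diag(4)
  Wi <- list(diag(2), diag(2))
  qk <- project_qk(X, I4, Wi, Wi)
  xs <- head_split(X, 2)
  expect_equal(qk$q$per_head, xs$per_head)
  expect_equal(qk$k$per_head, xs$per_head)
  qk0 <- project_qk(matrix(0, 4, 4), sym_normalize(matrix(1, 4, 4)), Wi, Wi)
  expect_true(all(vapply(qk0$q$per_head, function(m) all(m == 0), TRUE)))
})

test_that("q/k projection matches the brute-force loop oracle", {
  for (s in 1:50) {
    set.seed(s)
    n <- sample(2:6, 1); h <- sample(1:2, 1); hd <- sample(1:3, 1)
    d <- h * hd
    X <- matrix(rnorm(n * d), n, d)
    A <- matrix(runif(n * n), n, n); A <- A + t(A)
    An <- sym_normalize(A)
    Wq <- lapply(seq_len(h), function(i) matrix(rnorm(hd * hd), hd, hd))
    Wk <- lapply(seq_len(h), function(i) matrix(rnorm(hd * hd), hd, hd))
    qk <- project_qk(X, An, Wq, Wk)
    for (i in seq_len(h)) {
      xi <- X[, ((i - 1) * hd + 1):(i * hd), drop = FALSE]
      expect_equal(qk$q$per_head[[i]], mm_loop(mm_loop(An, xi), Wq[[i]]),
                   tolerance = 1e-10)
      expect_equal(qk$k$per_head[[i]], mm_loop(mm_loop(An, xi), Wk[[i]]),
                   tolerance = 1e-10)
    }
  }
})

test_that("scaled attention rows are stochastic, with uniform rows for zero queries", {
  q0 <- rand_heads(5, 3, 2, 1)
  q0$per_head <- lapply(q0$per_head, function(m) m * 0)
  k <- rand_heads(5, 3, 2, 2)
  S <- scaled_attention(q0, k)
  expect_equal(S, array(1 / 5, c(2, 5, 5)))
  q1 <- rand_heads(1, 2, 1, 3)
  expect_equal(scaled_attention(q1, q1), array(1, c(1, 1, 1)))
  # hand evaluation at n = 2, head_dim = 2
  q <- list(per_head = list(rbind(c(1, 0), c(0, 1))), heads = 1, head_dim = 2)
  k <- list(per_head = list(rbind(c(2, 1), c(1, 3))), heads = 1, head_dim = 2)
  Lh <- rbind(c(2, 1), c(1, 3))   # q_a . k_b entrywise by hand
  manual <- matrix(0, 2, 2)
  for (a in 1:2) {
    z <- exp(Lh[a, ] / sqrt(2))
    manual[a, ] <- z / sum(z)
  }
  expect_equal(scaled_attention(q, k)[1, , ], manual, tolerance = 1e-12)
  for (s in 1:100) {
    set.seed(s)
    n <- sample(2:8, 1)
    qs <- rand_heads(n, 3, 2, s); ks <- rand_heads(n, 3, 2, s + 1000)
    Sr <- scaled_attention(qs, ks)
    for (i in 1:2) expect_equal(rowSums(Sr[i, , ]), rep(1, n), tolerance = 1e-6)
  }
})

test_that("head features stack per-head scalar projections into an h x n matrix", {
  q <- rand_heads(3, 2, 2, 7); k <- rand_heads(3, 2, 2, 8)
  z <- q; z$per_head <- lapply(z$per_head, function(m) m * 0)
  expect_equal(head_features(z, z, matrix(1, 4, 2)), matrix(0, 2, 3))
  expect_equal(head_features(q, k, matrix(0, 4, 2)), matrix(0, 2, 3))
  set.seed(9)
  Wh <- matrix(rnorm(8), 4, 2)
  F_ <- head_features(q, k, Wh)
  expect_equal(dim(F_), c(2L, 3L))
  for (i in 1:2) {
    cat_i <- cbind(q$per_head[[i]], k$per_head[[i]])
    expect_equal(F_[i, ], as.vector(mm_loop(cat_i, matrix(Wh[, i], ncol = 1))),
                 tolerance = 1e-12)
  }
  expect_error(head_features(q, k, matrix(0, 3, 2)), "head_dim")
})

test_that("bilinear pooling is a Gram matrix", {
  expect_equal(bilinear_pool(matrix(0, 2, 4)), matrix(0, 2, 2))
  Fo <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(bilinear_pool(Fo), diag(2))
  set.seed(2)
  F_ <- matrix(rnorm(6), 2, 3)
  C <- bilinear_pool(F_)
  expect_equal(C, mm_loop(F_, t(F_)), tolerance = 1e-12)
  expect_true(all(eigen(C, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
})

test_that("shrinkage gate applies the slope-scaled sigmoid and builds diagonal selection", {
  g <- shrinkage_gate(matrix(0, 2, 2), matrix(1, 2, 4), rep(1, 4))
  expect_equal(g$Z, matrix(0.5, 2, 4))
  # a unit logit with unit slope gives sigmoid(1)
  C <- diag(2)
  Wc <- matrix(0, 2, 3); Wc[1, 2] <- 1
  g2 <- shrinkage_gate(C, Wc, rep(1, 3))
  expect_equal(g2$Z[1, 2], 1 / (1 + exp(-1)))
  expect_equal(g2$Z[1, 1], 0.5)
  # M_i is diag(Z[i, ])
  for (i in 1:2) expect_equal(g2$M[i, , ], diag(g2$Z[i, ], nrow = 3))
  expect_true(all(g2$Z > 0 & g2$Z < 1))
  expect_warning(shrinkage_gate(C, Wc, c(1, 0, 1)), "slope")
})

test_that("sparse selection equals the closed form z_a z_b S_ab", {
  set.seed(4)
  S <- array(runif(2 * 4 * 4), c(2, 4, 4))
  Z <- matrix(runif(8), 2, 4)
  M <- array(0, c(2, 4, 4))
  for (i in 1:2) M[i, , ] <- diag(Z[i, ])
  expect_equal(sparse_select(S, M), o_select(S, Z), tolerance = 1e-10)
  Mi <- array(0, c(2, 4, 4)); for (i in 1:2) Mi[i, , ] <- diag(4)
  expect_equal(sparse_select(S, Mi), S)
  expect_equal(sparse_select(S, array(0, c(2, 4, 4))), array(0, c(2, 4, 4)))
})

test_that("talking-heads mixing is a linear map across the head dimension", {
  set.seed(6)
  Shat <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  expect_equal(talk_heads(Shat, diag(2)), Shat)
  R0 <- talk_heads(Shat, rbind(c(0, 0), c(1, 1)))
  expect_equal(R0[1, , ], matrix(0, 3, 3))
  Rs <- talk_heads(Shat, rbind(c(0, 1), c(1, 0)))
  expect_equal(Rs[1, , ], Shat[2, , ])
  expect_equal(Rs[2, , ], Shat[1, , ])
  for (s in 1:50) {
    set.seed(s)
    h <- sample(2:4, 1); n <- sample(2:5, 1)
    Sh <- array(rnorm(h * n * n), c(h, n, n))
    Phi <- matrix(rnorm(h * h), h, h)
    expect_equal(talk_heads(Sh, Phi), o_talk(Sh, Phi), tolerance = 1e-10)
  }
})

test_that("value graph convolution has the residual and unit-degree fixed points", {
  set.seed(8)
  X <- matrix(rnorm(3 * 4), 3, 4)
  xs <- head_split(X, 2)
  R <- array(runif(2 * 3 * 3), c(2, 3, 3))
  W0 <- list(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(value_graph_conv(X, R, W0)$merged, X)
  RI <- array(0, c(2, 3, 3)); for (i in 1:2) RI[i, , ] <- diag(3)
  WI <- list(diag(2), diag(2))
  expect_equal(value_graph_conv(X, RI, WI)$merged, 2 * X)
  for (s in 1:50) {
    set.seed(s)
    n <- sample(2:5, 1); hd <- sample(1:3, 1)
    x1 <- list(per_head = list(matrix(rnorm(n * hd), n, hd)), heads = 1, head_dim = hd)
    R1 <- array(rnorm(n * n), c(1, n, n))
    Wv <- list(matrix(rnorm(hd * hd), hd, hd))
    expect_equal(value_graph_conv(x1, R1, Wv)$merged,
                 o_value_conv(x1$per_head, R1, Wv), tolerance = 1e-10)
    expect_equal(value_graph_conv(x1, R1, Wv, symmetrize = FALSE, residual = FALSE)$merged,
                 o_value_conv(x1$per_head, R1, Wv, symmetrize = FALSE, residual = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("symmetrized relation slices are exactly symmetric so the spectral analysis applies", {
  set.seed(12)
  R <- matrix(rnorm(25), 5, 5)
  Rt <- (R + t(R)) / 2
  expect_identical(Rt, t(Rt))
  sp <- spectral_response(abs(Rt), alpha = 2)
  expect_true(all(abs(Im(sp$eigenvalues)) == 0))
})

test_that("with identity mixing and open gates the core reduces to an S-guided conv", {
  set.seed(10)
  n <- 5; h <- 2; hd <- 3
  X <- matrix(rnorm(n * h * hd), n, h * hd)
  q <- rand_heads(n, hd, h, 21); k <- rand_heads(n, hd, h, 22)
  S <- scaled_attention(q, k)
  MI <- array(0, c(h, n, n)); for (i in seq_len(h)) MI[i, , ] <- diag(n)
  R <- talk_heads(sparse_select(S, MI), diag(h))
  expect_identical(R, S)
  Wv <- lapply(seq_len(h), function(i) matrix(rnorm(hd * hd), hd, hd))
  out <- value_graph_conv(X, R, Wv, symmetrize = FALSE)
  xs <- head_split(X, h)
  for (i in seq_len(h)) {
    # rows of S_i sum to 1, so the absolute-degree rule reduces to the identity
    expect_equal(out$values[[i]], S[i, , ] %*% xs$per_head[[i]] %*% Wv[[i]] +
                   xs$per_head[[i]], tolerance = 1e-10)
  }
})

test_that("every trainable tensor receives gradient on a random batch", {
  cfg <- gvt_config(blocks = 2, hidden = 16, heads = 2, tokens = 16, pool_to = 0,
                    classes = 3, image_size = 32, seed = 4)
  m <- build_model(cfg)
  set.seed(99)
  imgs <- lapply(1:2, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  p <- lapply(m$params, gvtr:::ag_leaf)
  loss <- gvtr:::image_batch_grad(m, imgs, c(1L, 3L), p)
  gvtr:::ag_backward(loss)
  for (nm in names(p)) {
    expect_false(is.null(p[[nm]]$grad), info = nm)
    expect_true(any(p[[nm]]$grad != 0), info = nm)
  }
})
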