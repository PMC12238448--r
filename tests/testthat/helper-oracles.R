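# Independent brute-force oracles: explicit scalar loops, no matrix products,
# so they share no code path with the implementation they check.

mm_loop <- function(A, B) {
  out <- matrix(0, nrow(A), ncol(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(B))) {
      s <- 0
      for (k in seq_len(ncol(A))) s <- s + A[i, k] * B[k, j]
      out[i, j] <- s
    }
  }
  out
}

o_cosdist <- function(X, eps = 1e-12) {
  n <- nrow(X)
  out <- matrix(0, n, n)
  nrm <- numeric(n)
  for (i in seq_len(n)) nrm[i] <- max(sqrt(sum(X[i, ]^2)), eps)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) out[i, j] <- 1 - sum(X[i, ] * X[j, ]) / (nrm[i] * nrm[j])
  }
  out
}

o_softmax_rows <- function(D) {
  n <- nrow(D)
  out <- matrix(0, n, ncol(D))
  for (i in seq_len(n)) {
    z <- 0
    for (k in seq_len(ncol(D))) z <- z + exp(D[i, k] - max(D[i, ]))
    for (j in seq_len(ncol(D))) out[i, j] <- exp(D[i, j] - max(D[i, ])) / z
  }
  out
}

o_combine <- function(AI, E) {
  n <- nrow(AI)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    out[i, j] <- (AI[i, j] + (i == j)) * E[i, j]
  }
  out
}

o_symnorm <- function(A, eps = 1e-12) {
  n <- nrow(A)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- max(sum(A[i, ]), eps)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    out[i, j] <- A[i, j] / (sqrt(d[i]) * sqrt(d[j]))
  }
  out
}

o_grid_neighbors <- function(rows, cols) {
  n <- rows * cols
  out <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    ra <- (a - 1) %/% cols; ca <- (a - 1) %% cols
    rb <- (b - 1) %/% cols; cb <- (b - 1) %% cols
    if (abs(ra - rb) <= 1 && abs(ca - cb) <= 1) out[a, b] <- 1
  }
  out
}

o_select <- function(S, Z) {
  h <- dim(S)[1]; n <- dim(S)[2]
  out <- array(0, dim(S))
  for (i in seq_len(h)) for (a in seq_len(n)) for (b in seq_len(n)) {
    out[i, a, b] <- Z[i, a] * Z[i, b] * S[i, a, b]
  }
  out
}

o_talk <- function(Shat, Phi) {
  h <- dim(Shat)[1]
  out <- array(0, dim(Shat))
  for (i in seq_len(h)) for (j in seq_len(h)) {
    out[i, , ] <- out[i, , ] + Phi[i, j] * Shat[j, , ]
  }
  out
}

o_value_conv <- function(x_heads, R, Wv, symmetrize = TRUE, residual = TRUE,
                         eps = 1e-12) {
  h <- dim(R)[1]; n <- dim(R)[2]
  merged <- NULL
  for (i in seq_len(h)) {
    Ri <- R[i, , , drop = TRUE]
    if (is.null(dim(Ri))) Ri <- matrix(Ri, n, n)
    if (symmetrize) {
      Rs <- matrix(0, n, n)
      for (a in seq_len(n)) for (b in seq_len(n)) Rs[a, b] <- (Ri[a, b] + Ri[b, a]) / 2
      Ri <- Rs
    }
    d <- numeric(n)
    for (a in seq_len(n)) d[a] <- max(sum(abs(Ri[a, ])), eps)
    N <- matrix(0, n, n)
    for (a in seq_len(n)) for (b in seq_len(n)) N[a, b] <- Ri[a, b] / sqrt(d[a] * d[b])
    v <- mm_loop(mm_loop(N, x_heads[[i]]), Wv[[i]])
    if (residual) v <- v + x_heads[[i]]
    merged <- cbind(merged, v)
  }
  merged
}

o_pool_tokens <- function(X, U) {
  t_ <- nrow(U); d <- ncol(X); n <- nrow(X)
  out <- matrix(0, t_, d)
  for (a in seq_len(t_)) for (b in seq_len(d)) {
    s <- 0
    for (i in seq_len(n)) for (k in seq_len(d)) {
      s <- s + U[a, k] * X[i, k] * X[i, b]
    }
    out[a, b] <- s
  }
  out
}

o_pool_adjacency <- function(A, C) {
  t_ <- nrow(C); n <- nrow(A)
  out <- matrix(0, t_, t_)
  for (a in seq_len(t_)) for (b in seq_len(t_)) {
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) s <- s + C[a, i] * A[i, j] * C[b, j]
    out[a, b] <- s
  }
  out
}

rand_tokens <- function(n, d, seed) {
  set.seed(seed)
  matrix(rnorm(n * d), n, d)
}

rand_heads <- function(n, hd, h, seed) {
  set.seed(seed)
  list(per_head = lapply(seq_len(h), function(i) matrix(rnorm(n * hd), n, hd)),
       heads = h, head_dim = hd)
}
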