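#' Split a token matrix evenly across attention heads
#'
#' @param x `n x d` matrix; `heads` must divide `d`.
#' @return List with `per_head` (list of `n x d/h` matrices), `heads`,
#'   `head_dim`.
#' @export
head_split <- function(x, heads) {
  x <- as.matrix(x)
  d <- ncol(x)
  if (d %% heads != 0L) stop("`heads` must divide the feature dimension")
  hd <- d %/% heads
  per <- lapply(seq_len(heads), function(i) x[, ((i - 1L) * hd + 1L):(i * hd), drop = FALSE])
  list(per_head = per, heads = heads, head_dim = hd)
}

#' Graph-convolutional query/key projection
#'
#' Per head `i`, computes `x_i^{q/k} = (D^{-1/2} A D^{-1/2}) x_i W_{q/k,i}`:
#' the symmetric-normalized token adjacency aggregates neighbour features
#' before the per-head linear projection, injecting the spatial-semantic
#' inductive bias into queries and keys.
#'
#' @param tokens `n x d` token matrix.
#' @param normalized_adjacency `n x n` normalized adjacency.
#' @param weights_q,weights_k Lists of `h` per-head `(d/h) x (d/h)` matrices.
#' @return List `list(q = HeadSplit, k = HeadSplit)`.
#' @export
project_qk <- function(tokens, normalized_adjacency, weights_q, weights_k) {
  h <- length(weights_q)
  stopifnot(length(weights_k) == h)
  xs <- head_split(tokens, h)
  P <- normalized_adjacency %*% as.matrix(tokens)
  ps <- head_split(P, h)
  q <- lapply(seq_len(h), function(i) ps$per_head[[i]] %*% weights_q[[i]])
  k <- lapply(seq_len(h), function(i) ps$per_head[[i]] %*% weights_k[[i]])
  list(q = list(per_head = q, heads = h, head_dim = xs$head_dim),
       k = list(per_head = k, heads = h, head_dim = xs$head_dim))
}

#' Scaled dot-product attention scores
#'
#' `S_i = softmax(q_i k_i^T / sqrt(d/h))` row-wise, per head. The scaling uses
#' the per-head dimension (the dimension actually entering each dot product).
#'
#' @param q,k HeadSplit structures (as from [project_qk()]).
#' @return `h x n x n` array of row-stochastic score matrices.
#' @export
scaled_attention <- function(q, k) {
  h <- q$heads
  n <- nrow(q$per_head[[1]])
  S <- array(0, c(h, n, n))
  for (i in seq_len(h)) {
    logits <- tcrossprod(q$per_head[[i]], k$per_head[[i]]) / sqrt(q$head_dim)
    S[i, , ] <- edge_softmax(logits)
  }
  S
}

#' Per-head scalar features from concatenated queries and keys
#'
#' Head `i`'s concatenated `[q_i, k_i]` (an `n x 2d/h` matrix) is projected by
#' the `i`-th column of `W_h`, giving one scalar per token; the rows stack to
#' `F` of shape `h x n`. This is the feature whose Gram matrix drives the
#' talking-heads gating.
#'
#' @param q,k HeadSplit structures.
#' @param W_h `(2*head_dim) x h` matrix.
#' @return `h x n` matrix `F`.
#' @export
head_features <- function(q, k, W_h) {
  h <- q$heads
  if (!all(dim(W_h) == c(2L * q$head_dim, h))) {
    stop("`W_h` must be (2*head_dim) x heads")
  }
  n <- nrow(q$per_head[[1]])
  F_ <- matrix(0, h, n)
  for (i in seq_len(h)) {
    F_[i, ] <- as.vector(cbind(q$per_head[[i]], k$per_head[[i]]) %*% W_h[, i])
  }
  F_
}

#' Bilinear (second-order) pooling of head features
#'
#' @param F_ `h x n` matrix.
#' @return Symmetric positive semidefinite `h x h` matrix `C = F F^T`.
#' @export
bilinear_pool <- function(F_) {
  tcrossprod(as.matrix(F_))
}

#' Sigmoid shrinkage gate and diagonal selection tensor
#'
#' `Y = C W_c`, `Z = sigmoid(Y / u)` (elementwise, with the trainable slope
#' vector `u` broadcast over rows), and `M_i = diag(Z[i, ])`. The gates pick
#' out, per head, which token rows/columns of the attention tensor survive
#' sparse selection. Near-zero slope entries are floored (sign-preserving) at
#' `eps` with a warning.
#'
#' @param C `h x h` bilinear-pooled feature matrix.
#' @param W_c `h x n` projection matrix.
#' @param u Length-`n` slope vector (initialized at 1 in the model).
#' @param eps Slope magnitude floor.
#' @return List `list(Z = h x n gates, M = h x n x n diagonal tensor)`.
#' @export
shrinkage_gate <- function(C, W_c, u, eps = 1e-8) {
  C <- as.matrix(C); W_c <- as.matrix(W_c)
  h <- nrow(C); n <- ncol(W_c)
  stopifnot(ncol(C) == h, nrow(W_c) == h, length(u) == n)
  if (any(abs(u) < eps)) {
    warning("near-zero shrinkage slope(s) floored at ", eps)
    s <- ifelse(u >= 0, 1, -1)
    u <- s * pmax(abs(u), eps)
  }
  Y <- C %*% W_c
  Z <- 1 / (1 + exp(-sweep(Y, 2L, u, "/")))
  M <- array(0, c(h, n, n))
  for (i in seq_len(h)) M[i, , ] <- diag(Z[i, ], nrow = n)
  list(Y = Y, Z = Z, M = M)
}

#' Sparse selection of the attention tensor
#'
#' `S_hat_i = M_i S_i M_i`; in closed form the `(a, b)` entry is
#' `z_a * z_b * S_i[a, b]`, zeroing rows/columns whose gates are shut.
#'
#' @param S `h x n x n` score tensor.
#' @param M `h x n x n` diagonal selection tensor.
#' @return `h x n x n` selected tensor.
#' @export
sparse_select <- function(S, M) {
  h <- dim(S)[1]
  out <- S
  for (i in seq_len(h)) {
    out[i, , ] <- M[i, , ] %*% S[i, , ] %*% M[i, , ]
  }
  out
}

#' Talking-heads mixing of selected attention tensors
#'
#' `R_i = sum_j Phi[i, j] * S_hat_j`: a learned `h x h` projection across the
#' heads dimension, letting every relation matrix depend on all heads.
#'
#' @param S_hat `h x n x n` selected score tensor.
#' @param Phi `h x h` mixing matrix.
#' @return `h x n x n` relation tensor `R`.
#' @export
talk_heads <- function(S_hat, Phi) {
  d <- dim(S_hat)
  h <- d[1]; n <- d[2]
  flat <- matrix(S_hat, h, n * n)   # row i = vec(S_hat_i)
  mixed <- as.matrix(Phi) %*% flat
  array(mixed, c(h, n, n))
}

#' Relation-guided value graph convolution with residual
#'
#' Per head, `x_i^v = (D^{-1/2} R~_i D^{-1/2}) x_i W_vi + x_i`, where `R~_i`
#' is the symmetrized relation slice `(R_i + R_i^T)/2` (disable with
#' `symmetrize = FALSE`) and `D = diag(rowSums(|R~_i|))` floored at `eps` —
#' the absolute-value degree keeps the inverse square root real when the
#' mixing matrix makes row sums nonpositive. Heads are concatenated into the
#' merged output.
#'
#' @param tokens HeadSplit of the block's input tokens (or an `n x d` matrix,
#'   split by `heads = dim(R)[1]`).
#' @param R `h x n x n` relation tensor.
#' @param weights_v List of `h` per-head `(d/h) x (d/h)` matrices.
#' @param symmetrize Symmetrize relation slices first (default `TRUE`).
#' @param residual Include the `+ x_i` term (default `TRUE`).
#' @param eps Degree floor.
#' @return List `list(values = list of n x d/h, merged = n x d)`.
#' @export
value_graph_conv <- function(tokens, R, weights_v, symmetrize = TRUE,
                             residual = TRUE, eps = 1e-12) {
  h <- dim(R)[1]
  if (is.matrix(tokens)) tokens <- head_split(tokens, h)
  vals <- vector("list", h)
  for (i in seq_len(h)) {
    Ri <- R[i, , ]
    if (symmetrize) Ri <- (Ri + t(Ri)) / 2
    dg <- pmax(rowSums(abs(Ri)), eps)
    di <- 1 / sqrt(dg)
    N <- di * Ri * rep(di, each = nrow(Ri))
    xi <- tokens$per_head[[i]]
    v <- N %*% xi %*% weights_v[[i]]
    if (residual) v <- v + xi
    vals[[i]] <- v
  }
  list(values = vals, merged = do.call(cbind, vals))
}
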