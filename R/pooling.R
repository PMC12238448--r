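#' Second-order graph pooling of tokens
#'
#' Reduces `n` tokens to `t` via `X' = (U X^T) X`, a bilinear (second-order)
#' aggregation: each pooled token is a `U`-weighted combination of the feature
#' covariance structure of the inputs. Quadratic in `X` (scaling `X` by `c`
#' scales `X'` by `c^2`). The model divides the result by `n` to keep
#' activation scale stable; this function returns the raw bilinear form.
#'
#' @param X `n x d` token matrix.
#' @param U `t x d` transformation matrix.
#' @return `t x d` pooled token matrix.
#' @export
pool_tokens <- function(X, U) {
  X <- as.matrix(X); U <- as.matrix(U)
  if (ncol(U) != ncol(X)) stop("`U` must be t x d with d matching `X`")
  (U %*% t(X)) %*% X
}

#' Adjacency transform under second-order pooling
#'
#' `A' = C A C^T` with the pooling projector `C = U X^T` computed from the
#' same token matrix that was pooled. A congruence transform, so symmetry of
#' `A` is preserved.
#'
#' @param A `n x n` adjacency.
#' @param C_pool `t x n` pooling projector.
#' @return `t x t` pooled adjacency.
#' @export
pool_adjacency <- function(A, C_pool) {
  A <- as.matrix(A); C_pool <- as.matrix(C_pool)
  if (ncol(C_pool) != nrow(A) || nrow(A) != ncol(A)) {
    stop("`C_pool` must be t x n with n matching the square `A`")
  }
  C_pool %*% A %*% t(C_pool)
}

#' Spatial prior for pooled tokens
#'
#' The 8-neighbour grid prior is undefined after pooling destroys the grid.
#' Post-pooling blocks instead use the binarized support of the symmetrized
#' pooled adjacency: the `k` largest-magnitude off-diagonal entries per row,
#' symmetrized by union. This keeps the "spatial prior masked by semantic
#' weights" structure with the same sparsity budget as the grid prior.
#'
#' @param A_pooled `t x t` pooled adjacency.
#' @param k Number of neighbours kept per row (default 8).
#' @return Symmetric binary `t x t` matrix with zero diagonal.
#' @export
pooled_spatial_prior <- function(A_pooled, k = 8L) {
  A <- abs(as.matrix(A_pooled))
  A <- (A + t(A)) / 2
  diag(A) <- 0
  t_ <- nrow(A)
  out <- matrix(0, t_, t_)
  kk <- min(k, t_ - 1L)
  if (kk > 0L) {
    for (i in seq_len(t_)) {
      ord <- order(A[i, ], decreasing = TRUE)[seq_len(kk)]
      ord <- ord[A[i, ord] > 0]
      out[i, ord] <- 1
    }
  }
  pmax(out, t(out))
}
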