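#' Per-block FLOP model: standard ViT vs graph-convolutional attention
#'
#' Evaluates the leading-order per-block operation counts. A standard ViT
#' block (multi-head self-attention `4nd^2 + 2n^2 d` plus feed-forward
#' `6nd^2`) totals `10nd^2 + 2n^2 d`. The graph-attention block costs three
#' graph convolutions `3(n^2 d + nd^2)`, the attention tensor `n^2 d`, and
#' the sparse-selection modification `2n^3`, totalling `3nd^2 + 4n^2 d + 2n^3`.
#' Costs linear in `n` or `d` (the small projection matrices and the diagonal
#' gates) are omitted from the leading terms; `verbose = TRUE` itemizes the
#' omissions. At `u = (n + d)/2` with `n = d` the totals are exactly `12 u^3`
#' and `9 u^3`.
#'
#' @param n Token count (>= 1).
#' @param d Hidden size (>= 1).
#' @param verbose Also return the itemized cost decomposition.
#' @return List with `n`, `d`, `vit_flops`, `gvt_flops`, `u_mean`,
#'   `vit_coeff`, `gvt_coeff` (and `breakdown` when `verbose`).
#' @export
flop_count <- function(n, d, verbose = FALSE) {
  stopifnot(n >= 1, d >= 1)
  n <- as.numeric(n); d <- as.numeric(d)
  vit <- 10 * n * d^2 + 2 * n^2 * d
  gvt <- 3 * n * d^2 + 4 * n^2 * d + 2 * n^3
  u <- (n + d) / 2
  out <- list(n = n, d = d, vit_flops = vit, gvt_flops = gvt, u_mean = u,
              vit_coeff = vit / u^3, gvt_coeff = gvt / u^3)
  if (verbose) {
    out$breakdown <- list(
      vit = c(msa = 4 * n * d^2 + 2 * n^2 * d, ffn = 6 * n * d^2),
      gvt = c(graph_convs = 3 * (n^2 * d + n * d^2),
              attention_tensor = n^2 * d,
              sparse_selection = 2 * n^3),
      omitted = "projection matrices and diagonal gates (linear in n or d)")
  }
  out
}

#' Spectral low-pass characterization of a relation matrix
#'
#' For a symmetric nonnegative relation matrix `R`, computes
#' `R_sym = D^{-1/2} R D^{-1/2} = I - L~` with `L~` the normalized Laplacian,
#' eigendecomposes `L~`, and evaluates the frequency response
#' `p(lambda) = (1 - lambda)^alpha` of `alpha` stacked symmetric-normalized
#' graph convolutions at each eigenvalue. Eigenvalues lie in `[0, 2]`, so
#' `|p| <= 1`: the stacked convolution is a low-pass graph filter, and deeper
#' stacks suppress mid-spectrum components harder.
#'
#' @param R Symmetric nonnegative `n x n` matrix.
#' @param alpha Positive integer layer count.
#' @param eps Degree floor.
#' @return List with `eigenvalues` (ascending), `response` (`p` at each
#'   eigenvalue), `alpha`.
#' @export
spectral_response <- function(R, alpha = 1L, eps = 1e-12) {
  R <- as.matrix(R)
  if (max(abs(R - t(R))) > 1e-8) stop("`R` must be symmetric")
  if (any(R < 0)) stop("`R` must be nonnegative (rectify/symmetrize first)")
  stopifnot(alpha >= 1)
  n <- nrow(R)
  d <- pmax(rowSums(R), eps)
  di <- 1 / sqrt(d)
  Rsym <- di * R * rep(di, each = n)
  L <- diag(n) - Rsym
  L <- (L + t(L)) / 2
  lam <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  list(eigenvalues = lam, response = (1 - lam)^alpha, alpha = as.integer(alpha))
}

#' Frequency response of stacked graph convolutions
#'
#' `p(lambda) = (1 - lambda)^alpha`, the filter that `alpha` stacked
#' symmetric-normalized graph convolutions apply to graph-signal components
#' at Laplacian eigenvalue `lambda`.
#'
#' @param lambda Numeric vector of eigenvalues.
#' @param alpha Positive integer depth.
#' @return Numeric vector of responses.
#' @export
frequency_response <- function(lambda, alpha = 1L) {
  stopifnot(alpha >= 1)
  (1 - lambda)^alpha
}

#' Numeric rank of the pre-softmax attention logits per head
#'
#' The logits `q_i k_i^T` have rank at most `min(n, d/h)`; when the per-head
#' dimension falls below the token count this is the low-rank bottleneck:
#' the head cannot assign independent attention patterns to all tokens. Rank
#' is counted as singular values above `tol * sigma_max`.
#'
#' @param q,k HeadSplit structures (see [head_split()]).
#' @param tol Relative singular-value threshold.
#' @return Integer vector of per-head numeric ranks.
#' @export
attention_logit_rank <- function(q, k, tol = 1e-8) {
  h <- q$heads
  vapply(seq_len(h), function(i) {
    L <- tcrossprod(q$per_head[[i]], k$per_head[[i]])
    sv <- svd(L, nu = 0, nv = 0)$d
    if (length(sv) == 0L || max(sv) == 0) return(0L)
    sum(sv > tol * max(sv))
  }, integer(1))
}
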