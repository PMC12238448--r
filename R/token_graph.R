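#' Spatial prior adjacency of a token grid
#'
#' Builds the binary adjacency recording 8-directional (horizontal, vertical
#' and diagonal) neighborhood among tokens laid out on a `rows x cols` grid in
#' row-major order. This is the spatial prior `A_I` combined with the semantic
#' edge weights to form the token graph.
#'
#' @param rows,cols Positive integers, the grid dimensions.
#' @return A symmetric binary `n x n` matrix with zero diagonal, `n = rows*cols`.
#' @examples
#' grid_adjacency(3, 3)[5, ]  # the centre token has 8 neighbours
#' @export
grid_adjacency <- function(rows, cols) {
  if (length(rows) != 1L || length(cols) != 1L || rows < 1 || cols < 1 ||
      rows != as.integer(rows) || cols != as.integer(cols)) {
    stop("`rows` and `cols` must be positive integers")
  }
  rows <- as.integer(rows); cols <- as.integer(cols)
  n <- rows * cols
  ri <- rep(seq_len(rows), each = cols)
  ci <- rep(seq_len(cols), times = rows)
  dr <- abs(outer(ri, ri, "-"))
  dc <- abs(outer(ci, ci, "-"))
  A <- (dr <= 1L & dc <= 1L) * 1
  diag(A) <- 0
  A
}

#' Pairwise cosine distance between token features
#'
#' Computes `1 - cos(v_i, v_j)` for all token pairs. Values lie in `[0, 2]`
#' (0 for identical directions, 1 for orthogonal, 2 for anti-parallel).
#' Zero-norm tokens (e.g. from fully padded patches) are handled by flooring
#' norms at `eps`; a warning is emitted so the caller knows the distances
#' involving those tokens are degenerate but finite.
#'
#' @param tokens Numeric `n x d` matrix of token features.
#' @param eps Norm floor, default `1e-12`.
#' @return Symmetric `n x n` matrix with zero diagonal.
#' @export
cosine_distance_matrix <- function(tokens, eps = 1e-12) {
  tokens <- as.matrix(tokens)
  stopifnot(all(is.finite(tokens)))
  nrm <- sqrt(rowSums(tokens^2))
  if (any(nrm < eps)) {
    warning("zero-norm token(s) encountered; norms floored at ", eps)
    nrm <- pmax(nrm, eps)
  }
  V <- tokens / nrm
  D <- 1 - tcrossprod(V)
  D <- (D + t(D)) / 2     # kill asymmetric round-off
  diag(D) <- 0
  D
}

#' Row-wise softmax over pairwise distances
#'
#' Turns a distance matrix into row-stochastic semantic edge weights
#' `E_ij = exp(D_ij) / sum_k exp(D_ik)`. Note the softmax is taken over
#' *distances*: more dissimilar pairs receive larger weight. Rows are
#' max-shifted before exponentiation to guard against overflow.
#'
#' @param distances Finite numeric `n x n` matrix.
#' @return Row-stochastic `n x n` matrix (each row sums to 1).
#' @export
edge_softmax <- function(distances) {
  distances <- as.matrix(distances)
  stopifnot(all(is.finite(distances)))
  m <- apply(distances, 1L, max)
  ex <- exp(distances - m)
  ex / rowSums(ex)
}

#' Combine the spatial prior with semantic edge weights
#'
#' `A = (A_I + I) * E` elementwise: the semantic weights survive only on the
#' grid-neighbour support plus the diagonal (self loops).
#'
#' @param spatial Binary `n x n` spatial prior `A_I`.
#' @param semantic Nonnegative `n x n` semantic weight matrix `E`.
#' @return Nonnegative `n x n` adjacency.
#' @export
combine_adjacency <- function(spatial, semantic) {
  spatial <- as.matrix(spatial); semantic <- as.matrix(semantic)
  if (!all(dim(spatial) == dim(semantic)) || nrow(spatial) != ncol(spatial)) {
    stop("`spatial` and `semantic` must be square matrices of the same size")
  }
  (spatial + diag(nrow(spatial))) * semantic
}

#' Symmetric degree normalization of an adjacency
#'
#' Returns `D^{-1/2} A D^{-1/2}` with `D = diag(rowSums(A))`. Degrees below
#' `eps` (isolated nodes) are floored so the result stays finite.
#'
#' @param A Nonnegative `n x n` adjacency.
#' @param eps Degree floor, default `1e-12`.
#' @return `n x n` matrix; symmetric whenever `A` is symmetric.
#' @export
sym_normalize <- function(A, eps = 1e-12) {
  A <- as.matrix(A)
  if (any(A < 0)) stop("`A` must be nonnegative")
  d <- pmax(rowSums(A), eps)
  di <- 1 / sqrt(d)
  di * A * rep(di, each = nrow(A))
}

#' Build the full adjacency bundle for a token map
#'
#' Convenience constructor running the whole chain: spatial prior (supplied or
#' derived from the grid), cosine distances, semantic softmax, combination and
#' symmetric normalization.
#'
#' @param tokens `n x d` token feature matrix.
#' @param spatial Optional `n x n` binary spatial prior; if `NULL`, `grid`
#'   must be given and an 8-neighbour grid prior is built.
#' @param grid Optional `c(rows, cols)` with `rows*cols == n`.
#' @param semantic_weighting `"distance"` (default; softmax over cosine
#'   distances, the literal formulation) or `"similarity"` (softmax over
#'   negated distances, so similar pairs get larger weight).
#' @return List with elements `spatial`, `semantic`, `combined`, `degrees`,
#'   `normalized`.
#' @export
adjacency_bundle <- function(tokens, spatial = NULL, grid = NULL,
                             semantic_weighting = c("distance", "similarity")) {
  semantic_weighting <- match.arg(semantic_weighting)
  tokens <- as.matrix(tokens)
  n <- nrow(tokens)
  if (is.null(spatial)) {
    if (is.null(grid)) stop("supply either `spatial` or `grid`")
    if (prod(grid) != n) stop("grid dims must multiply to the token count")
    spatial <- grid_adjacency(grid[1], grid[2])
  }
  D <- cosine_distance_matrix(tokens)
  if (semantic_weighting == "similarity") D <- -D
  E <- edge_softmax(D)
  A <- combine_adjacency(spatial, E)
  deg <- rowSums(A)
  list(spatial = spatial, semantic = E, combined = A,
       degrees = diag(deg, nrow = n), normalized = sym_normalize(A))
}
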