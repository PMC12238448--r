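#' Model configuration
#'
#' Mirrors the architecture tuples `(blocks, hidden, heads, tokens)` used for
#' the image models, e.g. `(7, 64, 8, 64)` with pooling from 64 to 16 tokens
#' before block 5. In graph mode (node classification) the model uses the
#' configured number of blocks with no pooling and `tokens` equals the node
#' count of the target graph.
#'
#' @param blocks Number of residual blocks.
#' @param hidden Hidden size `d` (heads must divide it).
#' @param heads Attention heads `h`.
#' @param tokens Input token count `n` (a perfect square in image mode; the
#'   node count in graph mode).
#' @param pool_to Pooled token count `t` (0 disables pooling).
#' @param pool_after_block Pooling sits after this block (default 4, so
#'   pooling precedes block 5 in the default 7-block model).
#' @param classes Number of output classes.
#' @param mode `"image"` or `"graph"`.
#' @param image_size Input resolution (image mode).
#' @param in_channels Image channels (image mode) or input feature dimension
#'   (graph mode, via `feature_dim`).
#' @param feature_dim Node feature dimension (graph mode).
#' @param ablation One of `"full"`, `"no_talking"`, `"dense_talking"`,
#'   `"no_residual"`.
#' @param semantic_weighting `"distance"` (literal formulation) or
#'   `"similarity"`.
#' @param symmetrize_relation Symmetrize relation slices before the value
#'   graph convolution (default `TRUE`).
#' @param prenorm Apply per-token pre-normalization before each attention
#'   core (default `TRUE`).
#' @param seed Seed for parameter initialization.
#' @return List of class `gvt_config`.
#' @export
gvt_config <- function(blocks = 7L, hidden = 64L, heads = 8L, tokens = 64L,
                       pool_to = 16L, pool_after_block = 4L, classes = 10L,
                       mode = c("image", "graph"), image_size = 256L,
                       in_channels = 3L, feature_dim = NULL,
                       ablation = c("full", "no_talking", "dense_talking", "no_residual"),
                       semantic_weighting = c("distance", "similarity"),
                       symmetrize_relation = TRUE, prenorm = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  ablation <- match.arg(ablation)
  semantic_weighting <- match.arg(semantic_weighting)
  if (hidden %% heads != 0L) stop("`heads` must divide `hidden`")
  if (mode == "image") {
    s <- sqrt(tokens)
    if (s != floor(s)) stop("`tokens` must be a perfect square in image mode")
  }
  if (mode == "graph") pool_to <- 0L
  if (pool_to > 0L) {
    if (pool_to >= tokens) stop("`pool_to` must be smaller than `tokens`")
    if (pool_after_block >= blocks) stop("`pool_after_block` must be < `blocks`")
  }
  structure(list(blocks = as.integer(blocks), hidden = as.integer(hidden),
                 heads = as.integer(heads), tokens = as.integer(tokens),
                 pool_to = as.integer(pool_to),
                 pool_after_block = as.integer(pool_after_block),
                 classes = as.integer(classes), mode = mode,
                 image_size = as.integer(image_size),
                 in_channels = as.integer(in_channels),
                 feature_dim = if (is.null(feature_dim)) NULL else as.integer(feature_dim),
                 ablation = ablation, semantic_weighting = semantic_weighting,
                 symmetrize_relation = isTRUE(symmetrize_relation),
                 prenorm = isTRUE(prenorm), seed = as.integer(seed)),
            class = "gvt_config")
}

# Token count entering block b.
block_tokens <- function(config, b) {
  if (config$pool_to > 0L && b > config$pool_after_block) config$pool_to
  else config$tokens
}

rnorm_mat <- function(nr, nc, sd) matrix(rnorm(nr * nc, sd = sd), nr, nc)

#' Build a model from a configuration
#'
#' Initializes all parameters (seeded by `config$seed`) and reports the
#' parameter count per component. Image mode assembles: convolutional stem ->
#' pre-pool blocks -> second-order graph pooling -> post-pool blocks ->
#' mean-pool head. Graph mode: input projection -> blocks (no pooling) ->
#' per-node head, with the spatial prior taken from the input edge list.
#'
#' @param config A [gvt_config()].
#' @return List of class `gvt_model` with `config`, `params` (named list of
#'   matrices), `embed` (stem configuration, image mode), and `param_report`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "gvt_config"))
  set.seed(config$seed)
  d <- config$hidden; h <- config$heads; dh <- d %/% h
  params <- list()
  embed <- NULL
  if (config$mode == "image") {
    embed <- embedding_config(config$in_channels, d, config$tokens)
    k2 <- embed$kernel^2
    params$stem_W1 <- rnorm_mat(k2 * embed$in_channels, d,
                                sqrt(2 / (k2 * embed$in_channels)))
    params$stem_b1 <- matrix(0, 1, d)
    chg <- d %/% embed$groups
    for (gi in seq_len(embed$groups)) {
      params[[paste0("stem_W2_g", gi)]] <- rnorm_mat(k2 * chg, chg, sqrt(2 / (k2 * chg)))
    }
    params$stem_b2 <- matrix(0, 1, d)
  } else {
    if (is.null(config$feature_dim)) stop("graph mode requires `feature_dim`")
    params$in_W <- rnorm_mat(config$feature_dim, d, 0.02)
    params$in_b <- matrix(0, 1, d)
  }
  for (b in seq_len(config$blocks)) {
    nb <- block_tokens(config, b)
    pre <- paste0("blk", b, "_")
    params[[paste0(pre, "ln_g")]] <- matrix(1, 1, d)
    params[[paste0(pre, "ln_b")]] <- matrix(0, 1, d)
    for (i in seq_len(h)) {
      params[[paste0(pre, "Wq", i)]] <- rnorm_mat(dh, dh, 0.02)
      params[[paste0(pre, "Wk", i)]] <- rnorm_mat(dh, dh, 0.02)
      params[[paste0(pre, "Wv", i)]] <- rnorm_mat(dh, dh, 0.02)
    }
    params[[paste0(pre, "Wh")]] <- rnorm_mat(2L * dh, h, 0.02)
    params[[paste0(pre, "Wc")]] <- rnorm_mat(h, nb, 0.02)
    params[[paste0(pre, "u")]] <- matrix(1, 1, nb)
    params[[paste0(pre, "Phi")]] <- diag(h)
  }
  if (config$pool_to > 0L) {
    params$pool_U <- rnorm_mat(config$pool_to, d, 1 / sqrt(d))
  }
  params$final_ln_g <- matrix(1, 1, d)
  params$final_ln_b <- matrix(0, 1, d)
  params$head_W <- rnorm_mat(d, config$classes, 0.02)
  params$head_b <- matrix(0, 1, config$classes)
  model <- structure(list(config = config, params = params, embed = embed),
                     class = "gvt_model")
  model$param_report <- parameter_report(model)
  model
}

#' Parameter count report
#'
#' @param model A `gvt_model`.
#' @return List with `total` and a named per-component `breakdown`.
#' @export
parameter_report <- function(model) {
  sizes <- vapply(model$params, length, 1L)
  comp <- sub("^(stem|in|blk[0-9]+|pool|final|head).*", "\\1", names(sizes))
  breakdown <- tapply(sizes, comp, sum)
  list(total = sum(sizes), breakdown = as.list(breakdown))
}

#' @export
print.gvt_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Graph-attention transformer (%s mode): %d blocks, d=%d, h=%d, n=%d",
              cfg$mode, cfg$blocks, cfg$hidden, cfg$heads, cfg$tokens))
  if (cfg$pool_to > 0L) {
    cat(sprintf(", pooled to %d after block %d", cfg$pool_to, cfg$pool_after_block))
  }
  cat(sprintf("\nclasses: %d  ablation: %s  parameters: %d\n",
              cfg$classes, cfg$ablation, x$param_report$total))
  invisible(x)
}

## ---- tape forward ----

# Adjacency chain on the tape: tokens node -> normalized adjacency node.
# `mask` is the constant (A_I + I) support matrix.
tape_adjacency <- function(Xn, mask, semantic_weighting) {
  sq <- ag_pow(ag_clamp_min(ag_rowsums(ag_pow(Xn, 2)), 1e-24), -0.5)
  Vn <- ag_mul_colvec(Xn, sq)
  Sim <- ag_matmul(Vn, ag_t(Vn))
  Dst <- ag_addc(ag_scale(Sim, -1), 1)          # 1 - cosine similarity
  if (semantic_weighting == "similarity") Dst <- ag_scale(Dst, -1)
  E <- ag_row_softmax(Dst)
  A <- ag_mulc(E, mask)
  deg <- ag_clamp_min(ag_rowsums(A), 1e-12)
  di <- ag_pow(deg, -0.5)
  list(A = A, norm = ag_mul_rowvec(ag_mul_colvec(A, di), ag_t(di)))
}

# One attention block on the tape. X: n x d node. Returns list(out, state).
tape_block <- function(X, mask, p, pre, config, capture = FALSE) {
  d <- config$hidden; h <- config$heads; dh <- d %/% h
  n <- nrow(X$value)
  Xn <- if (config$prenorm) {
    ag_layernorm(X, p[[paste0(pre, "ln_g")]], p[[paste0(pre, "ln_b")]])
  } else X
  adj <- tape_adjacency(Xn, mask, config$semantic_weighting)
  AX <- ag_matmul(adj$norm, Xn)
  q <- vector("list", h); k <- vector("list", h); xh <- vector("list", h)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * dh + 1L):(i * dh)
    xh[[i]] <- ag_cols(Xn, cols)
    AXi <- ag_cols(AX, cols)
    q[[i]] <- ag_matmul(AXi, p[[paste0(pre, "Wq", i)]])
    k[[i]] <- ag_matmul(AXi, p[[paste0(pre, "Wk", i)]])
  }
  S <- lapply(seq_len(h), function(i) {
    ag_row_softmax(ag_scale(ag_matmul(q[[i]], ag_t(k[[i]])), 1 / sqrt(dh)))
  })
  abl <- config$ablation
  if (abl == "no_talking") {
    R <- S
    Z <- NULL
  } else {
    if (abl == "dense_talking") {
      Shat <- S
      Z <- NULL
    } else {
      Wh <- p[[paste0(pre, "Wh")]]
      f <- lapply(seq_len(h), function(i) {
        ag_matmul(ag_cbind(list(q[[i]], k[[i]])), ag_cols(Wh, i))
      })
      F_ <- ag_t(ag_cbind(f))                      # h x n
      C <- ag_matmul(F_, ag_t(F_))
      Y <- ag_matmul(C, p[[paste0(pre, "Wc")]])
      uinv <- ag_pow(ag_clamp_min(p[[paste0(pre, "u")]], 1e-8), -1)
      Z <- ag_sigmoid(ag_mul_rowvec(Y, uinv))
      Shat <- lapply(seq_len(h), function(i) {
        zi <- ag_row(Z, i)
        ag_mul(ag_matmul(ag_t(zi), zi), S[[i]])    # (z z^T) .* S
      })
    }
    flat <- ag_rbind(lapply(Shat, ag_reshape, 1L, n * n))
    Rflat <- ag_matmul(p[[paste0(pre, "Phi")]], flat)
    R <- lapply(seq_len(h), function(i) ag_reshape(ag_row(Rflat, i), n, n))
  }
  vals <- vector("list", h)
  for (i in seq_len(h)) {
    Ri <- R[[i]]
    if (config$symmetrize_relation) Ri <- ag_scale(ag_add(Ri, ag_t(Ri)), 0.5)
    dg <- ag_clamp_min(ag_rowsums(ag_abs(Ri)), 1e-12)
    di <- ag_pow(dg, -0.5)
    N <- ag_mul_rowvec(ag_mul_colvec(Ri, di), ag_t(di))
    v <- ag_matmul(ag_matmul(N, xh[[i]]), p[[paste0(pre, "Wv", i)]])
    if (abl != "no_residual") v <- ag_add(v, xh[[i]])
    vals[[i]] <- v
  }
  merged <- ag_cbind(vals)
  out <- if (abl == "no_residual") merged else ag_add(merged, X)
  state <- NULL
  if (capture) {
    arr <- function(lst) {
      a <- array(0, c(h, n, n))
      for (i in seq_len(h)) a[i, , ] <- lst[[i]]$value
      a
    }
    state <- list(tokens_in = X$value, scores = arr(S), relation = arr(R),
                  gates = if (!is.null(Z)) Z$value else NULL,
                  adjacency = adj$A$value, normalized = adj$norm$value,
                  n = n)
  }
  list(out = out, state = state)
}

# Full image forward on the tape for one image. Returns list(logits, states,
# token_counts).
tape_forward_image <- function(model, image, p, capture = FALSE) {
  config <- model$config
  geo <- stem_geometry(dim(image)[1], dim(image)[2], model$embed)
  cols <- im2col_apply(image_to_posmat(image), geo$idx1$src)
  X <- stem_forward(cols, geo, model$embed, p)
  mask_pre <- grid_adjacency(geo$s, geo$s) + diag(config$tokens)
  mask <- mask_pre
  states <- if (capture) vector("list", config$blocks) else NULL
  token_counts <- integer(config$blocks)
  for (b in seq_len(config$blocks)) {
    token_counts[b] <- nrow(X$value)
    pre <- paste0("blk", b, "_")
    res <- tape_block(X, mask, p, pre, config, capture)
    X <- res$out
    if (capture) states[[b]] <- res$state
    if (config$pool_to > 0L && b == config$pool_after_block) {
      # second-order pooling; the pooled spatial prior is derived from the
      # (detached) pooled adjacency support
      n <- nrow(X$value)
      U <- p$pool_U
      Xp <- ag_scale(ag_matmul(ag_matmul(U, ag_t(X)), X), 1 / n)
      bund <- adjacency_bundle(X$value, spatial = mask_pre - diag(n),
                               semantic_weighting = config$semantic_weighting)
      Cp <- U$value %*% t(X$value)
      Ap <- pool_adjacency(bund$combined, Cp)
      prior <- pooled_spatial_prior(Ap, 8L)
      mask <- prior + diag(config$pool_to)
      X <- Xp
    }
  }
  Xf <- ag_layernorm(X, p$final_ln_g, p$final_ln_b)
  pooled <- ag_colmeans(Xf)
  logits <- ag_add_rowvec(ag_matmul(pooled, p$head_W), p$head_b)
  list(logits = logits, states = states, token_counts = token_counts)
}

# Node-mode forward on the tape: features (n x feature_dim), mask = A_I + I.
tape_forward_nodes <- function(model, features, mask, p, capture = FALSE) {
  config <- model$config
  X <- ag_add_rowvec(ag_matmul(ag_leaf(features), p$in_W), p$in_b)
  states <- if (capture) vector("list", config$blocks) else NULL
  for (b in seq_len(config$blocks)) {
    res <- tape_block(X, mask, p, paste0("blk", b, "_"), config, capture)
    X <- res$out
    if (capture) states[[b]] <- res$state
  }
  Xf <- ag_layernorm(X, p$final_ln_g, p$final_ln_b)
  logits <- ag_add_rowvec(ag_matmul(Xf, p$head_W), p$head_b)
  list(logits = logits, states = states)
}

#' Forward pass on images
#'
#' @param model Image-mode `gvt_model`.
#' @param images One `H x W x C` array or a list of them; `H = W` must equal
#'   the configured `image_size`.
#' @param trace Also return per-block token counts and captured block states
#'   for the first image.
#' @return `batch x classes` logits matrix; with `trace = TRUE`, a list
#'   `list(logits, token_counts, states)`.
#' @export
forward_image <- function(model, images, trace = FALSE) {
  stopifnot(model$config$mode == "image")
  if (!is.list(images)) images <- list(images)
  for (img in images) {
    if (dim(img)[1] != model$config$image_size || dim(img)[2] != model$config$image_size) {
      stop("image resolution ", dim(img)[1], "x", dim(img)[2],
           " does not match the configured image_size ", model$config$image_size)
    }
  }
  p <- lapply(model$params, ag_leaf)
  outs <- vector("list", length(images))
  tc <- NULL; st <- NULL
  for (j in seq_along(images)) {
    r <- tape_forward_image(model, images[[j]], p, capture = trace && j == 1L)
    outs[[j]] <- r$logits$value
    if (j == 1L) { tc <- r$token_counts; st <- r$states }
  }
  logits <- do.call(rbind, outs)
  if (trace) list(logits = logits, token_counts = tc, states = st) else logits
}

#' Forward pass on a node-classification graph
#'
#' Builds the spatial prior from the undirected edge list (duplicate edges
#' collapse under binarization), then runs the block stack and returns one
#' logit row per node.
#'
#' @param model Graph-mode `gvt_model` whose `tokens` equals the node count.
#' @param features `n x feature_dim` node feature matrix.
#' @param edges Two-column integer matrix of (src, dst) node indices (1-based).
#' @param trace Capture block states.
#' @return `n x classes` logits matrix (or a list with `states` if `trace`).
#' @export
forward_nodes <- function(model, features, edges, trace = FALSE) {
  stopifnot(model$config$mode == "graph")
  features <- as.matrix(features)
  n <- nrow(features)
  if (n != model$config$tokens) {
    stop("node count ", n, " does not match the configured token count ",
         model$config$tokens)
  }
  mask <- edge_list_to_adjacency(edges, n) + diag(n)
  p <- lapply(model$params, ag_leaf)
  r <- tape_forward_nodes(model, features, mask, p, capture = trace)
  if (trace) list(logits = r$logits$value, states = r$states) else r$logits$value
}

#' Binary symmetric adjacency from an edge list
#'
#' @param edges Two-column matrix of 1-based node indices.
#' @param n Node count.
#' @return `n x n` binary symmetric matrix with zero diagonal.
#' @export
edge_list_to_adjacency <- function(edges, n) {
  A <- matrix(0, n, n)
  if (length(edges)) {
    edges <- as.matrix(edges)
    if (any(edges < 1L) || any(edges > n)) stop("edge index out of range [1, ", n, "]")
    A[edges] <- 1
    A[edges[, 2:1, drop = FALSE]] <- 1
  }
  diag(A) <- 0
  A
}

## ---- config / checkpoint serialization ----

#' Write a configuration to a YAML file
#' @param config A `gvt_config`.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$symmetrize_relation <- as.logical(x$symmetrize_relation)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a configuration from a YAML file
#' @param path YAML file written by [write_config()].
#' @return A `gvt_config`.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(gvt_config, x)
}

#' Save a checkpoint
#'
#' A checkpoint bundles the configuration, all parameter matrices, the epoch
#' and a named metric map; it round-trips bit-identically.
#'
#' @param model `gvt_model`.
#' @param path Output file.
#' @param epoch Training epoch the parameters correspond to.
#' @param metrics Named list of metric values.
#' @export
save_checkpoint <- function(model, path, epoch = 0L, metrics = list()) {
  saveRDS(list(config = unclass(model$config), params = model$params,
               epoch = as.integer(epoch), metrics = metrics),
          path)
  invisible(path)
}

#' Load a checkpoint
#' @param path File written by [save_checkpoint()].
#' @return List with `model` (a `gvt_model`), `epoch`, `metrics`.
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  config <- do.call(gvt_config, x$config[!vapply(x$config, is.null, TRUE)])
  model <- structure(list(config = config, params = x$params,
                          embed = if (config$mode == "image")
                            embedding_config(config$in_channels, config$hidden,
                                             config$tokens) else NULL),
                     class = "gvt_model")
  model$param_report <- parameter_report(model)
  list(model = model, epoch = x$epoch, metrics = x$metrics)
}
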