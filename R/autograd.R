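# Minimal tape-based reverse-mode automatic differentiation over dense matrices.
#
# Every node is an environment holding a value, an optional gradient, its parent
# nodes and a backward closure that scatters the node's gradient to the parents.
# The tape is implicit: nodes reference their parents, and ag_backward() runs a
# topological sort from the loss node. Only what the model needs is implemented;
# all values are plain base-R matrices.

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0L

ag_node <- function(value, parents = list(), backward = NULL) {
  e <- new.env(parent = emptyenv())
  .ag$counter <- .ag$counter + 1L
  e$id <- .ag$counter
  e$value <- value
  e$parents <- parents
  e$backward <- backward
  e$grad <- NULL
  class(e) <- "ag_node"
  e
}

#' @noRd
ag_leaf <- function(value) ag_node(as.matrix(value))

ag_value <- function(x) if (inherits(x, "ag_node")) x$value else x

ag_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(node)
}

# Topological order by iterative DFS (recursion would overflow on deep tapes).
ag_toposort <- function(root) {
  seen <- new.env(parent = emptyenv())
  order <- vector("list", 256L)
  norder <- 0L
  stack <- list(list(node = root, idx = 0L))
  nstack <- 1L
  while (nstack > 0L) {
    fr <- stack[[nstack]]
    node <- fr$node
    key <- as.character(node$id)
    if (fr$idx == 0L && !is.null(seen[[key]])) { nstack <- nstack - 1L; next }
    if (fr$idx < length(node$parents)) {
      stack[[nstack]]$idx <- fr$idx + 1L
      child <- node$parents[[fr$idx + 1L]]
      if (is.null(seen[[as.character(child$id)]])) {
        nstack <- nstack + 1L
        stack[[nstack]] <- list(node = child, idx = 0L)
      }
    } else {
      seen[[key]] <- TRUE
      norder <- norder + 1L
      if (norder > length(order)) order <- c(order, vector("list", length(order)))
      order[[norder]] <- node
      nstack <- nstack - 1L
    }
  }
  order[seq_len(norder)]
}

#' Run reverse-mode accumulation from a scalar root node.
#' @noRd
ag_backward <- function(root) {
  stopifnot(length(root$value) == 1L)
  topo <- ag_toposort(root)
  root$grad <- matrix(1, 1L, 1L)
  for (i in rev(seq_along(topo))) {
    node <- topo[[i]]
    if (!is.null(node$backward) && !is.null(node$grad)) node$backward(node)
  }
  invisible(root)
}

## ---- primitive operations ----

ag_matmul <- function(a, b) {
  ag_node(a$value %*% b$value, list(a, b), function(n) {
    ag_accum(a, n$grad %*% t(b$value))
    ag_accum(b, t(a$value) %*% n$grad)
  })
}

ag_add <- function(a, b) {
  ag_node(a$value + b$value, list(a, b), function(n) {
    ag_accum(a, n$grad); ag_accum(b, n$grad)
  })
}

ag_sub <- function(a, b) {
  ag_node(a$value - b$value, list(a, b), function(n) {
    ag_accum(a, n$grad); ag_accum(b, -n$grad)
  })
}

# matrix + (1 x m) row vector, broadcast over rows
ag_add_rowvec <- function(a, v) {
  ag_node(sweep(a$value, 2L, as.vector(v$value), "+"), list(a, v), function(n) {
    ag_accum(a, n$grad)
    ag_accum(v, matrix(colSums(n$grad), 1L))
  })
}

ag_mul <- function(a, b) {
  ag_node(a$value * b$value, list(a, b), function(n) {
    ag_accum(a, n$grad * b$value)
    ag_accum(b, n$grad * a$value)
  })
}

# multiply by a constant matrix (no gradient into the constant)
ag_mulc <- function(a, const) {
  ag_node(a$value * const, list(a), function(n) ag_accum(a, n$grad * const))
}

ag_scale <- function(a, s) {
  ag_node(a$value * s, list(a), function(n) ag_accum(a, n$grad * s))
}

ag_addc <- function(a, c0) {
  ag_node(a$value + c0, list(a), function(n) ag_accum(a, n$grad))
}

ag_t <- function(a) {
  ag_node(t(a$value), list(a), function(n) ag_accum(a, t(n$grad)))
}

# matrix * column vector (n x 1), broadcast over columns
ag_mul_colvec <- function(a, v) {
  ag_node(a$value * as.vector(v$value), list(a, v), function(n) {
    ag_accum(a, n$grad * as.vector(v$value))
    ag_accum(v, matrix(rowSums(n$grad * a$value), ncol = 1L))
  })
}

# matrix * row vector (1 x m), broadcast over rows
ag_mul_rowvec <- function(a, v) {
  ag_node(sweep(a$value, 2L, as.vector(v$value), "*"), list(a, v), function(n) {
    ag_accum(a, sweep(n$grad, 2L, as.vector(v$value), "*"))
    ag_accum(v, matrix(colSums(n$grad * a$value), 1L))
  })
}

ag_row_softmax <- function(a) {
  x <- a$value
  m <- apply(x, 1L, max)
  ex <- exp(x - m)
  p <- ex / rowSums(ex)
  ag_node(p, list(a), function(n) {
    g <- n$grad
    ag_accum(a, p * (g - rowSums(g * p)))
  })
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ag_node(s, list(a), function(n) ag_accum(a, n$grad * s * (1 - s)))
}

ag_gelu <- function(a) {
  x <- a$value
  ag_node(x * pnorm(x), list(a), function(n) {
    ag_accum(a, n$grad * (pnorm(x) + x * dnorm(x)))
  })
}

# elementwise power with a constant exponent (inputs assumed positive where needed)
ag_pow <- function(a, p) {
  ag_node(a$value^p, list(a), function(n) {
    ag_accum(a, n$grad * p * a$value^(p - 1))
  })
}

ag_clamp_min <- function(a, m) {
  v <- pmax(a$value, m)
  ag_node(v, list(a), function(n) ag_accum(a, n$grad * (a$value > m)))
}

ag_abs <- function(a) {
  ag_node(abs(a$value), list(a), function(n) ag_accum(a, n$grad * sign(a$value)))
}

ag_rowsums <- function(a) {
  m <- ncol(a$value)
  ag_node(matrix(rowSums(a$value), ncol = 1L), list(a), function(n) {
    ag_accum(a, matrix(n$grad, nrow(a$value), m))
  })
}

ag_sum_all <- function(a) {
  ag_node(matrix(sum(a$value), 1L, 1L), list(a), function(n) {
    ag_accum(a, matrix(as.numeric(n$grad), nrow(a$value), ncol(a$value)))
  })
}

ag_colmeans <- function(a) {
  nr <- nrow(a$value)
  ag_node(matrix(colMeans(a$value), 1L), list(a), function(n) {
    ag_accum(a, matrix(n$grad, nr, ncol(a$value), byrow = TRUE) / nr)
  })
}

ag_cols <- function(a, idx) {
  ag_node(a$value[, idx, drop = FALSE], list(a), function(n) {
    g <- matrix(0, nrow(a$value), ncol(a$value))
    g[, idx] <- n$grad
    ag_accum(a, g)
  })
}

ag_rows <- function(a, idx) {
  ag_node(a$value[idx, , drop = FALSE], list(a), function(n) {
    g <- matrix(0, nrow(a$value), ncol(a$value))
    g[idx, ] <- n$grad
    ag_accum(a, g)
  })
}

ag_row <- function(a, i) ag_rows(a, i)

ag_cbind <- function(nodes) {
  widths <- vapply(nodes, function(x) ncol(x$value), 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ag_node(do.call(cbind, lapply(nodes, `[[`, "value")), nodes, function(n) {
    for (j in seq_along(nodes)) {
      ag_accum(nodes[[j]], n$grad[, starts[j]:ends[j], drop = FALSE])
    }
  })
}

ag_rbind <- function(nodes) {
  hts <- vapply(nodes, function(x) nrow(x$value), 1L)
  ends <- cumsum(hts)
  starts <- ends - hts + 1L
  ag_node(do.call(rbind, lapply(nodes, `[[`, "value")), nodes, function(n) {
    for (j in seq_along(nodes)) {
      ag_accum(nodes[[j]], n$grad[starts[j]:ends[j], , drop = FALSE])
    }
  })
}

ag_reshape <- function(a, nr, nc) {
  ag_node(matrix(a$value, nr, nc), list(a), function(n) {
    ag_accum(a, matrix(n$grad, nrow(a$value), ncol(a$value)))
  })
}

# Per-row (token-wise) standardisation over features with learned affine.
ag_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$value
  m <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  g <- as.vector(gamma$value)
  out <- sweep(sweep(xhat, 2L, g, "*"), 2L, as.vector(beta$value), "+")
  ag_node(out, list(a, gamma, beta), function(n) {
    G <- n$grad
    ag_accum(gamma, matrix(colSums(G * xhat), 1L))
    ag_accum(beta, matrix(colSums(G), 1L))
    dxhat <- sweep(G, 2L, g, "*")
    rs1 <- rowSums(dxhat)
    rs2 <- rowSums(dxhat * xhat)
    ag_accum(a, (inv / m) * (m * dxhat - rs1 - xhat * rs2))
  })
}

# Mean cross-entropy from logits (rows = samples) against integer class labels.
ag_cross_entropy <- function(logits, targets) {
  x <- logits$value
  nr <- nrow(x)
  stopifnot(length(targets) == nr)
  m <- apply(x, 1L, max)
  lse <- m + log(rowSums(exp(x - m)))
  picked <- x[cbind(seq_len(nr), targets)]
  loss <- mean(lse - picked)
  ag_node(matrix(loss, 1L, 1L), list(logits), function(n) {
    p <- exp(x - lse)   # row-wise softmax
    p[cbind(seq_len(nr), targets)] <- p[cbind(seq_len(nr), targets)] - 1
    ag_accum(logits, (as.numeric(n$grad) / nr) * p)
  })
}

## ---- im2col gather for convolution as matrix multiply ----

# Source-row index table for a k x k kernel over an r x c grid (row-major
# positions), stride s, zero padding p. Entry 0 marks a padded location.
im2col_index <- function(r, c, k, stride, pad) {
  out_r <- (r + 2L * pad - k) %/% stride + 1L
  out_c <- (c + 2L * pad - k) %/% stride + 1L
  npos <- out_r * out_c
  src <- matrix(0L, npos, k * k)
  o <- 0L
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      o <- o + 1L
      # top-left of out position (i,j) is (1 - pad + (i-1)*stride, 1 - pad + (j-1)*stride)
      oi <- rep(seq_len(out_r), each = out_c)
      oj <- rep(seq_len(out_c), times = out_r)
      ri <- 1L - pad + (oi - 1L) * stride + (a - 1L)
      cj <- 1L - pad + (oj - 1L) * stride + (b - 1L)
      ok <- ri >= 1L & ri <= r & cj >= 1L & cj <= c
      src[, o] <- ifelse(ok, (ri - 1L) * c + cj, 0L)
    }
  }
  list(src = src, out_r = out_r, out_c = out_c)
}

# Plain-value im2col: X is (r*c) x ch row-major positions; returns npos_out x (k^2*ch).
im2col_apply <- function(X, src) {
  ch <- ncol(X)
  k2 <- ncol(src)
  Xz <- rbind(matrix(0, 1L, ch), X)
  out <- matrix(0, nrow(src), k2 * ch)
  for (o in seq_len(k2)) {
    out[, ((o - 1L) * ch + 1L):(o * ch)] <- Xz[src[, o] + 1L, , drop = FALSE]
  }
  out
}

ag_im2col <- function(a, src) {
  ch <- ncol(a$value)
  ag_node(im2col_apply(a$value, src), list(a), function(n) {
    g <- matrix(0, nrow(a$value), ch)
    for (o in seq_len(ncol(src))) {
      idx <- src[, o]
      keep <- idx > 0L
      if (any(keep)) {
        cols <- ((o - 1L) * ch + 1L):(o * ch)
        g[idx[keep], ] <- g[idx[keep], , drop = FALSE] +
          n$grad[keep, cols, drop = FALSE]
      }
    }
    ag_accum(a, g)
  })
}
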