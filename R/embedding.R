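#' Convolutional token embedding configuration
#'
#' The stem maps an image to a `sqrt(tokens) x sqrt(tokens)` grid of tokens
#' with a two-layer group convolution: layer 1 (`in_channels -> hidden`,
#' kernel `kernel`, stride `patch_side/2`, ungrouped — too few input
#' channels to group), layer 2 (`hidden -> hidden`, kernel `kernel`,
#' stride 2, `groups = hidden/8`), each followed by a GELU nonlinearity.
#' No positional embeddings are used anywhere: locality is carried by the
#' convolution and the spatial adjacency prior.
#'
#' @param in_channels Input channels (3 for RGB).
#' @param hidden Token feature dimension `d`; must be divisible by 8 when
#'   grouped (falls back to 1 group otherwise).
#' @param tokens Token count `n`; must be a perfect square.
#' @param kernel Odd kernel size, default 5.
#' @return List of class `embedding_config`.
#' @export
embedding_config <- function(in_channels = 3L, hidden = 64L, tokens = 64L,
                             kernel = 5L) {
  s <- sqrt(tokens)
  if (s != floor(s)) stop("`tokens` must be a perfect square")
  if (kernel %% 2L != 1L) stop("`kernel` must be odd")
  groups <- if (hidden %% 8L == 0L) hidden %/% 8L else 1L
  structure(list(in_channels = as.integer(in_channels),
                 hidden = as.integer(hidden), tokens = as.integer(tokens),
                 kernel = as.integer(kernel), groups = groups, layers = 2L),
            class = "embedding_config")
}

# Flatten an H x W x C image array to an (H*W) x C row-major position matrix.
image_to_posmat <- function(img) {
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  out <- matrix(0, H * W, C)
  for (ch in seq_len(C)) out[, ch] <- as.vector(t(img[, , ch]))
  out
}

# Stem geometry for an image of side H given the token grid side s.
stem_geometry <- function(H, W, cfg) {
  s <- as.integer(sqrt(cfg$tokens))
  if (H != W) stop("images must be square at the configured resolution; resize upstream")
  if (H %% s != 0L) stop("image side ", H, " is not divisible by the token grid side ",
                         s, "; resize the image")
  p <- H %/% s
  if (p %% 2L != 0L) stop("patch side ", p, " must be even for the two-stride stem")
  pad <- (cfg$kernel - 1L) %/% 2L
  list(s = s, patch = p, stride1 = p %/% 2L, pad = pad,
       idx1 = im2col_index(H, W, cfg$kernel, p %/% 2L, pad),
       idx2 = im2col_index(2L * s, 2L * s, cfg$kernel, 2L, pad))
}

# Tape forward of the stem. `img_cols` is the constant im2col matrix of the
# image for layer 1; params are ag_node leaves.
stem_forward <- function(img_cols, geo, cfg, p) {
  h1 <- ag_gelu(ag_add_rowvec(ag_matmul(ag_leaf(img_cols), p$stem_W1), p$stem_b1))
  g <- cfg$groups
  chg <- cfg$hidden %/% g
  parts <- vector("list", g)
  for (gi in seq_len(g)) {
    cols <- ((gi - 1L) * chg + 1L):(gi * chg)
    parts[[gi]] <- ag_matmul(ag_im2col(ag_cols(h1, cols), geo$idx2$src),
                             p[[paste0("stem_W2_g", gi)]])
  }
  ag_gelu(ag_add_rowvec(ag_cbind(parts), p$stem_b2))
}

#' Embed an image into a token map
#'
#' Runs the model's convolutional stem on one image, returning the token
#' features and grid shape. Deterministic given the model's weights.
#'
#' @param image `H x W x C` numeric array (values already standardized) with
#'   `H = W` divisible by `sqrt(tokens)`.
#' @param model A model built by [build_model()] (image mode).
#' @return List with `features` (`n x d` matrix), `grid` (`c(s, s)`),
#'   `n`, `d`.
#' @export
embed_image <- function(image, model) {
  cfg <- model$embed
  geo <- stem_geometry(dim(image)[1], dim(image)[2], cfg)
  cols <- im2col_apply(image_to_posmat(image), geo$idx1$src)
  p <- lapply(model$params, ag_leaf)
  tok <- stem_forward(cols, geo, cfg, p)$value
  list(features = tok, grid = c(geo$s, geo$s), n = nrow(tok), d = ncol(tok))
}

#' Load and standardize a raster image
#'
#' Reads a PNG, converts to RGB in `[0, 1]`, resizes to `size x size` with
#' bilinear interpolation, then standardizes per channel.
#'
#' @param path PNG file path.
#' @param size Target square side in pixels.
#' @param mean,sd Per-channel standardization constants (recycled), defaults
#'   0.5/0.5.
#' @return `size x size x 3` numeric array.
#' @export
load_image <- function(path, size, mean = 0.5, sd = 0.5) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[1] != size || dim(img)[2] != size) img <- resize_bilinear(img, size, size)
  standardize_image(img, mean, sd)
}

#' @noRd
standardize_image <- function(img, mean = 0.5, sd = 0.5) {
  C <- dim(img)[3]
  mean <- rep(mean, length.out = C); sd <- rep(sd, length.out = C)
  for (ch in seq_len(C)) img[, , ch] <- (img[, , ch] - mean[ch]) / sd[ch]
  img
}

# Bilinear resize of an H x W x C array.
resize_bilinear <- function(img, H2, W2) {
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  yi <- (seq_len(H2) - 0.5) * H / H2 + 0.5
  xi <- (seq_len(W2) - 0.5) * W / W2 + 0.5
  y0 <- pmin(pmax(floor(yi), 1L), H); y1 <- pmin(y0 + 1L, H)
  x0 <- pmin(pmax(floor(xi), 1L), W); x1 <- pmin(x0 + 1L, W)
  wy <- pmin(pmax(yi - y0, 0), 1); wx <- pmin(pmax(xi - x0, 0), 1)
  out <- array(0, c(H2, W2, C))
  for (ch in seq_len(C)) {
    P <- img[, , ch]
    out[, , ch] <- (1 - wy) * ((P[y0, x0] * rep((1 - wx), each = H2)) +
                               (P[y0, x1] * rep(wx, each = H2))) +
                   wy * ((P[y1, x0] * rep((1 - wx), each = H2)) +
                         (P[y1, x1] * rep(wx, each = H2)))
  }
  out
}
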