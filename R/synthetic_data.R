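#' Generate a toy labeled image dataset with class-specific local motifs
#'
#' Each class is defined by a distinct spatial motif: a textured square of
#' side `motif_scale` pixels (solid, checkerboard, horizontal or vertical
#' stripes, cycling over classes) rendered at a class-specific grid cell with
#' a class-specific colour, over a mid-grey background, plus additive
#' Gaussian pixel noise. Placing motifs at distinct cells makes the 8-neighbour
#' spatial token adjacency informative, which is exactly the small-data regime
#' the model's graph prior targets. Classes are balanced and split 80/20 into
#' train/test; everything is a pure function of the spec (including the seed).
#'
#' @param classes Number of classes.
#' @param per_class Images per class.
#' @param size Square image side in pixels; must be divisible by the token
#'   grid used downstream.
#' @param motif_scale Motif side in pixels.
#' @param noise_sd Gaussian pixel noise standard deviation (pixel units,
#'   images in `[0, 1]`).
#' @param seed RNG seed.
#' @param train_frac Train fraction of the split (default 0.8).
#' @return List with `train` and `test`, each `list(images, labels)` where
#'   `images` is a list of `size x size x 3` arrays in `[0, 1]` and `labels`
#'   an integer vector in `1..classes`; plus the generating `spec`.
#' @export
make_image_dataset <- function(classes = 4L, per_class = 50L, size = 32L,
                               motif_scale = 8L, noise_sd = 0.1, seed = 1L,
                               train_frac = 0.8) {
  stopifnot(classes >= 2L, per_class >= 2L, noise_sd >= 0, motif_scale <= size)
  set.seed(seed)
  cells <- floor(size / motif_scale)
  # distinct cell per class, deterministic scatter over the cell grid
  cell_pos <- cbind(((seq_len(classes) - 1L) * 2L) %% cells,
                    (((seq_len(classes) - 1L) * 2L) %/% cells * 3L +
                       (seq_len(classes) - 1L)) %% cells)
  colours <- cbind(c(0.9, 0.2, 0.2, 0.9, 0.6, 0.2, 0.9, 0.5),
                   c(0.2, 0.9, 0.2, 0.9, 0.3, 0.6, 0.6, 0.5),
                   c(0.2, 0.2, 0.9, 0.2, 0.9, 0.9, 0.3, 0.9))
  pat <- function(kind, m) {
    ix <- matrix(rep(seq_len(m), m), m, m)
    iy <- t(ix)
    switch(kind,
           matrix(1, m, m),                       # solid
           (ix + iy) %% 2L,                       # checkerboard
           ix %% 2L,                              # horizontal stripes
           iy %% 2L)                              # vertical stripes
  }
  images <- vector("list", classes * per_class)
  labels <- integer(classes * per_class)
  idx <- 0L
  for (cl in seq_len(classes)) {
    r0 <- cell_pos[cl, 1] * motif_scale
    c0 <- cell_pos[cl, 2] * motif_scale
    tex <- pat(((cl - 1L) %% 4L) + 1L, motif_scale)
    col <- colours[((cl - 1L) %% nrow(colours)) + 1L, ]
    for (j in seq_len(per_class)) {
      idx <- idx + 1L
      img <- array(0.5, c(size, size, 3L))
      for (ch in 1:3) {
        img[r0 + seq_len(motif_scale), c0 + seq_len(motif_scale), ch] <-
          0.5 + (col[ch] - 0.5) * tex
      }
      if (noise_sd > 0) {
        img <- img + array(rnorm(size * size * 3L, sd = noise_sd), dim(img))
      }
      images[[idx]] <- pmin(pmax(img, 0), 1)
      labels[idx] <- cl
    }
  }
  ntr <- round(train_frac * per_class)
  tr <- unlist(lapply(seq_len(classes), function(cl) {
    (cl - 1L) * per_class + seq_len(ntr)
  }))
  te <- setdiff(seq_along(labels), tr)
  list(train = list(images = images[tr], labels = labels[tr]),
       test = list(images = images[te], labels = labels[te]),
       spec = list(classes = classes, per_class = per_class, size = size,
                   motif_scale = motif_scale, noise_sd = noise_sd, seed = seed,
                   train_frac = train_frac))
}

#' Generate a planted-partition citation-style graph dataset
#'
#' Nodes get classes (balanced), edges are drawn one endpoint at a time:
#' with probability `homophily` the second endpoint is sampled from the same
#' class, otherwise from a different class; the expected edge count is
#' `mean_degree * nodes / 2` (duplicates and self loops removed). Node
#' features are the class-mean vector plus isotropic Gaussian noise. Exactly
#' `floor(label_rate * nodes)` training labels are drawn, stratified by class
#' (this reproduces the canonical 140 training labels at Cora's printed 0.052
#' rate); remaining nodes split evenly into validation and test masks.
#'
#' @param nodes,classes,feature_dim Graph dimensions.
#' @param homophily Probability mass of intra-class edges, in `[0, 1]`.
#' @param mean_degree Target mean node degree.
#' @param label_rate Fraction of nodes carrying training labels, `(0, 1]`.
#' @param feature_noise_sd Noise around the class-mean features.
#' @param seed RNG seed.
#' @return List with `features` (`nodes x feature_dim`), `edges` (two-column
#'   matrix, each undirected edge once), `labels` (integer), `train_mask`,
#'   `val_mask`, `test_mask` (logical vectors), and `spec`.
#' @export
make_citation_dataset <- function(nodes = 400L, classes = 4L, feature_dim = 32L,
                                  homophily = 0.9, mean_degree = 5,
                                  label_rate = 0.05, feature_noise_sd = 0.5,
                                  seed = 1L) {
  stopifnot(homophily >= 0, homophily <= 1, label_rate > 0, label_rate <= 1)
  if (floor(label_rate * nodes) < classes) {
    stop("label_rate too small: need at least one labeled node per class")
  }
  set.seed(seed)
  labels <- rep_len(seq_len(classes), nodes)[sample.int(nodes)]
  m <- round(mean_degree * nodes / 2)
  src <- sample.int(nodes, m, replace = TRUE)
  same <- runif(m) < homophily
  dst <- integer(m)
  for (j in seq_len(m)) {
    pool <- if (same[j]) which(labels == labels[src[j]]) else which(labels != labels[src[j]])
    pool <- setdiff(pool, src[j])
    dst[j] <- if (length(pool)) pool[sample.int(length(pool), 1L)] else src[j]
  }
  e <- cbind(pmin(src, dst), pmax(src, dst))
  e <- unique(e[e[, 1] != e[, 2], , drop = FALSE])
  mu <- matrix(rnorm(classes * feature_dim), classes, feature_dim)
  features <- mu[labels, , drop = FALSE] +
    matrix(rnorm(nodes * feature_dim, sd = feature_noise_sd), nodes, feature_dim)
  ntrain <- floor(label_rate * nodes)
  per <- diff(round(seq(0, ntrain, length.out = classes + 1L)))
  train_idx <- unlist(lapply(seq_len(classes), function(cl) {
    cand <- which(labels == cl)
    cand[sample.int(length(cand), min(per[cl], length(cand)))]
  }))
  # top up in case a class was short
  short <- ntrain - length(train_idx)
  if (short > 0L) {
    rest <- setdiff(seq_len(nodes), train_idx)
    train_idx <- c(train_idx, rest[sample.int(length(rest), short)])
  }
  rest <- setdiff(seq_len(nodes), train_idx)
  rest <- rest[sample.int(length(rest))]
  nval <- length(rest) %/% 2L
  train_mask <- val_mask <- test_mask <- rep(FALSE, nodes)
  train_mask[train_idx] <- TRUE
  val_mask[rest[seq_len(nval)]] <- TRUE
  test_mask[rest[(nval + 1L):length(rest)]] <- TRUE
  list(features = features, edges = e, labels = labels,
       train_mask = train_mask, val_mask = val_mask, test_mask = test_mask,
       spec = list(nodes = nodes, classes = classes, feature_dim = feature_dim,
                   homophily = homophily, mean_degree = mean_degree,
                   label_rate = label_rate, feature_noise_sd = feature_noise_sd,
                   seed = seed))
}

## ---- on-disk formats shared with the CLI loaders ----

#' Write an image dataset as PNG files plus a labels CSV
#'
#' Layout: `<dir>/images/<split>_<i>.png` and `<dir>/labels.csv` with columns
#' `filename,label,split`.
#'
#' @param dataset Result of [make_image_dataset()].
#' @param dir Output directory (created).
#' @export
write_image_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (split in c("train", "test")) {
    part <- dataset[[split]]
    for (j in seq_along(part$images)) {
      fn <- sprintf("%s_%04d.png", split, j)
      png::writePNG(part$images[[j]], file.path(dir, "images", fn))
      rows[[length(rows) + 1L]] <- data.frame(filename = fn,
                                              label = part$labels[j],
                                              split = split)
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "labels.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read an image dataset written by [write_image_dataset()]
#' @param dir Dataset directory.
#' @return Same structure as [make_image_dataset()] (without `spec`).
#' @export
read_image_dataset <- function(dir) {
  lab_path <- file.path(dir, "labels.csv")
  if (!file.exists(lab_path)) stop("malformed dataset: missing ", lab_path)
  lab <- utils::read.csv(lab_path)
  out <- list()
  for (split in c("train", "test")) {
    sel <- lab[lab$split == split, , drop = FALSE]
    imgs <- lapply(sel$filename, function(fn) {
      path <- file.path(dir, "images", fn)
      if (!file.exists(path)) stop("malformed dataset: missing image ", path)
      img <- png::readPNG(path)
      if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
      img[, , 1:3, drop = FALSE]
    })
    out[[split]] <- list(images = imgs, labels = as.integer(sel$label))
  }
  out
}

#' Write a citation-style graph dataset (edge TSV + CSV tables)
#'
#' Layout: `edges.tsv` (src, dst), `features.csv`, `nodes.csv`
#' (label, train_mask, val_mask, test_mask).
#'
#' @param dataset Result of [make_citation_dataset()].
#' @param dir Output directory (created).
#' @export
write_citation_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(dataset$edges, file.path(dir, "edges.tsv"), sep = "\t",
                     row.names = FALSE, col.names = c("src", "dst"))
  utils::write.csv(as.data.frame(dataset$features), file.path(dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(label = dataset$labels,
                              train_mask = dataset$train_mask,
                              val_mask = dataset$val_mask,
                              test_mask = dataset$test_mask),
                   file.path(dir, "nodes.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a citation-style graph dataset written by [write_citation_dataset()]
#' @param dir Dataset directory.
#' @return Same structure as [make_citation_dataset()] (without `spec`).
#' @export
read_citation_dataset <- function(dir) {
  for (f in c("edges.tsv", "features.csv", "nodes.csv")) {
    if (!file.exists(file.path(dir, f))) stop("malformed dataset: missing ", f)
  }
  edges <- as.matrix(utils::read.table(file.path(dir, "edges.tsv"), header = TRUE,
                                       sep = "\t"))
  features <- as.matrix(utils::read.csv(file.path(dir, "features.csv")))
  nodes <- utils::read.csv(file.path(dir, "nodes.csv"))
  list(features = unname(features), edges = unname(edges),
       labels = as.integer(nodes$label),
       train_mask = as.logical(nodes$train_mask),
       val_mask = as.logical(nodes$val_mask),
       test_mask = as.logical(nodes$test_mask))
}
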