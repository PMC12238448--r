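#' Training configuration
#'
#' Defaults follow the published recipe: AdamW with weight decay 0.05, initial
#' learning rate 5e-4 with cosine decay, batch size 64, plain cross-entropy,
#' no warmup, single device. Desk-scale epoch defaults are 20 (image mode)
#' and 100 (node mode).
#'
#' @param optimizer Only `"adamw"` is implemented.
#' @param weight_decay Decoupled weight decay (applied to weight matrices,
#'   not to biases, normalization parameters or the shrinkage slopes).
#' @param lr Initial learning rate.
#' @param schedule `"cosine"` or `"constant"`.
#' @param batch_size Minibatch size (image mode; node mode is full-batch).
#' @param epochs Training epochs.
#' @param seed Seed covering shuffling (model init is seeded by the model
#'   config).
#' @return List of class `train_config`.
#' @export
train_config <- function(optimizer = "adamw", weight_decay = 0.05, lr = 5e-4,
                         schedule = c("cosine", "constant"), batch_size = 64L,
                         epochs = 20L, seed = 1L) {
  schedule <- match.arg(schedule)
  stopifnot(lr > 0, batch_size >= 1L, epochs >= 0L)
  structure(list(optimizer = optimizer, weight_decay = weight_decay, lr = lr,
                 schedule = schedule, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

# Parameter names receiving weight decay: 2D weight matrices only.
decay_mask <- function(params) {
  grepl("W[qkvhc]?[0-9]*$|Wh$|Wc$|Phi$|pool_U$|_W[12]$|_W2_g[0-9]+$|head_W$|in_W$|stem_W1$",
        names(params))
}

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamw_step <- function(params, grads, state, lr, weight_decay, decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
    if (decay[[nm]]) upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

cosine_lr <- function(base_lr, epoch, epochs, schedule) {
  if (schedule == "constant" || epochs <= 1L) return(base_lr)
  base_lr * 0.5 * (1 + cos(pi * (epoch - 1) / (epochs - 1)))
}

# Mean loss and gradient over a batch of images (list) with integer labels.
image_batch_grad <- function(model, images, labels, p) {
  loss_nodes <- vector("list", length(images))
  for (j in seq_along(images)) {
    r <- tape_forward_image(model, images[[j]], p)
    loss_nodes[[j]] <- ag_cross_entropy(r$logits, labels[j])
  }
  total <- loss_nodes[[1]]
  if (length(loss_nodes) > 1L) {
    for (j in 2:length(loss_nodes)) total <- ag_add(total, loss_nodes[[j]])
  }
  ag_scale(total, 1 / length(loss_nodes))
}

#' Train a model
#'
#' Runs the optimization loop (cross-entropy loss, AdamW, cosine decay) on an
#' image dataset (as produced by [make_image_dataset()] or a directory in the
#' documented layout) or on a node-classification dataset (full-batch, with
#' the training mask). Fully seeded: the same configs and seed give identical
#' metric histories. Returns the best checkpoint (by eval accuracy) and the
#' per-epoch history.
#'
#' @param model_config A [gvt_config()].
#' @param tc A [train_config()].
#' @param data A dataset list, or a path to a dataset directory.
#' @param checkpoint_path Optional path; the best checkpoint is saved there.
#' @param verbose Print per-epoch progress.
#' @return List with `model` (best parameters), `history` (data.frame of
#'   epoch, lr, train_loss, eval_accuracy), `best_epoch`.
#' @export
gvt_train <- function(model_config, tc, data, checkpoint_path = NULL,
                      verbose = FALSE) {
  if (is.character(data)) data <- load_dataset(data)
  model <- build_model(model_config)
  set.seed(tc$seed)
  if (model_config$mode == "image") {
    out <- train_images(model, tc, data, verbose)
  } else {
    out <- train_nodes(model, tc, data, verbose)
  }
  if (!is.null(checkpoint_path)) {
    save_checkpoint(out$model, checkpoint_path, epoch = out$best_epoch,
                    metrics = list(eval_accuracy = out$best_acc))
  }
  out
}

train_images <- function(model, tc, data, verbose) {
  imgs <- lapply(data$train$images, standardize_image)
  labs <- data$train$labels
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), eval_accuracy = numeric())
  best <- list(params = model$params, acc = -Inf, epoch = 0L)
  opt <- adamw_init(model$params)
  decay <- as.list(setNames(decay_mask(model$params), names(model$params)))
  for (ep in seq_len(tc$epochs)) {
    lr <- cosine_lr(tc$lr, ep, tc$epochs, tc$schedule)
    ord <- sample.int(length(imgs))
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = tc$batch_size)) {
      sel <- ord[start:min(start + tc$batch_size - 1L, length(ord))]
      p <- lapply(model$params, ag_leaf)
      loss <- image_batch_grad(model, imgs[sel], labs[sel], p)
      ag_backward(loss)
      grads <- lapply(p, function(x) x$grad)
      st <- adamw_step(model$params, grads, opt, lr, tc$weight_decay, decay)
      model$params <- st$params; opt <- st$state
      ep_loss <- ep_loss + loss$value; nb <- nb + 1L
    }
    acc <- evaluate_images(model, data$test)$accuracy
    history <- rbind(history, data.frame(epoch = ep, lr = lr,
                                         train_loss = ep_loss / nb,
                                         eval_accuracy = acc))
    if (acc > best$acc) best <- list(params = model$params, acc = acc, epoch = ep)
    if (verbose) message(sprintf("epoch %d  lr %.2e  loss %.4f  acc %.3f",
                                 ep, lr, ep_loss / nb, acc))
  }
  if (tc$epochs > 0L) model$params <- best$params
  list(model = model, history = history, best_epoch = best$epoch,
       best_acc = if (is.finite(best$acc)) best$acc else NA_real_)
}

train_nodes <- function(model, tc, data, verbose) {
  n <- nrow(data$features)
  mask <- edge_list_to_adjacency(data$edges, n) + diag(n)
  tr <- which(data$train_mask)
  ev <- if (any(data$test_mask)) which(data$test_mask) else seq_len(n)
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), eval_accuracy = numeric())
  best <- list(params = model$params, acc = -Inf, epoch = 0L)
  opt <- adamw_init(model$params)
  decay <- as.list(setNames(decay_mask(model$params), names(model$params)))
  for (ep in seq_len(tc$epochs)) {
    lr <- cosine_lr(tc$lr, ep, tc$epochs, tc$schedule)
    p <- lapply(model$params, ag_leaf)
    r <- tape_forward_nodes(model, data$features, mask, p)
    loss <- ag_cross_entropy(ag_rows(r$logits, tr), data$labels[tr])
    ag_backward(loss)
    st <- adamw_step(model$params, lapply(p, function(x) x$grad), opt, lr,
                     tc$weight_decay, decay)
    model$params <- st$params; opt <- st$state
    logits <- forward_nodes(model, data$features, data$edges)
    pred <- max.col(logits, ties.method = "first")
    acc <- mean(pred[ev] == data$labels[ev])
    history <- rbind(history, data.frame(epoch = ep, lr = lr,
                                         train_loss = as.numeric(loss$value),
                                         eval_accuracy = acc))
    if (acc > best$acc) best <- list(params = model$params, acc = acc, epoch = ep)
    if (verbose) message(sprintf("epoch %d  loss %.4f  acc %.3f",
                                 ep, loss$value, acc))
  }
  if (tc$epochs > 0L) model$params <- best$params
  list(model = model, history = history, best_epoch = best$epoch,
       best_acc = if (is.finite(best$acc)) best$acc else NA_real_)
}

evaluate_images <- function(model, split) {
  imgs <- lapply(split$images, standardize_image)
  logits <- forward_image(model, imgs)
  pred <- max.col(logits, ties.method = "first")
  acc <- mean(pred == split$labels)
  per <- vapply(sort(unique(split$labels)), function(cl) {
    mean(pred[split$labels == cl] == cl)
  }, numeric(1))
  names(per) <- as.character(sort(unique(split$labels)))
  list(accuracy = acc, per_class = per, predictions = pred)
}

#' Evaluate a model or checkpoint on a dataset
#'
#' Top-1 accuracy (correct / total) on the test split, with a per-class
#' breakdown. Deterministic.
#'
#' @param model A `gvt_model`, or a path to a checkpoint file.
#' @param data A dataset list or dataset directory path.
#' @return List with `accuracy`, `per_class`, `predictions`.
#' @export
gvt_evaluate <- function(model, data) {
  if (is.character(model)) model <- load_checkpoint(model)$model
  if (is.character(data)) data <- load_dataset(data)
  if (model$config$mode == "image") {
    nclass <- length(unique(c(data$train$labels, data$test$labels)))
    if (nclass > model$config$classes) {
      stop("dataset has ", nclass, " classes but the model was built for ",
           model$config$classes)
    }
    evaluate_images(model, data$test)
  } else {
    logits <- forward_nodes(model, data$features, data$edges)
    pred <- max.col(logits, ties.method = "first")
    ev <- if (any(data$test_mask)) which(data$test_mask) else seq_along(data$labels)
    per <- vapply(sort(unique(data$labels[ev])), function(cl) {
      sel <- ev[data$labels[ev] == cl]
      mean(pred[sel] == cl)
    }, numeric(1))
    names(per) <- as.character(sort(unique(data$labels[ev])))
    list(accuracy = mean(pred[ev] == data$labels[ev]), per_class = per,
         predictions = pred)
  }
}

# Detect and load a dataset directory (image layout vs graph layout).
load_dataset <- function(path) {
  if (file.exists(file.path(path, "labels.csv"))) read_image_dataset(path)
  else if (file.exists(file.path(path, "edges.tsv"))) read_citation_dataset(path)
  else stop("no recognizable dataset at ", path,
            " (expected labels.csv or edges.tsv)")
}
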