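# Training and evaluation: stratified 9:1 split, Adam on
# cross-entropy + lambda * link penalty, per-epoch logging.

#' Training configuration
#'
#' Defaults: Adam, learning rate 0.001, batch size 100, 150 epochs,
#' stratified 9:1 train/test split, link-penalty weight 0.1.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Records per minibatch.
#' @param epochs Training epochs.
#' @param split_ratio Training fraction of the 9:1-style split.
#' @param lambda Link-penalty weight (0 disables the regularizer).
#' @param link_normalize Normalize the link penalty by ordered-pair count.
#' @param seed Integer seed governing split, shuffling, and initialization.
#' @param eval_every Evaluate on the test set every this many epochs (the
#'   log carries `NA` in between).
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 100,
                         epochs = 150, split_ratio = 0.9, lambda = 0.1,
                         link_normalize = TRUE, seed = 1L, eval_every = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            split_ratio > 0, split_ratio < 1)
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), split_ratio = split_ratio,
                 lambda = lambda, link_normalize = isTRUE(link_normalize),
                 seed = as.integer(seed), eval_every = as.integer(eval_every),
                 optimizer = "adam"),
            class = "train_config")
}

#' Stratified train/test split of a dataset
#'
#' Per class, a seeded shuffle assigns `round(split_ratio * n_class)` records
#' to training and the rest to test, preserving class proportions within
#' rounding. A class with fewer than 2 records goes entirely to training with
#' a warning.
#'
#' @param dataset An `ecg_dataset`.
#' @param config A [train_config()] (uses `split_ratio` and `seed`).
#' @return List with `train` and `test` (`ecg_dataset`s, disjoint).
#' @export
split_dataset <- function(dataset, config = train_config()) {
  stopifnot(length(dataset) >= 2)
  labels <- dataset_labels(dataset)
  train_idx <- integer(0)
  test_idx <- integer(0)
  with_seed(derive_seed(config$seed, "split"), {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      if (length(idx) < 2) {
        warning(sprintf(
          "class %d has %d record(s); placed in training only", cls,
          length(idx)), call. = FALSE)
        train_idx <- c(train_idx, idx)
        next
      }
      idx <- idx[sample.int(length(idx))]
      n_train <- max(1L, min(length(idx) - 1L,
                             round(config$split_ratio * length(idx))))
      train_idx <- c(train_idx, idx[seq_len(n_train)])
      test_idx <- c(test_idx, idx[-seq_len(n_train)])
    }
  })
  list(train = dataset[sort(train_idx)], test = dataset[sort(test_idx)])
}

#' Train the CNN-transformer classifier
#'
#' Runs `epochs` passes of minibatch Adam on the composite loss
#' (cross-entropy + `lambda` x link penalty). Records per epoch: training
#' loss and its decomposition, training accuracy, and (every `eval_every`
#' epochs) test accuracy and macro F1. Fully reproducible from
#' `config$seed` on one device.
#'
#' @param train_stacks List of `segment_stack`s (the training set, already
#'   preprocessed and segmented).
#' @param config A [train_config()].
#' @param model_cfg A [model_config()].
#' @param test_stacks Optional list of `segment_stack`s for per-epoch
#'   evaluation.
#' @param verbose Log a line per epoch.
#' @return List with `model` (trained `ecg_model`) and `log` (data frame,
#'   one row per epoch: `epoch`, `train_loss`, `ce_term`, `link_term`,
#'   `train_accuracy`, `test_accuracy`, `test_macro_f1`).
#' @export
train_model <- function(train_stacks, config = train_config(),
                        model_cfg = model_config(), test_stacks = NULL,
                        verbose = TRUE) {
  if (length(train_stacks) == 0) stop("empty training set", call. = FALSE)
  labels <- vapply(train_stacks, function(s) s$label, integer(1))
  if (anyNA(labels)) stop("all training records must be labelled", call. = FALSE)
  model <- model_init(model_cfg, seed = derive_seed(config$seed, "init"))
  opt <- adam_state(model$params)
  n <- length(train_stacks)
  log_rows <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    order_idx <- with_seed(derive_seed(config$seed, sprintf("epoch%d", epoch)),
                           sample.int(n))
    batch_starts <- seq.int(1L, n, by = config$batch_size)
    ep_loss <- 0; ep_ce <- 0; ep_link <- 0; ep_correct <- 0L
    for (bs in batch_starts) {
      idx <- order_idx[bs:min(bs + config$batch_size - 1L, n)]
      stacks <- train_stacks[idx]
      y <- labels[idx]
      fw <- model_forward(model, stacks, training = TRUE)
      model <- fw$model
      lb <- total_loss(fw$probs, y, fw$embeddings, lambda = config$lambda,
                       normalize = config$link_normalize, training = TRUE)
      if (!is.finite(lb$total)) {
        stop(sprintf("non-finite loss at epoch %d, batch starting %d", epoch,
                     bs), call. = FALSE)
      }
      onehot <- matrix(0, length(y), model_cfg$n_classes)
      onehot[cbind(seq_along(y), y + 1L)] <- 1
      dlogits <- (fw$probs - onehot) / length(y)
      dembed <- if (config$lambda > 0) {
        config$lambda * link_penalty_grad(fw$embeddings, build_links(y),
                                          normalize = config$link_normalize)
      } else NULL
      grads <- model_backward(model, fw$cache, dlogits, dembed)
      upd <- adam_update(model$params, grads, opt, lr = config$learning_rate)
      model$params <- upd$params
      opt <- upd$state
      w <- length(y) / n
      ep_loss <- ep_loss + w * lb$total
      ep_ce <- ep_ce + w * lb$classification_term
      ep_link <- ep_link + w * lb$link_term
      ep_correct <- ep_correct + sum(max.col(fw$probs, ties.method = "first") - 1L == y)
    }
    test_acc <- NA_real_; test_f1 <- NA_real_
    if (!is.null(test_stacks) && epoch %% config$eval_every == 0L) {
      ev <- evaluate_model(model, test_stacks,
                           n_classes = model_cfg$n_classes)
      test_acc <- ev$accuracy
      test_f1 <- ev$diagnostics$macro_f1
    }
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, train_loss = ep_loss, ce_term = ep_ce,
      link_term = ep_link, train_accuracy = ep_correct / n,
      test_accuracy = test_acc, test_macro_f1 = test_f1)
    if (verbose) {
      log_msg("train", sprintf(
        "epoch %d/%d loss %.4f (ce %.4f, link %.4f) acc %.3f test_f1 %s",
        epoch, config$epochs, ep_loss, ep_ce, ep_link, ep_correct / n,
        ifelse(is.na(test_f1), "-", sprintf("%.3f", test_f1))))
    }
  }
  list(model = model, log = do.call(rbind, log_rows))
}

#' Evaluate a trained model on a test set
#'
#' Deterministic evaluation-mode forward pass; scoring is delegated to
#' [class_diagnostics()].
#'
#' @param model A trained `ecg_model`.
#' @param test_stacks List of labelled `segment_stack`s.
#' @param n_classes Number of classes for the diagnostics.
#' @return List with `diagnostics` (a [class_diagnostics()] object),
#'   `accuracy`, `predicted`, `embeddings`, `labels`.
#' @export
evaluate_model <- function(model, test_stacks, n_classes = 9) {
  labels <- vapply(test_stacks, function(s) s$label, integer(1))
  pr <- model_predict(model, test_stacks)
  diag_ <- class_diagnostics(labels, pr$predicted, pr$embeddings, n_classes)
  list(diagnostics = diag_, accuracy = mean(pr$predicted == labels),
       predicted = pr$predicted, embeddings = pr$embeddings, labels = labels)
}

#' Save a trained model (weights + full configuration) to one file
#'
#' @param model An `ecg_model`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Checkpoint file.
#' @return The `ecg_model`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ecg_model")) {
    stop(sprintf("'%s' is not an ecg_model checkpoint", path), call. = FALSE)
  }
  model
}
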