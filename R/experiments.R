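# Reproducible reduced-scale experiments: the package's own study conditions
# for exercising the full pipeline on synthetic data at desk scale.

#' Intra- minus inter-class embedding correlation gap
#'
#' Mean pairwise Pearson correlation between embeddings of same-class records
#' minus the mean between different-class records. The link penalty is
#' designed to widen exactly this gap (same-class similar, different-class
#' dissimilar).
#'
#' @param embeddings `n x d` embedding matrix.
#' @param labels Integer vector of 0-based labels.
#' @return Scalar gap (positive when same-class embeddings are more similar).
#' @export
embedding_correlation_gap <- function(embeddings, labels) {
  stopifnot(nrow(embeddings) == length(labels), nrow(embeddings) >= 2)
  C <- stats::cor(t(embeddings))
  same <- outer(labels, labels, `==`)
  diag(C) <- NA
  diag(same) <- NA
  mean(C[which(same)], na.rm = TRUE) - mean(C[which(!same)], na.rm = TRUE)
}

#' Reduced model configuration for small-scale experiments
#'
#' Two conv blocks, two encoder layers, `d_model` 32 (4 heads), 32-dim CNN
#' features — the scaled-down architecture used by the package's reduced
#' synthetic experiments.
#'
#' @param n_classes Number of output classes.
#' @param window_size Window length in samples.
#' @return A [model_config()].
#' @export
reduced_model_config <- function(n_classes = 3, window_size = 3000) {
  model_config(conv_layers = reduced_conv_layers(), cnn_feature_dim = 32,
               d_model = 32, n_encoder_layers = 2, n_heads = 4,
               ffn_hidden = 64, n_classes = n_classes,
               classifier_hidden = 32, window_size = window_size)
}

#' Run one reduced-scale synthetic training experiment
#'
#' Generates a class-balanced corrupted synthetic dataset, preprocesses and
#' segments it, performs a stratified 9:1 split, trains the reduced model
#' with the given link-penalty weight, and evaluates on the held-out set.
#' Deterministic given `seed`.
#'
#' @param seed Integer seed for data, split, initialization, and shuffling.
#' @param lambda Link-penalty weight.
#' @param n_records Dataset size (default 300).
#' @param n_classes Number of classes, taken from the start of
#'   [ecg_classes()] (default 3: normal, AF, I-AVB).
#' @param epochs Training epochs (default 20).
#' @param batch_size Minibatch size (default 30).
#' @param duration_range Record durations in seconds (default `c(6, 12)`).
#' @param verbose Log epochs.
#' @return List with `model`, `log`, `evaluation` (from [evaluate_model()]),
#'   `gap` (test-set [embedding_correlation_gap()]), and `configs`.
#' @export
run_reduced_experiment <- function(seed, lambda = 0.1, n_records = 300,
                                   n_classes = 3,
                                   epochs = 20, batch_size = 30,
                                   duration_range = c(6, 12),
                                   verbose = FALSE) {
  spec <- synthetic_spec(n_records = n_records, n_classes = n_classes,
                         duration_range = duration_range,
                         seed = derive_seed(seed, "data"))
  dataset <- generate_dataset(spec)
  pre_cfg <- preprocess_config()
  tr_cfg <- train_config(batch_size = batch_size, epochs = epochs,
                         lambda = lambda, seed = derive_seed(seed, "train"),
                         eval_every = epochs)
  model_cfg <- reduced_model_config(n_classes = n_classes,
                                    window_size = pre_cfg$window_size)
  sp <- split_dataset(dataset, tr_cfg)
  train_stacks <- preprocess_dataset(sp$train, pre_cfg)
  test_stacks <- preprocess_dataset(sp$test, pre_cfg)
  tr <- train_model(train_stacks, tr_cfg, model_cfg,
                    test_stacks = test_stacks, verbose = verbose)
  ev <- evaluate_model(tr$model, test_stacks, n_classes = n_classes)
  list(model = tr$model, log = tr$log, evaluation = ev,
       gap = embedding_correlation_gap(ev$embeddings, ev$labels),
       configs = list(spec = spec, preprocess = pre_cfg, model = model_cfg,
                      train = tr_cfg))
}

#' Class-center similarity vs misclassification association experiment
#'
#' Trains a deliberately short-budget reduced model on a multi-class
#' synthetic dataset, then relates, over unordered class pairs, the Pearson
#' similarity of class-center embeddings to the pairwise misclassification
#' count: classes whose centers are similar should be confused more often.
#' Predictions and centers are computed over the full dataset so confusion
#' counts carry signal at desk scale.
#'
#' @param seed Integer seed.
#' @param n_records Dataset size (default 200).
#' @param n_classes Number of classes (default 5).
#' @param epochs Training epochs; deliberately few, so the classifier is
#'   imperfect and confusions occur (default 3).
#' @param lambda Link-penalty weight.
#' @param batch_size Minibatch size.
#' @return List with `pairs` (data frame: class pair, center similarity,
#'   misclassification count), `similarity`, `confusion`, `accuracy`.
#' @export
run_similarity_experiment <- function(seed, n_records = 200, n_classes = 5,
                                      epochs = 3, lambda = 0.1,
                                      batch_size = 30) {
  spec <- synthetic_spec(n_records = n_records, n_classes = n_classes,
                         duration_range = c(6, 12),
                         seed = derive_seed(seed, "simdata"))
  dataset <- generate_dataset(spec)
  pre_cfg <- preprocess_config()
  tr_cfg <- train_config(batch_size = batch_size, epochs = epochs,
                         lambda = lambda, seed = derive_seed(seed, "simtrain"),
                         eval_every = epochs)
  model_cfg <- reduced_model_config(n_classes = n_classes,
                                    window_size = pre_cfg$window_size)
  sp <- split_dataset(dataset, tr_cfg)
  train_stacks <- preprocess_dataset(sp$train, pre_cfg)
  tr <- train_model(train_stacks, tr_cfg, model_cfg, verbose = FALSE)
  all_stacks <- c(train_stacks, preprocess_dataset(sp$test, pre_cfg))
  labels <- vapply(all_stacks, function(s) s$label, integer(1))
  pr <- model_predict(tr$model, all_stacks)
  N <- confusion_matrix(labels, pr$predicted, n_classes)
  S <- similarity_matrix(class_centers(pr$embeddings, labels, n_classes))
  pairs <- do.call(rbind, lapply(seq_len(n_classes - 1), function(i) {
    do.call(rbind, lapply((i + 1):n_classes, function(j) {
      data.frame(class_i = i - 1L, class_j = j - 1L,
                 similarity = S[i, j],
                 misclassified = N[i, j] + N[j, i])
    }))
  }))
  list(pairs = pairs, similarity = S, confusion = N,
       accuracy = mean(pr$predicted == labels))
}
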