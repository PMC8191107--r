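# Evaluation: confusion matrix, per-class and macro F1, class-center
# embeddings and their Pearson similarity matrix.

#' Confusion matrix of true vs predicted labels
#'
#' @param true_labels,predicted_labels Integer vectors of 0-based labels.
#' @param n_classes Number of classes (default 9).
#' @return `n_classes x n_classes` integer matrix; entry `[i, j]` counts
#'   records of true class `i-1` predicted as class `j-1`. Row/column names
#'   are the class names.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, n_classes = 9) {
  true_labels <- as.integer(true_labels)
  predicted_labels <- as.integer(predicted_labels)
  stopifnot(length(true_labels) == length(predicted_labels))
  if (any(c(true_labels, predicted_labels) < 0L) ||
      any(c(true_labels, predicted_labels) >= n_classes)) {
    stop(sprintf("labels must lie in 0..%d", n_classes - 1L), call. = FALSE)
  }
  N <- matrix(0L, n_classes, n_classes,
              dimnames = list(true = ecg_classes()[seq_len(n_classes)],
                              predicted = ecg_classes()[seq_len(n_classes)]))
  for (k in seq_along(true_labels)) {
    i <- true_labels[k] + 1L
    j <- predicted_labels[k] + 1L
    N[i, j] <- N[i, j] + 1L
  }
  N
}

#' Per-class and macro F1 from a confusion matrix
#'
#' Per-class F1 is `2 TP / (2 TP + FP + FN)` — the harmonic mean of positive
#' predictive value and sensitivity. A class absent from both the rows and
#' columns (no true and no predicted instances) has undefined F1 and is
#' excluded from the macro average with a note.
#'
#' @param N Confusion matrix from [confusion_matrix()].
#' @return List with `per_class` (named numeric, `NA` where undefined) and
#'   `macro` (unweighted mean over defined classes).
#' @export
per_class_f1 <- function(N) {
  n_classes <- nrow(N)
  f1 <- rep(NA_real_, n_classes)
  for (i in seq_len(n_classes)) {
    tp <- N[i, i]
    denom <- sum(N[i, ]) + sum(N[, i])      # 2TP + FP + FN
    if (denom > 0) f1[i] <- 2 * tp / denom
  }
  names(f1) <- rownames(N)
  if (anyNA(f1)) {
    message(sprintf("F1 undefined for class(es) %s (no instances); excluded from macro average",
                    paste(names(f1)[is.na(f1)], collapse = ", ")))
  }
  list(per_class = f1, macro = mean(f1, na.rm = TRUE))
}

#' Class-center embeddings
#'
#' The center of class `i` minimizes the summed squared distance to that
#' class's embeddings; the closed-form minimizer is the per-class mean.
#' Classes with no samples get an `NA` row.
#'
#' @param embeddings `n x d` embedding matrix.
#' @param labels Integer vector of 0-based labels.
#' @param n_classes Number of classes (default 9).
#' @return `n_classes x d` matrix of centers (row `i` = class `i-1`), with
#'   `NA` rows for empty classes.
#' @export
class_centers <- function(embeddings, labels, n_classes = 9) {
  labels <- as.integer(labels)
  d <- ncol(embeddings)
  centers <- matrix(NA_real_, n_classes, d,
                    dimnames = list(ecg_classes()[seq_len(n_classes)], NULL))
  for (i in seq_len(n_classes)) {
    rows <- which(labels == i - 1L)
    if (length(rows) > 0) {
      centers[i, ] <- colMeans(embeddings[rows, , drop = FALSE])
    }
  }
  if (anyNA(centers[, 1])) {
    message(sprintf("no embeddings for class(es) %s; center absent",
                    paste(rownames(centers)[is.na(centers[, 1])],
                          collapse = ", ")))
  }
  centers
}

#' Pearson similarity matrix of class centers
#'
#' @param centers `k x d` matrix of class-center vectors (rows may be `NA`
#'   for absent classes).
#' @return `k x k` matrix of pairwise Pearson correlations; symmetric with
#'   unit diagonal where defined, `NA` for absent or zero-variance centers.
#' @export
similarity_matrix <- function(centers) {
  k <- nrow(centers)
  S <- matrix(NA_real_, k, k, dimnames = list(rownames(centers),
                                              rownames(centers)))
  ok <- !is.na(centers[, 1]) & apply(centers, 1, stats::sd) > 0
  if (any(ok)) {
    S[ok, ok] <- stats::cor(t(centers[ok, , drop = FALSE]))
  }
  S
}

#' Full classification diagnostics
#'
#' @param true_labels,predicted_labels Integer vectors of 0-based labels.
#' @param embeddings `n x d` record embeddings (evaluation-mode).
#' @param n_classes Number of classes.
#' @return Object of class `class_diagnostics`: confusion matrix, per-class
#'   F1, macro F1, class centers, and center similarity matrix.
#' @export
class_diagnostics <- function(true_labels, predicted_labels, embeddings,
                              n_classes = 9) {
  N <- confusion_matrix(true_labels, predicted_labels, n_classes)
  f1 <- per_class_f1(N)
  centers <- class_centers(embeddings, true_labels, n_classes)
  structure(list(confusion = N, per_class_f1 = f1$per_class,
                 macro_f1 = f1$macro, centers = centers,
                 similarity = similarity_matrix(centers)),
            class = "class_diagnostics")
}

#' @export
print.class_diagnostics <- function(x, ...) {
  cat("Confusion matrix (true x predicted):\n")
  print(x$confusion)
  cat("\nPer-class F1:\n")
  print(round(x$per_class_f1, 3))
  cat(sprintf("\nMacro F1: %.3f\n", x$macro_f1))
  invisible(x)
}

#' Write embeddings with labels to CSV
#'
#' Full-precision export of record embeddings for external projection or
#' plotting; columns `record_id`, `label`, `e1..ed`.
#'
#' @param embeddings `n x d` matrix.
#' @param labels Integer vector of 0-based labels (may contain `NA`).
#' @param path Output CSV path.
#' @param record_ids Optional record identifiers (default `rec1..recn`).
#' @return `path`, invisibly.
#' @export
export_embeddings <- function(embeddings, labels, path,
                              record_ids = NULL) {
  n <- nrow(embeddings)
  if (is.null(record_ids)) record_ids <- sprintf("rec%d", seq_len(n))
  stopifnot(length(labels) == n, length(record_ids) == n)
  df <- data.frame(record_id = record_ids, label = as.integer(labels))
  emb <- as.data.frame(embeddings)
  names(emb) <- sprintf("e%d", seq_len(ncol(embeddings)))
  df <- cbind(df, emb)
  tryCatch(
    utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, row.names = FALSE, quote = FALSE),
    error = function(e) stop(sprintf("cannot write embeddings to '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  invisible(path)
}
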