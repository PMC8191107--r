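# Classification loss with the must-link/cannot-link embedding regularizer.
#
# Records of the same class form must-links (e = +1), records of different
# classes cannot-links (e = -1). The penalty sum over ordered pairs p != q of
# (1/2) ||beta_p - e_pq beta_q||^2 is minimized when same-class embeddings
# coincide and different-class embeddings are antipodal, pushing intra-class
# Pearson correlation toward +1 and inter-class correlation toward -1.

#' Build the must-link/cannot-link indicator matrix from labels
#'
#' @param labels Integer vector of 0-based class labels.
#' @return `n x n` matrix with `+1` where labels agree (must-link, including
#'   the diagonal) and `-1` where they differ (cannot-link); symmetric.
#' @export
build_links <- function(labels) {
  labels <- as.integer(labels)
  if (any(labels < 0L | labels > 8L)) {
    stop("labels must lie in 0..8", call. = FALSE)
  }
  same <- outer(labels, labels, `==`)
  matrix(ifelse(same, 1, -1), length(labels), length(labels))
}

#' Link-constraint penalty over a batch of embeddings
#'
#' Sum over ordered pairs `p != q` of `0.5 * ||beta_p - e_pq * beta_q||^2`,
#' optionally divided by the number of ordered pairs (the default, so the
#' penalty's scale does not grow with batch size). Zero exactly when every
#' must-linked pair is identical and every cannot-linked pair antipodal.
#'
#' @param embeddings `n x d` matrix of record embeddings (one per record).
#' @param links `n x n` link matrix from [build_links()].
#' @param normalize Divide by the number of ordered pairs (default `TRUE`).
#' @return Scalar penalty (non-negative).
#' @export
link_penalty <- function(embeddings, links, normalize = TRUE) {
  n <- nrow(embeddings)
  if (n < 2L) return(0)
  G <- embeddings %*% t(embeddings)           # Gram matrix
  sq <- diag(G)
  # ||b_p - e b_q||^2 = ||b_p||^2 + ||b_q||^2 - 2 e <b_p, b_q>
  M <- outer(sq, sq, `+`) - 2 * links * G
  diag(M) <- 0                                 # ordered pairs p != q only
  total <- 0.5 * sum(M)
  if (normalize) total / (n * (n - 1L)) else total
}

#' Gradient of the link penalty w.r.t. the embeddings
#'
#' Closed form: `d/d beta_p = sum_{q != p} 2 (beta_p - e_pq beta_q)`
#' (both ordered pairs containing `p` contribute), divided by the pair count
#' when `normalize = TRUE`.
#'
#' @inheritParams link_penalty
#' @return `n x d` gradient matrix.
#' @export
link_penalty_grad <- function(embeddings, links, normalize = TRUE) {
  n <- nrow(embeddings)
  if (n < 2L) return(embeddings * 0)
  E <- links
  diag(E) <- 0
  grad <- 2 * ((n - 1L) * embeddings - E %*% embeddings)
  if (normalize) grad / (n * (n - 1L)) else grad
}

#' Cross-entropy of predicted class probabilities
#'
#' @param probs `n x n_classes` row-stochastic probability matrix.
#' @param labels Integer vector of 0-based true labels.
#' @param eps Floor applied inside the logarithm.
#' @return Mean negative log-probability of the true class.
#' @export
cross_entropy <- function(probs, labels, eps = 1e-12) {
  n <- nrow(probs)
  p_true <- probs[cbind(seq_len(n), as.integer(labels) + 1L)]
  -mean(log(pmax(p_true, eps)))
}

#' Total training loss: cross-entropy + lambda * link penalty
#'
#' The composite objective: the classification term is the mean cross-entropy
#' of the softmax scores, the link term the pairwise embedding penalty
#' (applied during training only, like any regularizer).
#'
#' @param probs `n x n_classes` probabilities from the classification head.
#' @param labels Integer vector of 0-based true labels.
#' @param embeddings `n x d` record embeddings.
#' @param lambda Non-negative weight of the link term.
#' @param normalize Normalize the link penalty by pair count.
#' @param training Compute the link term? (`FALSE` = inference: link term 0.)
#' @return Object of class `loss_breakdown`: list with `classification_term`,
#'   `link_term`, `lambda`, `total`.
#' @export
total_loss <- function(probs, labels, embeddings, lambda = 0.1,
                       normalize = TRUE, training = TRUE) {
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  ce <- cross_entropy(probs, labels)
  lk <- if (training && lambda > 0) {
    link_penalty(embeddings, build_links(labels), normalize = normalize)
  } else 0
  structure(list(classification_term = ce, link_term = lk, lambda = lambda,
                 total = ce + lambda * lk),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss: %.6f = CE %.6f + %g * link %.6f\n",
              x$total, x$classification_term, x$lambda, x$link_term))
  invisible(x)
}
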