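# CNN-per-window feature extractor + transformer encoder over the window
# sequence + classification head.
#
# Each record's fixed-length windows map independently through the CNN to one
# feature vector per window; a linear projection brings features to d_model,
# sinusoidal positional encoding is added, the encoder stack runs over the
# window sequence, and pooling over tokens yields one embedding per record
# (X_embed) that feeds both the classifier and the link penalty.

#' Model configuration
#'
#' @param conv_layers List of conv blocks, each `list(out_channels,
#'   kernel_size, pool_size)`; each block is conv -> batch norm -> ReLU ->
#'   max pool. The default has seven blocks with decreasing kernel sizes.
#'   Kernel sizes must be odd ('same' padding); the product of pool sizes
#'   must divide `window_size`.
#' @param cnn_feature_dim Width of the per-window feature vector produced by
#'   the CNN's final flatten + linear stage (default 150).
#' @param d_model Transformer token width (default 256); all encoder
#'   sublayers preserve it.
#' @param n_encoder_layers Number of identical encoder layers (default 8).
#' @param n_heads Attention heads; must divide `d_model` (default 8).
#' @param ffn_hidden Hidden width of the position-wise feed-forward network
#'   (default 1024).
#' @param n_classes Number of output classes (default 9).
#' @param classifier_hidden Hidden width of the classification head
#'   (linear -> ReLU -> linear -> softmax; default 128).
#' @param pooling How the token sequence is pooled to one record embedding:
#'   `"mean"` (default) or `"first"` (first token).
#' @param window_size Expected window length in samples (default 3000).
#' @param pe_odd_sin Use sine (not cosine) for odd positional-encoding
#'   columns, reproducing the duplicated-sine variant (default `FALSE`).
#' @return Object of class `model_config`.
#' @export
model_config <- function(conv_layers = default_conv_layers(),
                         cnn_feature_dim = 150, d_model = 256,
                         n_encoder_layers = 8, n_heads = 8,
                         ffn_hidden = 1024, n_classes = 9,
                         classifier_hidden = 128,
                         pooling = c("mean", "first"),
                         window_size = 3000, pe_odd_sin = FALSE) {
  pooling <- match.arg(pooling)
  if (d_model %% n_heads != 0) {
    stop(sprintf("d_model (%d) must be divisible by n_heads (%d)",
                 d_model, n_heads), call. = FALSE)
  }
  if (d_model %% 2 != 0) {
    stop("d_model must be even (sin/cos positional-encoding pairs)",
         call. = FALSE)
  }
  for (cl in conv_layers) {
    stopifnot(length(cl) == 3)
    if (cl[[2]] %% 2 == 0) {
      stop("conv kernel sizes must be odd ('same' padding)", call. = FALSE)
    }
  }
  pool_prod <- prod(vapply(conv_layers, function(cl) cl[[3]], numeric(1)))
  if (window_size %% pool_prod != 0) {
    stop(sprintf(
      "window_size %d not divisible by the product of pool sizes (%d); use a window length that is a multiple of %d",
      window_size, pool_prod, pool_prod), call. = FALSE)
  }
  structure(list(
    conv_layers = conv_layers, cnn_feature_dim = as.integer(cnn_feature_dim),
    d_model = as.integer(d_model),
    n_encoder_layers = as.integer(n_encoder_layers),
    n_heads = as.integer(n_heads), ffn_hidden = as.integer(ffn_hidden),
    n_classes = as.integer(n_classes),
    classifier_hidden = as.integer(classifier_hidden),
    pooling = pooling, window_size = as.integer(window_size),
    pe_odd_sin = isTRUE(pe_odd_sin)
  ), class = "model_config")
}

#' Default seven-block CNN stack
#'
#' Seven conv blocks with decreasing kernel sizes (15, 15, 11, 11, 7, 7, 5),
#' channels growing from 16 and capped at 128, pool sizes chosen so their
#' product (600) divides the 3000-sample window; the final feature map is
#' 5 positions x 128 channels.
#'
#' @return List of `list(out_channels, kernel_size, pool_size)`.
#' @export
default_conv_layers <- function() {
  list(list(16L, 15L, 2L), list(32L, 15L, 2L), list(64L, 11L, 2L),
       list(64L, 11L, 5L), list(128L, 7L, 5L), list(128L, 7L, 3L),
       list(128L, 5L, 1L))
}

#' Reduced two-block CNN stack for small-scale experiments
#'
#' @return List of `list(out_channels, kernel_size, pool_size)`.
#' @export
reduced_conv_layers <- function() {
  list(list(8L, 15L, 5L), list(16L, 11L, 5L))
}

# Per-window feature-map length after the conv/pool stack.
cnn_out_length <- function(config) {
  T_ <- config$window_size
  for (cl in config$conv_layers) T_ <- T_ %/% cl[[3]]
  as.integer(T_)
}

#' Initialize model weights
#'
#' Glorot-uniform weights, zero biases, unit batch-norm/layer-norm gains;
#' fully reproducible from `seed`.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return Object of class `ecg_model`: list with `config`, `params` (flat
#'   named list of arrays), and `bn_running` (batch-norm running statistics).
#' @export
model_init <- function(config, seed = 1L) {
  with_seed(seed, {
    params <- list()
    cin <- N_LEADS
    for (i in seq_along(config$conv_layers)) {
      cl <- config$conv_layers[[i]]
      cout <- cl[[1]]; k <- cl[[2]]
      params[[sprintf("conv%d_W", i)]] <- init_matrix(k * cin, cout)
      params[[sprintf("conv%d_b", i)]] <- numeric(cout)
      params[[sprintf("bn%d_gamma", i)]] <- rep(1, cout)
      params[[sprintf("bn%d_beta", i)]] <- numeric(cout)
      cin <- cout
    }
    flat_dim <- cnn_out_length(config) * cin
    params$cnnfc_W <- init_matrix(flat_dim, config$cnn_feature_dim)
    params$cnnfc_b <- numeric(config$cnn_feature_dim)
    params$proj_W <- init_matrix(config$cnn_feature_dim, config$d_model)
    params$proj_b <- numeric(config$d_model)
    d <- config$d_model
    for (l in seq_len(config$n_encoder_layers)) {
      pre <- sprintf("enc%d_", l)
      for (nm in c("Wq", "Wk", "Wv", "Wo")) {
        params[[paste0(pre, nm)]] <- init_matrix(d, d)
      }
      for (nm in c("bq", "bk", "bv", "bo")) {
        params[[paste0(pre, nm)]] <- numeric(d)
      }
      params[[paste0(pre, "ln1_gamma")]] <- rep(1, d)
      params[[paste0(pre, "ln1_beta")]] <- numeric(d)
      params[[paste0(pre, "ffn_W1")]] <- init_matrix(d, config$ffn_hidden)
      params[[paste0(pre, "ffn_b1")]] <- numeric(config$ffn_hidden)
      params[[paste0(pre, "ffn_W2")]] <- init_matrix(config$ffn_hidden, d)
      params[[paste0(pre, "ffn_b2")]] <- numeric(d)
      params[[paste0(pre, "ln2_gamma")]] <- rep(1, d)
      params[[paste0(pre, "ln2_beta")]] <- numeric(d)
    }
    params$cls_W1 <- init_matrix(d, config$classifier_hidden)
    params$cls_b1 <- numeric(config$classifier_hidden)
    params$cls_W2 <- init_matrix(config$classifier_hidden, config$n_classes)
    params$cls_b2 <- numeric(config$n_classes)
    bn_running <- lapply(config$conv_layers, function(cl) {
      list(mean = numeric(cl[[1]]), var = rep(1, cl[[1]]))
    })
    structure(list(config = config, params = params, bn_running = bn_running),
              class = "ecg_model")
  })
}

#' @export
print.ecg_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(
    "<ecg_model: %d conv blocks -> %d features -> %d encoder layers (d_model %d, %d heads) -> %d classes; %s parameters>\n",
    length(x$config$conv_layers), x$config$cnn_feature_dim,
    x$config$n_encoder_layers, x$config$d_model, x$config$n_heads,
    x$config$n_classes, format(np, big.mark = ",")))
  invisible(x)
}

#' Sinusoidal positional encoding
#'
#' Column `2i` (0-based) holds `sin(pos / 10000^(2i/d_model))` and column
#' `2i+1` the matching cosine (or sine again when `odd_sin = TRUE`).
#' Positions are 0-based.
#'
#' @param n_positions Number of sequence positions.
#' @param d_model Encoding width (even).
#' @param odd_sin Use sine for odd columns instead of cosine.
#' @return `n_positions x d_model` matrix.
#' @export
positional_encoding <- function(n_positions, d_model, odd_sin = FALSE) {
  stopifnot(d_model %% 2 == 0)
  pos <- seq_len(n_positions) - 1
  i2 <- 2 * (seq_len(d_model %/% 2) - 1)          # 0, 2, 4, ...
  ang <- outer(pos, 1 / 10000^(i2 / d_model))
  pe <- matrix(0, n_positions, d_model)
  pe[, seq.int(1, d_model, by = 2)] <- sin(ang)
  pe[, seq.int(2, d_model, by = 2)] <- if (odd_sin) sin(ang) else cos(ang)
  pe
}

#' Scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(d_k)) V` with the softmax taken row-wise over keys.
#'
#' @param Q Queries, `n x d_k`.
#' @param K Keys, `m x d_k`.
#' @param V Values, `m x d_v`.
#' @return List with `context` (`n x d_v`) and `weights` (`n x m`,
#'   row-stochastic attention weights).
#' @export
scaled_dot_attention <- function(Q, K, V) {
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  A <- softmax_rows(Q %*% t(K) / sqrt(ncol(Q)))
  list(context = A %*% V, weights = A)
}

# ---- multi-head self-attention (one record's token matrix x: n x d) --------

mha_forward <- function(x, params, pre, n_heads) {
  d <- ncol(x)
  dh <- d %/% n_heads
  Q <- sweep(x %*% params[[paste0(pre, "Wq")]], 2, params[[paste0(pre, "bq")]], `+`)
  K <- sweep(x %*% params[[paste0(pre, "Wk")]], 2, params[[paste0(pre, "bk")]], `+`)
  V <- sweep(x %*% params[[paste0(pre, "Wv")]], 2, params[[paste0(pre, "bv")]], `+`)
  Ctx <- matrix(0, nrow(x), d)
  Aws <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    A <- softmax_rows(Q[, cols, drop = FALSE] %*%
                        t(K[, cols, drop = FALSE]) / sqrt(dh))
    Aws[[h]] <- A
    Ctx[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  out <- sweep(Ctx %*% params[[paste0(pre, "Wo")]], 2,
               params[[paste0(pre, "bo")]], `+`)
  list(out = out,
       cache = list(x = x, Q = Q, K = K, V = V, Ctx = Ctx, Aws = Aws,
                    pre = pre, n_heads = n_heads, dh = dh))
}

mha_backward <- function(cache, params, dout) {
  pre <- cache$pre
  g <- list()
  g[[paste0(pre, "Wo")]] <- crossprod(cache$Ctx, dout)
  g[[paste0(pre, "bo")]] <- colSums(dout)
  dCtx <- dout %*% t(params[[paste0(pre, "Wo")]])
  dQ <- matrix(0, nrow(dout), ncol(dout))
  dK <- dQ; dV <- dQ
  for (h in seq_len(cache$n_heads)) {
    cols <- ((h - 1L) * cache$dh + 1L):(h * cache$dh)
    A <- cache$Aws[[h]]
    Vh <- cache$V[, cols, drop = FALSE]
    dCh <- dCtx[, cols, drop = FALSE]
    dA <- dCh %*% t(Vh)
    dV[, cols] <- crossprod(A, dCh)
    dS <- A * (dA - rowSums(dA * A))      # softmax Jacobian, row-wise
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] / sqrt(cache$dh)
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE]) / sqrt(cache$dh)
  }
  dx <- matrix(0, nrow(dout), ncol(dout))
  for (nm in c("q", "k", "v")) {
    dZ <- switch(nm, q = dQ, k = dK, v = dV)
    W <- params[[paste0(pre, "W", nm)]]
    g[[paste0(pre, "W", nm)]] <- crossprod(cache$x, dZ)
    g[[paste0(pre, "b", nm)]] <- colSums(dZ)
    dx <- dx + dZ %*% t(W)
  }
  list(dx = dx, grads = g)
}

# ---- one encoder layer: LN(x + MHA(x)) -> LN(. + FFN(.)) -------------------

encoder_layer_forward <- function(x, params, pre, config) {
  mha <- mha_forward(x, params, pre, config$n_heads)
  ln1 <- layernorm_forward(x + mha$out, params[[paste0(pre, "ln1_gamma")]],
                           params[[paste0(pre, "ln1_beta")]])
  f1 <- linear_forward(ln1$out, params[[paste0(pre, "ffn_W1")]],
                       params[[paste0(pre, "ffn_b1")]])
  r1 <- relu_forward(f1$out)
  f2 <- linear_forward(r1$out, params[[paste0(pre, "ffn_W2")]],
                       params[[paste0(pre, "ffn_b2")]])
  ln2 <- layernorm_forward(ln1$out + f2$out,
                           params[[paste0(pre, "ln2_gamma")]],
                           params[[paste0(pre, "ln2_beta")]])
  list(out = ln2$out,
       cache = list(mha = mha$cache, ln1 = ln1$cache, f1 = f1$cache,
                    r1 = r1$cache, f2 = f2$cache, ln2 = ln2$cache, pre = pre))
}

encoder_layer_backward <- function(cache, params, dout) {
  pre <- cache$pre
  g <- list()
  b2 <- layernorm_backward(cache$ln2, dout)
  g[[paste0(pre, "ln2_gamma")]] <- b2$dgamma
  g[[paste0(pre, "ln2_beta")]] <- b2$dbeta
  bf2 <- linear_backward(cache$f2, b2$dx)
  g[[paste0(pre, "ffn_W2")]] <- bf2$dW
  g[[paste0(pre, "ffn_b2")]] <- bf2$db
  br1 <- relu_backward(cache$r1, bf2$dx)
  bf1 <- linear_backward(cache$f1, br1)
  g[[paste0(pre, "ffn_W1")]] <- bf1$dW
  g[[paste0(pre, "ffn_b1")]] <- bf1$db
  dln1 <- b2$dx + bf1$dx                  # residual around the FFN
  b1 <- layernorm_backward(cache$ln1, dln1)
  g[[paste0(pre, "ln1_gamma")]] <- b1$dgamma
  g[[paste0(pre, "ln1_beta")]] <- b1$dbeta
  bm <- mha_backward(cache$mha, params, b1$dx)
  g <- c(g, bm$grads)
  list(dx = b1$dx + bm$dx, grads = g)    # residual around the MHA
}

# ---- CNN over a stack of windows -------------------------------------------

# Stacked im2col index: B contiguous window blocks of length T_, padding taps
# pointing at the global zero row B*T_ + 1.
stack_conv_index <- function(T_, k, B) {
  idx1 <- conv_index(T_, k)
  pad <- idx1 == T_ + 1L
  out <- matrix(0L, B * T_, k)
  for (b in seq_len(B)) {
    blk <- idx1 + (b - 1L) * T_
    blk[pad] <- B * T_ + 1L
    out[((b - 1L) * T_ + 1L):(b * T_), ] <- blk
  }
  out
}

# x: (B*T) x 12 stacked windows. Returns per-window features (B x feat_dim).
cnn_forward <- function(x, B, model, training) {
  config <- model$config
  params <- model$params
  caches <- list()
  T_ <- nrow(x) %/% B
  for (i in seq_along(config$conv_layers)) {
    cl <- config$conv_layers[[i]]
    idx <- stack_conv_index(T_, cl[[2]], B)
    cv <- conv1d_forward(x, params[[sprintf("conv%d_W", i)]],
                         params[[sprintf("conv%d_b", i)]], idx)
    bn <- batchnorm_forward(cv$out, params[[sprintf("bn%d_gamma", i)]],
                            params[[sprintf("bn%d_beta", i)]],
                            model$bn_running[[i]], training)
    model$bn_running[[i]] <- bn$running
    rl <- relu_forward(bn$out)
    if (cl[[3]] > 1L) {
      mp <- maxpool_forward(rl$out, cl[[3]])
      x <- mp$out
      mp_cache <- mp$cache
    } else {
      x <- rl$out
      mp_cache <- NULL
    }
    caches[[i]] <- list(cv = cv$cache, bn = bn$cache, rl = rl$cache,
                        mp = mp_cache)
    T_ <- T_ %/% cl[[3]]
  }
  C_ <- ncol(x)
  # flatten each window block (T_ x C_) to one row, time-major within channel
  arr <- array(x, dim = c(T_, B, C_))
  flat <- t(matrix(aperm(arr, c(1, 3, 2)), ncol = B))
  fc <- linear_forward(flat, params$cnnfc_W, params$cnnfc_b)
  list(features = fc$out, bn_running = model$bn_running,
       cache = list(conv = caches, fc = fc$cache, T_f = T_, C_f = C_, B = B))
}

cnn_backward <- function(cache, model, dfeat) {
  params <- model$params
  g <- list()
  bfc <- linear_backward(cache$fc, dfeat)
  g$cnnfc_W <- bfc$dW
  g$cnnfc_b <- bfc$db
  arr <- array(t(bfc$dx), dim = c(cache$T_f, cache$C_f, cache$B))
  dx <- matrix(aperm(arr, c(1, 3, 2)), ncol = cache$C_f)
  for (i in rev(seq_along(model$config$conv_layers))) {
    cc <- cache$conv[[i]]
    if (!is.null(cc$mp)) dx <- maxpool_backward(cc$mp, dx)
    dx <- relu_backward(cc$rl, dx)
    bb <- batchnorm_backward(cc$bn, dx)
    g[[sprintf("bn%d_gamma", i)]] <- bb$dgamma
    g[[sprintf("bn%d_beta", i)]] <- bb$dbeta
    bc <- conv1d_backward(cc$cv, bb$dx)
    g[[sprintf("conv%d_W", i)]] <- bc$dW
    g[[sprintf("conv%d_b", i)]] <- bc$db
    dx <- bc$dx
  }
  g
}

#' Per-window CNN features for one segment stack
#'
#' Applies the convolutional feature extractor independently to every window
#' of a record, in evaluation mode (batch-norm running statistics).
#'
#' @param stack A `segment_stack` from [segment_record()].
#' @param model An [model_init()] model.
#' @return `n_windows x cnn_feature_dim` feature matrix.
#' @export
cnn_extract <- function(stack, model) {
  if (dim(stack$segments)[3] != model$config$window_size) {
    stop(sprintf("window length %d does not match the model's expected %d",
                 dim(stack$segments)[3], model$config$window_size),
         call. = FALSE)
  }
  x <- stack_windows(list(stack))
  cnn_forward(x$x, x$B, model, training = FALSE)$features
}

# Stack all windows of a list of segment_stacks into one (B_total*W) x 12
# matrix (rows = samples, window blocks contiguous) + per-record window counts.
stack_windows <- function(stacks) {
  counts <- vapply(stacks, function(s) dim(s$segments)[1], integer(1))
  W <- dim(stacks[[1]]$segments)[3]
  blocks <- lapply(stacks, function(s) {
    nw <- dim(s$segments)[1]
    do.call(rbind, lapply(seq_len(nw), function(w) t(s$segments[w, , ])))
  })
  list(x = do.call(rbind, blocks), B = sum(counts), counts = counts, W = W)
}

# ---- full forward / backward -----------------------------------------------

#' Forward pass over a batch of segmented records
#'
#' CNN per window (batched across the whole stack), linear projection to
#' `d_model`, positional encoding, `n_encoder_layers` encoder layers per
#' record, pooling over tokens to one embedding per record, classification
#' head with softmax.
#'
#' @param model An `ecg_model`.
#' @param stacks List of `segment_stack` objects (one per record).
#' @param training Logical; training mode uses batch statistics for batch
#'   norm and updates running statistics.
#' @return List with `probs` (`n_records x n_classes`, rows sum to 1),
#'   `embeddings` (`n_records x d_model`), `model` (with updated batch-norm
#'   running statistics), and `cache` (for [model_backward()]).
#' @export
model_forward <- function(model, stacks, training = FALSE) {
  config <- model$config
  params <- model$params
  sw <- stack_windows(stacks)
  if (sw$W != config$window_size) {
    stop(sprintf("window length %d does not match the model's expected %d",
                 sw$W, config$window_size), call. = FALSE)
  }
  cf <- cnn_forward(sw$x, sw$B, model, training)
  model$bn_running <- cf$bn_running
  pj <- linear_forward(cf$features, params$proj_W, params$proj_b)
  # split tokens per record, add positional encoding, run the encoder stack
  ends <- cumsum(sw$counts)
  starts <- ends - sw$counts + 1L
  R <- length(stacks)
  emb <- matrix(0, R, config$d_model)
  rec_caches <- vector("list", R)
  pe_full <- positional_encoding(max(sw$counts), config$d_model,
                                 config$pe_odd_sin)
  for (r in seq_len(R)) {
    tok <- pj$out[starts[r]:ends[r], , drop = FALSE] +
      pe_full[seq_len(sw$counts[r]), , drop = FALSE]
    layer_caches <- vector("list", config$n_encoder_layers)
    for (l in seq_len(config$n_encoder_layers)) {
      el <- encoder_layer_forward(tok, params, sprintf("enc%d_", l), config)
      tok <- el$out
      layer_caches[[l]] <- el$cache
    }
    emb[r, ] <- if (config$pooling == "mean") colMeans(tok) else tok[1, ]
    rec_caches[[r]] <- list(layers = layer_caches, n_tok = sw$counts[r])
  }
  c1 <- linear_forward(emb, params$cls_W1, params$cls_b1)
  a1 <- relu_forward(c1$out)
  c2 <- linear_forward(a1$out, params$cls_W2, params$cls_b2)
  probs <- softmax_rows(c2$out)
  list(probs = probs, embeddings = emb, model = model,
       cache = list(cnn = cf$cache, pj = pj$cache, rec = rec_caches,
                    starts = starts, ends = ends,
                    c1 = c1$cache, a1 = a1$cache, c2 = c2$cache,
                    n_tokens_total = sw$B))
}

#' Backward pass: gradients of the total loss w.r.t. all parameters
#'
#' @param model An `ecg_model`.
#' @param cache Cache from [model_forward()] (training mode).
#' @param dlogits Gradient at the pre-softmax classifier output
#'   (`n_records x n_classes`; for cross-entropy this is
#'   `(probs - onehot) / n_records`).
#' @param dembed_extra Extra gradient arriving directly at the embeddings
#'   (`n_records x d_model`), e.g. from the link penalty; or `NULL`.
#' @return Named list of parameter gradients matching `model$params`.
#' @export
model_backward <- function(model, cache, dlogits, dembed_extra = NULL) {
  config <- model$config
  params <- model$params
  g <- list()
  b2 <- linear_backward(cache$c2, dlogits)
  g$cls_W2 <- b2$dW; g$cls_b2 <- b2$db
  da1 <- relu_backward(cache$a1, b2$dx)
  b1 <- linear_backward(cache$c1, da1)
  g$cls_W1 <- b1$dW; g$cls_b1 <- b1$db
  demb <- b1$dx
  if (!is.null(dembed_extra)) demb <- demb + dembed_extra
  dtok_all <- matrix(0, cache$n_tokens_total, config$d_model)
  for (r in seq_along(cache$rec)) {
    rc <- cache$rec[[r]]
    n_tok <- rc$n_tok
    dtok <- if (config$pooling == "mean") {
      matrix(demb[r, ] / n_tok, n_tok, config$d_model, byrow = TRUE)
    } else {
      m <- matrix(0, n_tok, config$d_model)
      m[1, ] <- demb[r, ]
      m
    }
    for (l in rev(seq_len(config$n_encoder_layers))) {
      bl <- encoder_layer_backward(rc$layers[[l]], params, dtok)
      dtok <- bl$dx
      g <- acc_grads(g, bl$grads)
    }
    dtok_all[cache$starts[r]:cache$ends[r], ] <- dtok
  }
  bp <- linear_backward(cache$pj, dtok_all)
  g$proj_W <- bp$dW; g$proj_b <- bp$db
  g <- c(g, cnn_backward(cache$cnn, model, bp$dx))
  g
}

#' Class probabilities for a batch of records
#'
#' Evaluation-mode forward pass (deterministic given fixed weights).
#'
#' @param model An `ecg_model`.
#' @param stacks List of `segment_stack` objects.
#' @return List with `probs`, `predicted` (0-based labels), `embeddings`.
#' @export
model_predict <- function(model, stacks) {
  fw <- model_forward(model, stacks, training = FALSE)
  list(probs = fw$probs,
       predicted = max.col(fw$probs, ties.method = "first") - 1L,
       embeddings = fw$embeddings)
}

#' Layer-by-layer description of a model
#'
#' @param model An `ecg_model`.
#' @return Data frame with one row per layer: name, output shape, parameters.
#' @export
describe_model <- function(model) {
  config <- model$config
  rows <- list()
  T_ <- config$window_size
  cin <- N_LEADS
  for (i in seq_along(config$conv_layers)) {
    cl <- config$conv_layers[[i]]
    T_ <- T_ %/% cl[[3]]
    rows[[length(rows) + 1]] <- data.frame(
      layer = sprintf("conv_block_%d (k=%d, pool=%d)", i, cl[[2]], cl[[3]]),
      output = sprintf("%d x %d", T_, cl[[1]]),
      params = cl[[2]] * cin * cl[[1]] + 3L * cl[[1]])
    cin <- cl[[1]]
  }
  add <- function(name, out, np) {
    rows[[length(rows) + 1]] <<- data.frame(layer = name, output = out,
                                            params = np)
  }
  flat <- T_ * cin
  add("flatten + linear", sprintf("%d", config$cnn_feature_dim),
      flat * config$cnn_feature_dim + config$cnn_feature_dim)
  add("token projection", sprintf("%d", config$d_model),
      config$cnn_feature_dim * config$d_model + config$d_model)
  d <- config$d_model
  per_layer <- 4L * (d * d + d) + 2L * d * config$ffn_hidden +
    config$ffn_hidden + d + 4L * d
  add(sprintf("encoder x %d (heads=%d, ffn=%d)", config$n_encoder_layers,
              config$n_heads, config$ffn_hidden),
      sprintf("n_windows x %d", d), config$n_encoder_layers * per_layer)
  add(sprintf("pooling (%s)", config$pooling), sprintf("%d", d), 0L)
  add("classifier", sprintf("%d", config$n_classes),
      d * config$classifier_hidden + config$classifier_hidden +
        config$classifier_hidden * config$n_classes + config$n_classes)
  do.call(rbind, rows)
}
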