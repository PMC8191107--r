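# Neural-network primitives: forward and backward passes written as explicit
# matrix code, plus Adam. Each forward returns list(out, cache); each backward
# takes (cache, grad_out) and returns list(dx, and parameter gradients).
#
# Conventions: activations are row-major matrices (rows = positions/samples,
# columns = channels/features); convolution is 1-D with 'same' zero padding
# (odd kernel sizes) realized by im2col so both passes are matrix products.

init_matrix <- function(nin, nout) {
  # Glorot/fan-average uniform
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

# ---- conv1d ----------------------------------------------------------------

# Builds the im2col row-index matrix for a window of length T and kernel k
# ('same' zero padding). Row t, tap j -> source sample index, or T+1 for the
# virtual zero row appended to the input.
conv_index <- function(T_, k) {
  pad <- (k - 1L) %/% 2L
  idx <- outer(seq_len(T_), seq_len(k) - 1L - pad, `+`)
  idx[idx < 1L | idx > T_] <- T_ + 1L
  idx
}

# x: T x Cin; W: (k*Cin) x Cout (tap-major: tap j block = columns of channel);
# returns T x Cout.
conv1d_forward <- function(x, W, b, idx) {
  k <- ncol(idx)
  xz <- rbind(x, 0)                       # virtual zero row for padding
  xcol <- do.call(cbind, lapply(seq_len(k), function(j) xz[idx[, j], , drop = FALSE]))
  out <- xcol %*% W
  out <- sweep(out, 2, b, `+`)
  list(out = out, cache = list(xcol = xcol, W = W, idx = idx,
                               T_ = nrow(x), Cin = ncol(x)))
}

conv1d_backward <- function(cache, dout) {
  k <- ncol(cache$idx)
  Cin <- cache$Cin
  dW <- crossprod(cache$xcol, dout)
  db <- colSums(dout)
  dxcol <- dout %*% t(cache$W)
  dx <- matrix(0, cache$T_, Cin)
  for (j in seq_len(k)) {
    cols <- ((j - 1L) * Cin + 1L):(j * Cin)
    src <- cache$idx[, j]
    ok <- src <= cache$T_                 # drop padding taps
    dx[src[ok], ] <- dx[src[ok], ] + dxcol[ok, cols, drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

# ---- batch normalization (per channel over all rows of the stack) ----------

batchnorm_forward <- function(x, gamma, beta, running, training,
                              momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2, mu)^2)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(x, 2, mu), 2, inv, `*`)
  out <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(out = out, running = running,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, training = training))
}

batchnorm_backward <- function(cache, dout) {
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  if (cache$training) {
    N <- nrow(dout)
    dxhat <- sweep(dout, 2, cache$gamma, `*`)
    dx <- sweep(dxhat - matrix(colMeans(dxhat), N, ncol(dout), byrow = TRUE) -
                  xhat * matrix(colMeans(dxhat * xhat), N, ncol(dout), byrow = TRUE),
                2, cache$inv, `*`)
  } else {
    dx <- sweep(sweep(dout, 2, cache$gamma, `*`), 2, cache$inv, `*`)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- ReLU ------------------------------------------------------------------

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(cache, dout) dout * cache

# ---- max pooling (non-overlapping, along rows, per window) -----------------

# x: (B*T) x C with all windows the same length T divisible by p; windows are
# contiguous row blocks, so pooling groups never straddle a window boundary.
maxpool_forward <- function(x, p) {
  N <- nrow(x); C <- ncol(x)
  G <- N %/% p
  out <- matrix(0, G, C)
  arg <- matrix(0L, G, C)
  for (ch in seq_len(C)) {
    m <- matrix(x[, ch], nrow = p)
    mx <- m[1, ]; am <- rep(1L, G)
    if (p > 1) for (i in 2:p) {
      upd <- m[i, ] > mx
      mx[upd] <- m[i, upd]
      am[upd] <- i
    }
    out[, ch] <- mx
    arg[, ch] <- am
  }
  list(out = out, cache = list(arg = arg, p = p, N = N))
}

maxpool_backward <- function(cache, dout) {
  p <- cache$p
  G <- nrow(dout); C <- ncol(dout)
  dx <- matrix(0, cache$N, C)
  rows <- (seq_len(G) - 1L) * p
  for (ch in seq_len(C)) {
    dx[cbind(rows + cache$arg[, ch], ch)] <- dout[, ch]
  }
  dx
}

# ---- linear ----------------------------------------------------------------

linear_forward <- function(x, W, b) {
  out <- sweep(x %*% W, 2, b, `+`)
  list(out = out, cache = list(x = x, W = W))
}

linear_backward <- function(cache, dout) {
  list(dx = dout %*% t(cache$W),
       dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

# ---- layer normalization (per row over features) ---------------------------

layernorm_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(out = out, cache = list(xhat = xhat, inv = inv, gamma = gamma))
}

layernorm_backward <- function(cache, dout) {
  xhat <- cache$xhat
  D <- ncol(dout)
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, cache$gamma, `*`)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- softmax ---------------------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- Adam ------------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_update <- function(params, grads, state, lr = 1e-3,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Accumulate gradient lists (same names) in place.
acc_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) {
    acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
  }
  acc
}
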