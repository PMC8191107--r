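# Multilevel discrete wavelet transform with symmetric signal extension.
#
# Analysis keeps floor((n + f - 1)/2) coefficients per band (f = filter
# length), a redundant boundary representation under which synthesis-and-crop
# is an exact left inverse for any signal length, so reconstruction from
# unmodified coefficients reproduces the input to machine precision.

# bior2.6 biorthogonal spline wavelet filter bank (filter length 14).
BIOR26 <- local({
  dec_lo <- c(0, -0.006905339660024878, 0.013810679320049757,
              0.04695630968816917, -0.1077232986963881, -0.16987135563661201,
              0.4474660099696121, 0.966747552403483, 0.4474660099696121,
              -0.16987135563661201, -0.1077232986963881, 0.04695630968816917,
              0.013810679320049757, -0.006905339660024878)
  dec_hi <- c(0, 0, 0, 0, 0, 0.3535533905932738, -0.7071067811865476,
              0.3535533905932738, 0, 0, 0, 0, 0, 0)
  # synthesis filters: quadrature mirror of the analysis pair
  rec_lo <- c(0, 0, 0, 0, 0, 0.3535533905932738, 0.7071067811865476,
              0.3535533905932738, 0, 0, 0, 0, 0, 0)
  rec_hi <- c(0, 0.006905339660024878, 0.013810679320049757,
              -0.04695630968816917, -0.1077232986963881, 0.16987135563661201,
              0.4474660099696121, -0.966747552403483, 0.4474660099696121,
              0.16987135563661201, -0.1077232986963881, -0.04695630968816917,
              0.013810679320049757, 0.006905339660024878)
  list(dec_lo = dec_lo, dec_hi = dec_hi, rec_lo = rec_lo, rec_hi = rec_hi)
})

wavelet_filters <- function(wavelet_name) {
  if (!identical(wavelet_name, "bior2.6")) {
    stop(sprintf("unsupported wavelet '%s' (available: bior2.6)", wavelet_name),
         call. = FALSE)
  }
  BIOR26
}

# Symmetric (half-point, edge-repeating) extension: x2 x1 | x1 .. xn | xn xn-1
sym_ext <- function(x, e) {
  n <- length(x)
  m <- seq.int(1 - e, n + e)
  k <- (m - 1) %% (2 * n)
  k <- ifelse(k < 0, k + 2 * n, k)
  idx <- ifelse(k < n, k + 1, 2 * n - k)
  x[idx]
}

# One analysis step: returns approximation and detail coefficients of length
# floor((n + f - 1)/2).
dwt_step <- function(x, filters) {
  f <- length(filters$dec_lo)
  n <- length(x)
  ext <- sym_ext(x, f - 1)           # length n + 2(f-1)
  kmax <- n + f - 1
  ylo <- numeric(kmax)
  yhi <- numeric(kmax)
  ks <- seq_len(kmax)
  for (j in seq_len(f)) {
    seg <- ext[ks - j + f]
    ylo <- ylo + filters$dec_lo[j] * seg
    yhi <- yhi + filters$dec_hi[j] * seg
  }
  ds <- seq.int(2, kmax, by = 2)
  list(cA = ylo[ds], cD = yhi[ds])
}

# One synthesis step: exact inverse of dwt_step for unmodified coefficients;
# output length 2*L - f + 2 (callers truncate to the stored input length).
idwt_step <- function(cA, cD, filters) {
  f <- length(filters$rec_lo)
  L <- length(cA)
  stopifnot(length(cD) == L)
  up <- function(cf) {
    u <- numeric(2 * L)
    u[seq.int(1, 2 * L, by = 2)] <- cf
    u
  }
  full_conv <- function(u, flt) {
    nu <- length(u)
    out <- numeric(nu + f - 1)
    for (j in seq_len(f)) {
      out[seq.int(j, j + nu - 1)] <- out[seq.int(j, j + nu - 1)] + flt[j] * u
    }
    out
  }
  y <- full_conv(up(cA), filters$rec_lo) + full_conv(up(cD), filters$rec_hi)
  # crop the boundary transient: f-2 leading, f-1 trailing samples
  y[seq.int(f - 1, length(y) - (f - 1))]
}

min_length_for_levels <- function(n_levels, f = 14L) {
  # each analysis level needs at least one full filter support
  as.integer(f * 2^(n_levels - 1))
}

#' Multilevel wavelet decomposition of one channel
#'
#' @param x Numeric vector.
#' @param n_levels Number of decomposition levels.
#' @param wavelet_name Wavelet family (currently `"bior2.6"`).
#' @return List with `approx` (coarsest approximation), `details` (list,
#'   element `i` = detail coefficients at level `i`, level 1 = finest),
#'   `lengths` (input length at each level, used for exact reconstruction),
#'   and `wavelet_name`.
#' @export
wavedec <- function(x, n_levels = 6, wavelet_name = "bior2.6") {
  filters <- wavelet_filters(wavelet_name)
  f <- length(filters$dec_lo)
  need <- min_length_for_levels(n_levels, f)
  if (length(x) < need) {
    stop(sprintf(
      "signal length %d too short for %d-level %s decomposition (minimum %d samples)",
      length(x), n_levels, wavelet_name, need), call. = FALSE)
  }
  details <- vector("list", n_levels)
  lengths <- integer(n_levels)
  a <- x
  for (lev in seq_len(n_levels)) {
    lengths[lev] <- length(a)
    st <- dwt_step(a, filters)
    details[[lev]] <- st$cD
    a <- st$cA
  }
  list(approx = a, details = details, lengths = lengths,
       wavelet_name = wavelet_name)
}

#' Multilevel wavelet reconstruction
#'
#' Inverse of [wavedec()]; exact to machine precision when coefficients are
#' unmodified.
#'
#' @param decomposition A list as returned by [wavedec()].
#' @return Numeric vector of the original length.
#' @export
waverec <- function(decomposition) {
  filters <- wavelet_filters(decomposition$wavelet_name)
  a <- decomposition$approx
  n_levels <- length(decomposition$details)
  for (lev in rev(seq_len(n_levels))) {
    a <- idwt_step(a, decomposition$details[[lev]], filters)
    n_target <- decomposition$lengths[lev]
    a <- a[seq_len(n_target)]
  }
  a
}
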