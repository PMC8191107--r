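# Signal conditioning: difference-method outlier clipping, six-level bior2.6
# wavelet denoising (zero detail levels 1-2 and the level-6 approximation),
# and fixed-window segmentation of variable-length records.

#' Preprocessing configuration
#'
#' @param wavelet_name Wavelet family for denoising (default `"bior2.6"`).
#' @param n_levels Decomposition depth (default 6).
#' @param zeroed_detail_levels Detail levels set to zero; level 1 is the
#'   finest (highest-frequency) band. Default `c(1, 2)` removes high-frequency
#'   noise (muscle/EMG band).
#' @param zero_final_approximation Zero the coarsest approximation? Default
#'   `TRUE`: at 500 Hz with 6 levels this removes the 0-3.9 Hz band where
#'   baseline wander lives.
#' @param outlier_rule Threshold rule for outlier clipping: `"mad"`
#'   (median + k * MAD of |signal| per channel, robust default),
#'   `"percentile"` (the `outlier_q` quantile of |signal|), or `"fixed"`
#'   (absolute threshold `outlier_fixed` mV).
#' @param outlier_k Multiplier for the MAD rule (default 8).
#' @param outlier_q Quantile for the percentile rule (default 0.999).
#' @param outlier_fixed Threshold in mV for the fixed rule.
#' @param window_size Segment length in samples (default 3000 = 6 s at 500 Hz).
#' @param step_size Hop between segment starts in samples (default 1500).
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(wavelet_name = "bior2.6", n_levels = 6,
                              zeroed_detail_levels = c(1, 2),
                              zero_final_approximation = TRUE,
                              outlier_rule = c("mad", "percentile", "fixed"),
                              outlier_k = 8, outlier_q = 0.999,
                              outlier_fixed = 5,
                              window_size = 3000, step_size = 1500) {
  outlier_rule <- match.arg(outlier_rule)
  stopifnot(n_levels >= 1, window_size > 0, step_size > 0,
            step_size <= window_size)
  if (length(zeroed_detail_levels) > 0 &&
      max(zeroed_detail_levels) > n_levels) {
    stop("zeroed_detail_levels must not exceed n_levels", call. = FALSE)
  }
  structure(list(
    wavelet_name = wavelet_name, n_levels = as.integer(n_levels),
    zeroed_detail_levels = as.integer(zeroed_detail_levels),
    zero_final_approximation = isTRUE(zero_final_approximation),
    outlier_rule = outlier_rule, outlier_k = outlier_k,
    outlier_q = outlier_q, outlier_fixed = outlier_fixed,
    window_size = as.integer(window_size), step_size = as.integer(step_size)
  ), class = "preprocess_config")
}

outlier_threshold <- function(x, config) {
  switch(config$outlier_rule,
    mad = {
      a <- abs(x)
      m <- stats::mad(a)
      if (m == 0) return(NA_real_)  # constant channel: rule undefined
      stats::median(a) + config$outlier_k * m
    },
    percentile = stats::quantile(abs(x), config$outlier_q, names = FALSE),
    fixed = config$outlier_fixed
  )
}

#' Clip large-amplitude outliers to a per-channel threshold
#'
#' Spike artifacts carry voltages far above physiological range. For each
#' channel a threshold is set from the complete signal (per `outlier_rule`);
#' every sample whose magnitude exceeds it is replaced by the signed
#' threshold, so `max(|output|) <= threshold` channel-wise.
#'
#' @param record An [ecg_record()].
#' @param config A [preprocess_config()].
#' @return The clipped record, with attribute `thresholds` (per-channel, mV).
#' @export
remove_outliers <- function(record, config = preprocess_config()) {
  sig <- record$signal
  thr <- numeric(nrow(sig))
  for (ch in seq_len(nrow(sig))) {
    th <- outlier_threshold(sig[ch, ], config)
    thr[ch] <- th
    if (is.na(th)) {
      warning(sprintf(
        "record '%s' channel %d: constant channel, outlier threshold undefined; left unchanged",
        record$record_id, ch), call. = FALSE)
      next
    }
    sig[ch, ] <- pmin(pmax(sig[ch, ], -th), th)
  }
  out <- ecg_record(record$record_id, sig, fs = record$fs, label = record$label)
  attr(out, "thresholds") <- thr
  out
}

#' Wavelet denoising of a 12-lead record
#'
#' Per channel: `n_levels`-level discrete wavelet decomposition with
#' `wavelet_name`, zero the detail coefficients at `zeroed_detail_levels`
#' (high-frequency noise) and, if configured, the final approximation
#' (baseline drift), then reconstruct. Output length equals input length.
#' All coefficient operations are linear, so the operator itself is linear.
#'
#' @param record An [ecg_record()].
#' @param config A [preprocess_config()].
#' @return The denoised record.
#' @export
wavelet_denoise <- function(record, config = preprocess_config()) {
  sig <- record$signal
  out <- matrix(0, nrow(sig), ncol(sig))
  for (ch in seq_len(nrow(sig))) {
    d <- wavedec(sig[ch, ], n_levels = config$n_levels,
                 wavelet_name = config$wavelet_name)
    for (lev in config$zeroed_detail_levels) {
      d$details[[lev]] <- d$details[[lev]] * 0
    }
    if (config$zero_final_approximation) {
      d$approx <- d$approx * 0
    }
    out[ch, ] <- waverec(d)
  }
  ecg_record(record$record_id, out, fs = record$fs, label = record$label)
}

#' Number of fixed-length windows in a record
#'
#' @param n_samples Record length in samples.
#' @param window_size Window length in samples.
#' @param step_size Hop in samples.
#' @return `floor((n_samples - window_size) / step_size) + 1` for
#'   `n_samples >= window_size`.
#' @export
n_windows <- function(n_samples, window_size, step_size) {
  if (n_samples < window_size) return(0L)
  as.integer((n_samples - window_size) %/% step_size + 1L)
}

#' Split a record into fixed-length windows
#'
#' Windows start at offsets `0, step, 2*step, ...`; samples after the last
#' full window are dropped. At the default settings (window 3000, step 1500,
#' 500 Hz) the 6-s corpus minimum yields exactly one window.
#'
#' @param record An [ecg_record()] (normally already preprocessed).
#' @param config A [preprocess_config()] providing `window_size`/`step_size`.
#' @return Object of class `segment_stack`: list with `record_id`, `segments`
#'   (array `n_windows x 12 x window_size`), `label`, `fs`.
#' @export
segment_record <- function(record, config = preprocess_config()) {
  W <- config$window_size
  S <- config$step_size
  T_ <- ncol(record$signal)
  if (T_ < W) {
    stop(sprintf(
      "record '%s': %d samples shorter than window_size %d; cannot segment",
      record$record_id, T_, W), call. = FALSE)
  }
  nw <- n_windows(T_, W, S)
  segs <- array(0, dim = c(nw, N_LEADS, W))
  for (w in seq_len(nw)) {
    off <- (w - 1L) * S
    segs[w, , ] <- record$signal[, (off + 1L):(off + W)]
  }
  structure(list(record_id = record$record_id, segments = segs,
                 label = record$label, fs = record$fs),
            class = "segment_stack")
}

#' Full signal conditioning for one record
#'
#' Pipeline order: outlier clipping, then wavelet denoising. Segmentation is
#' left to [segment_record()] so callers can inspect the conditioned signal.
#'
#' @param record An [ecg_record()].
#' @param config A [preprocess_config()].
#' @return The conditioned record.
#' @export
preprocess_record <- function(record, config = preprocess_config()) {
  wavelet_denoise(remove_outliers(record, config), config)
}

#' Preprocess and segment a whole dataset
#'
#' @param dataset An `ecg_dataset`.
#' @param config A [preprocess_config()].
#' @return List of `segment_stack` objects, one per record.
#' @export
preprocess_dataset <- function(dataset, config = preprocess_config()) {
  lapply(dataset, function(rec) {
    segment_record(preprocess_record(rec, config), config)
  })
}

# Periodogram power in (0, f_hi] Hz (mean removed, so DC is excluded).
band_power <- function(x, fs, f_hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2
  freqs <- (seq_len(n) - 1) * fs / n
  half <- seq_len(floor(n / 2))
  sum(sp[half][freqs[half] <= f_hi])
}
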