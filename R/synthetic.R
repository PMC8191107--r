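# Class-conditional synthetic 12-lead ECG generator.
#
# Beats are cartoon P-QRS-T cycles built from Gaussian bumps plus a smoothed
# ST-segment plateau; classes are distinguished by the interval/offset
# parameters that define them clinically (PR interval for first-degree AV
# block, ST offset for STD/STE, QRS width for bundle-branch blocks, ...).
# One per-lead amplitude vector scales the common waveform across the 12
# leads. All randomness flows from the seed carried in the spec.

#' Specification of a synthetic 12-lead ECG dataset
#'
#' Defines the study conditions the generator emulates: 12 channels at 500 Hz,
#' record durations between 6 and 60 s, one of up to 9 arrhythmia classes per
#' record, and the three noise processes the preprocessing stage targets
#' (sub-hertz sinusoidal baseline wander, zero-mean high-frequency noise, and
#' sparse large-amplitude spike artifacts).
#'
#' @param n_records Number of records to generate.
#' @param n_classes Number of classes used (first `n_classes` of
#'   [ecg_classes()], at most 9).
#' @param fs Sampling rate, samples/second.
#' @param duration_range Length-2 numeric, record duration bounds in seconds;
#'   must lie within `[6, 60]`.
#' @param baseline_amp Baseline-wander amplitude, mV.
#' @param baseline_freq Baseline-wander frequency, Hz (must be below 0.5).
#' @param hf_noise_sd Standard deviation of the high-frequency noise, mV.
#' @param spike_rate Expected spike-artifact count per second of record.
#' @param spike_amp Spike amplitude, mV (much larger than the QRS amplitude).
#' @param seed Integer seed; identical spec + seed gives bit-identical output.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_records = 100, n_classes = 9, fs = 500,
                           duration_range = c(6, 60),
                           baseline_amp = 0.3, baseline_freq = 0.2,
                           hf_noise_sd = 0.05, spike_rate = 0.1,
                           spike_amp = 8, seed = 1L) {
  stopifnot(n_records >= 1, n_classes >= 1, n_classes <= 9, fs > 0,
            length(duration_range) == 2,
            duration_range[1] <= duration_range[2])
  if (duration_range[1] < 6 || duration_range[2] > 60) {
    stop("duration_range must lie within [6, 60] seconds", call. = FALSE)
  }
  if (baseline_freq >= 0.5) {
    stop("baseline_freq must be below 0.5 Hz (baseline wander band)",
         call. = FALSE)
  }
  structure(list(
    n_records = as.integer(n_records), n_classes = as.integer(n_classes),
    fs = fs, duration_range = as.numeric(duration_range),
    baseline_amp = baseline_amp, baseline_freq = baseline_freq,
    hf_noise_sd = hf_noise_sd, spike_rate = spike_rate,
    spike_amp = spike_amp, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# Per-lead projection of the common beat waveform; signs/magnitudes loosely
# follow typical limb/precordial lead polarity.
LEAD_GAINS <- c(0.60, 1.00, 0.45, -0.75, 0.30, 0.70,
                -0.35, 0.50, 0.80, 1.05, 0.95, 0.85)

#' Morphology parameters that define each arrhythmia class
#'
#' The generator's defining parameters at cartoon level: PR interval (s),
#' ST-segment offset (mV), QRS width scale, P-wave amplitude (mV), an R'
#' bump amplitude (RBBB), RR-interval jitter fraction, and the probability
#' that a beat is an ectopic (premature, wide, P-less) beat.
#'
#' @param class_id Class name (see [ecg_classes()]) or integer label in 0..8.
#' @return Named list of beat parameters.
#' @export
beat_params <- function(class_id) {
  cls <- resolve_class(class_id)
  p <- list(pr_interval = 0.16, st_offset = 0, qrs_width_scale = 1,
            p_amp = 0.15, rprime_amp = 0, rr_jitter = 0.03,
            ectopic_prob = 0, r_amp = 1.0, t_amp = 0.30)
  switch(cls,
    "normal" = p,
    "AF"     = { p$p_amp <- 0; p$rr_jitter <- 0.18; p },
    "I-AVB"  = { p$pr_interval <- 0.26; p },
    "LBBB"   = { p$qrs_width_scale <- 2.6; p$r_amp <- 0.85; p$t_amp <- -0.25; p },
    "RBBB"   = { p$rprime_amp <- 0.55; p$qrs_width_scale <- 1.5; p },
    "PAC"    = { p$ectopic_prob <- 0.35; p$p_amp <- 0.22; p },
    "PVC"    = { p$ectopic_prob <- 0.35; p$qrs_width_scale <- 1.2; p },
    "STD"    = { p$st_offset <- -0.15; p },
    "STE"    = { p$st_offset <- 0.15; p }
  )
}

resolve_class <- function(class_id) {
  classes <- ecg_classes()
  if (is.numeric(class_id)) {
    if (class_id < 0 || class_id > 8) {
      stop(sprintf("unknown class label %s (must be 0..8)", class_id),
           call. = FALSE)
    }
    return(classes[as.integer(class_id) + 1L])
  }
  if (!class_id %in% classes) {
    stop(sprintf("unknown class '%s' (known: %s)", class_id,
                 paste(classes, collapse = ", ")), call. = FALSE)
  }
  class_id
}

gauss_bump <- function(t, amp, center, width) {
  amp * exp(-0.5 * ((t - center) / width)^2)
}

# Smooth plateau between t0 and t1 with raised-cosine edges of width w.
st_plateau <- function(t, t0, t1, w = 0.015) {
  rise <- ifelse(t < t0 - w, 0,
          ifelse(t > t0 + w, 1, 0.5 * (1 + sin(pi * (t - t0) / (2 * w)))))
  fall <- ifelse(t < t1 - w, 1,
          ifelse(t > t1 + w, 0, 0.5 * (1 - sin(pi * (t - t1) / (2 * w)))))
  rise * fall
}

#' Generate one clean P-QRS-T beat
#'
#' Builds a single cardiac cycle for all 12 leads from Gaussian bumps whose
#' parameters come from [beat_params()]. The QRS onset sits at
#' `pr_interval` seconds after the P wave, so the first-degree AV block class
#' carries its defining prolonged PR interval (> 0.2 s), and the ST classes
#' their defining ST-segment offset (|offset| > 0.1 mV).
#'
#' @param class_id Class name or 0-based label.
#' @param fs Sampling rate, samples/second.
#' @param rr RR interval (beat duration) in seconds.
#' @param ectopic If `TRUE`, render the beat as an ectopic (premature-complex)
#'   morphology: no P wave, widened and taller QRS.
#' @return A `12 x round(rr * fs)` matrix in mV, with attribute `params` (the
#'   [beat_params()] used).
#' @export
generate_clean_beat <- function(class_id, fs = 500, rr = 0.8, ectopic = FALSE) {
  p <- beat_params(class_id)
  n <- round(rr * fs)
  t <- (seq_len(n) - 1) / fs
  ws <- p$qrs_width_scale
  p_amp <- p$p_amp
  r_amp <- p$r_amp
  if (ectopic) {
    p_amp <- 0
    ws <- ws * 2
    r_amp <- r_amp * 1.25
  }
  qrs_on <- 0.22 + (p$pr_interval - 0.16)   # shift QRS right for long PR
  p_center <- qrs_on - p$pr_interval + 0.05 # P wave precedes QRS by PR
  r_center <- qrs_on + 0.04 * ws
  s_center <- qrs_on + 0.07 * ws
  st0 <- s_center + 0.03 * ws
  st1 <- st0 + 0.12
  t_center <- st1 + 0.06
  base <- gauss_bump(t, p_amp, p_center, 0.025) +
    gauss_bump(t, -0.12, qrs_on + 0.015 * ws, 0.010 * ws) +
    gauss_bump(t, r_amp, r_center, 0.012 * ws) +
    gauss_bump(t, p$rprime_amp, r_center + 0.045, 0.012) +
    gauss_bump(t, -0.18, s_center, 0.010 * ws) +
    p$st_offset * st_plateau(t, st0, st1) +
    gauss_bump(t, p$t_amp, t_center, 0.045)
  beat <- outer(LEAD_GAINS, base)
  attr(beat, "params") <- p
  beat
}

#' Generate one clean synthetic record
#'
#' Tiles class-conditional beats to a duration drawn uniformly from
#' `spec$duration_range`, with per-beat RR jitter (largest for atrial
#' fibrillation) and random ectopic beats for the premature-complex classes.
#'
#' @param spec A [synthetic_spec()].
#' @param class_id Class name or 0-based label.
#' @param record_id Identifier for the record.
#' @param seed Integer seed for this record (defaults to `spec$seed`).
#' @return An [ecg_record()] with the clean (noise-free) signal.
#' @export
generate_record <- function(spec, class_id, record_id = "rec", seed = spec$seed) {
  cls <- resolve_class(class_id)
  label <- match(cls, ecg_classes()) - 1L
  p <- beat_params(cls)
  with_seed(seed, {
    dur <- runif(1, spec$duration_range[1], spec$duration_range[2])
    n_total <- round(dur * spec$fs)
    gain <- runif(1, 0.9, 1.1)                # per-record amplitude scale
    rr_base <- 60 / runif(1, 62, 95)          # heart rate 62-95 bpm
    sig <- matrix(0, N_LEADS, n_total)
    pos <- 1L
    while (pos <= n_total) {
      rr <- rr_base * (1 + p$rr_jitter * (2 * runif(1) - 1))
      ect <- runif(1) < p$ectopic_prob
      if (ect) rr <- rr * 0.75                # premature beats come early
      beat <- generate_clean_beat(cls, spec$fs, rr = rr, ectopic = ect)
      len <- min(ncol(beat), n_total - pos + 1L)
      sig[, pos:(pos + len - 1L)] <- beat[, seq_len(len)]
      pos <- pos + ncol(beat)
    }
    ecg_record(record_id, gain * sig, fs = spec$fs, label = label)
  })
}

#' Add baseline wander, high-frequency noise, and spike artifacts
#'
#' The three corruptions the preprocessing stage is built to remove:
#' (a) a sinusoidal baseline drift of amplitude `baseline_amp` at
#' `baseline_freq` (< 0.5 Hz, random phase per lead), (b) i.i.d. Gaussian
#' noise of sd `hf_noise_sd`, and (c) Poisson-placed spikes of amplitude
#' `spike_amp`, far above physiological voltages. Corruption is additive and
#' reproducible: the realization is returned in attribute `noise`.
#'
#' @param record A clean [ecg_record()].
#' @param spec A [synthetic_spec()] giving the noise levels.
#' @param seed Integer seed for the noise realization.
#' @return The corrupted record, with attributes `noise` (the added `12 x T`
#'   noise matrix) and `n_spikes` (the Poisson spike-count draw).
#' @export
corrupt_record <- function(record, spec, seed = spec$seed) {
  n <- ncol(record$signal)
  t <- (seq_len(n) - 1) / record$fs
  with_seed(seed, {
    noise <- matrix(0, N_LEADS, n)
    if (spec$baseline_amp > 0) {
      phase <- runif(N_LEADS, 0, 2 * pi)
      for (ch in seq_len(N_LEADS)) {
        noise[ch, ] <- noise[ch, ] +
          spec$baseline_amp * sin(2 * pi * spec$baseline_freq * t + phase[ch])
      }
    }
    if (spec$hf_noise_sd > 0) {
      noise <- noise + matrix(rnorm(N_LEADS * n, sd = spec$hf_noise_sd),
                              N_LEADS, n)
    }
    n_spikes <- 0L
    if (spec$spike_rate > 0 && spec$spike_amp != 0) {
      n_spikes <- rpois(1, spec$spike_rate * n / record$fs)
      if (n_spikes > 0) {
        at <- sample.int(n, n_spikes, replace = TRUE)
        ch <- sample.int(N_LEADS, n_spikes, replace = TRUE)
        sgn <- sample(c(-1, 1), n_spikes, replace = TRUE)
        for (k in seq_len(n_spikes)) {
          noise[ch[k], at[k]] <- noise[ch[k], at[k]] + sgn[k] * spec$spike_amp
        }
      }
    }
    out <- ecg_record(record$record_id, record$signal + noise,
                      fs = record$fs, label = record$label)
    attr(out, "noise") <- noise
    attr(out, "n_spikes") <- as.integer(n_spikes)
    out
  })
}

#' Generate a labelled synthetic dataset
#'
#' Produces `spec$n_records` records with labels spread over the first
#' `spec$n_classes` classes in round-robin order (exactly balanced up to
#' remainder), each clean record corrupted by the spec's noise model when
#' `corrupt = TRUE`. Every record gets its own child seed derived from
#' `spec$seed`, so the dataset is bit-reproducible.
#'
#' @param spec A [synthetic_spec()].
#' @param corrupt Add the noise model on top of the clean signals?
#' @return An `ecg_dataset` (list of [ecg_record()]s). When `corrupt = TRUE`
#'   each record keeps its clean signal in attribute `clean`.
#' @export
generate_dataset <- function(spec, corrupt = TRUE) {
  labels <- rep(seq_len(spec$n_classes) - 1L, length.out = spec$n_records)
  records <- vector("list", spec$n_records)
  for (i in seq_len(spec$n_records)) {
    rid <- sprintf("syn%04d", i)
    rec <- generate_record(spec, labels[i], record_id = rid,
                           seed = derive_seed(spec$seed, paste0("rec", i)))
    if (corrupt) {
      clean <- rec$signal
      rec <- corrupt_record(rec, spec,
                            seed = derive_seed(spec$seed, paste0("noise", i)))
      attr(rec, "clean") <- clean
    }
    records[[i]] <- rec
  }
  new_dataset(records)
}
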