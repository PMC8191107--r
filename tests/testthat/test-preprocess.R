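# Signal conditioning: outlier clipping, wavelet denoising, segmentation.

test_that("outlier clipping replaces exceedances with the signed threshold", {
  sig <- matrix(0, 12, 1000)
  sig[3, ] <- c(0, 0, 10, 0, rep(c(-0.5, 0.5), 498))
  sig[5, 100] <- -20
  rec <- ecg_record("r1", sig, fs = 500)
  cfg <- preprocess_config(outlier_rule = "fixed", outlier_fixed = 1)
  out <- remove_outliers(rec, cfg)
  expect_equal(out$signal[3, 1:4], c(0, 0, 1, 0))
  expect_equal(out$signal[5, 100], -1)
  expect_true(all(abs(out$signal) <= 1))
  # samples below threshold are untouched
  expect_identical(out$signal[3, 5:1000], sig[3, 5:1000])
})

test_that("clipping is the identity when nothing exceeds the threshold", {
  rec <- fixture_record()
  cfg <- preprocess_config(outlier_rule = "fixed", outlier_fixed = 100)
  expect_identical(remove_outliers(rec, cfg)$signal, rec$signal)
})

test_that("MAD thresholds bound every channel and handle constant channels", {
  rec <- fixture_record()
  spec <- synthetic_spec(n_records = 1, duration_range = c(6, 6),
                         baseline_amp = 0, hf_noise_sd = 0.05,
                         spike_rate = 2, spike_amp = 8, seed = 21)
  noisy <- corrupt_record(rec, spec, seed = 21)
  out <- remove_outliers(noisy, preprocess_config())
  thr <- attr(out, "thresholds")
  for (ch in 1:12) expect_lte(max(abs(out$signal[ch, ])), thr[ch] + 1e-12)
  # spikes (8 mV) are far above any MAD threshold of a ~1 mV signal
  expect_true(all(thr < 8))

  flat <- ecg_record("flat", matrix(1, 12, 1000), fs = 500)
  ws <- capture_warnings(out2 <- remove_outliers(flat, preprocess_config()))
  expect_length(ws, 12)                      # one per constant channel
  expect_match(ws, "constant", all = TRUE)
  expect_identical(out2$signal, flat$signal)
})

test_that("denoising zeroes DC and is a no-op with nothing zeroed", {
  const <- ecg_record("dc", matrix(0.7, 12, 3000), fs = 500)
  cfg <- preprocess_config()
  out <- wavelet_denoise(const, cfg)
  expect_lt(max(abs(out$signal)), 1e-10)  # DC lives in the zeroed approximation

  rec <- fixture_record()
  cfg_id <- preprocess_config(zeroed_detail_levels = integer(0),
                              zero_final_approximation = FALSE)
  out_id <- wavelet_denoise(rec, cfg_id)
  expect_equal(out_id$signal, rec$signal, tolerance = 1e-10)
})

test_that("denoising is linear and preserves length", {
  rec <- fixture_record()
  cfg <- preprocess_config()
  d1 <- wavelet_denoise(rec, cfg)
  expect_equal(ncol(d1$signal), ncol(rec$signal))
  scaled <- ecg_record(rec$record_id, 3.5 * rec$signal, fs = rec$fs,
                       label = rec$label)
  d2 <- wavelet_denoise(scaled, cfg)
  expect_equal(d2$signal, 3.5 * d1$signal, tolerance = 1e-10)
})

test_that("denoising removes at least 90% of sub-0.5 Hz wander power", {
  rec <- fixture_record()
  spec <- synthetic_spec(n_records = 1, duration_range = c(6, 6),
                         baseline_amp = 0.5, baseline_freq = 0.2,
                         hf_noise_sd = 0, spike_rate = 0, seed = 17)
  noisy <- corrupt_record(rec, spec, seed = 17)
  den <- wavelet_denoise(noisy, preprocess_config())
  for (ch in c(2, 7, 11)) {
    p_before <- ecglink:::band_power(noisy$signal[ch, ], 500, 0.5)
    p_after <- ecglink:::band_power(den$signal[ch, ], 500, 0.5)
    expect_lt(p_after, 0.1 * p_before)
  }
})

test_that("denoised output tracks the clean signal better than the corrupted input", {
  spec <- synthetic_spec(n_records = 1, duration_range = c(10, 10),
                         baseline_amp = 0.4, baseline_freq = 0.25,
                         hf_noise_sd = 0.08, spike_rate = 0.5, spike_amp = 8,
                         seed = 33)
  clean <- generate_record(spec, "normal", seed = 33)
  noisy <- corrupt_record(clean, spec, seed = 34)
  cond <- preprocess_record(noisy, preprocess_config())
  for (ch in c(2, 9)) {
    r_noisy <- cor(noisy$signal[ch, ], clean$signal[ch, ])
    r_cond <- cor(cond$signal[ch, ], clean$signal[ch, ])
    expect_gt(r_cond, r_noisy)
  }
})

test_that("window counts follow the closed form, including corpus settings", {
  expect_equal(n_windows(3000, 3000, 1500), 1L)
  expect_equal(n_windows(6000, 3000, 1500), 3L)
  expect_equal(n_windows(30000, 3000, 1500), 19L)
  # property over a grid of (T, W, S) with S <= W
  for (T_ in c(3000, 4096, 7001, 30000)) {
    for (W in c(1000, 3000)) {
      for (S in c(250, 1000, W)) {
        expect_equal(n_windows(T_, W, S), floor((T_ - W) / S) + 1)
      }
    }
  }
})

test_that("segmentation returns ordered contiguous slices with the label", {
  spec <- synthetic_spec(n_records = 1, duration_range = c(12, 12), seed = 3)
  rec <- generate_record(spec, "STD", seed = 3)
  cfg <- preprocess_config()
  st <- segment_record(rec, cfg)
  expect_s3_class(st, "segment_stack")
  expect_equal(dim(st$segments), c(3, 12, 3000))
  expect_equal(st$label, 7L)
  for (w in 1:3) {
    off <- (w - 1) * 1500
    expect_identical(st$segments[w, , ], rec$signal[, (off + 1):(off + 3000)])
  }
})

test_that("records shorter than one window are rejected by name", {
  short <- ecg_record("tiny", matrix(0, 12, 2999), fs = 500)
  expect_error(segment_record(short, preprocess_config()), "tiny")
  expect_error(segment_record(short, preprocess_config()), "3000")
})

test_that("config invariants are enforced", {
  expect_error(preprocess_config(step_size = 4000), "step_size")
  expect_error(preprocess_config(zeroed_detail_levels = c(1, 7)), "n_levels")
})
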