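make_noise_rec <- function(seed, n = 8000 * 3, fs = 8000, sigma = 0.1) {
  bpinterp:::with_seed(seed, {
    raw_recording(pmax(pmin(rnorm(n, sd = sigma), 1), -1),
                  sample_rate_hz = fs, silence_lead_s = 1)
  })
}

test_that("STFT analysis-synthesis is an exact round trip", {
  rec <- make_noise_rec(1)
  sf <- stft(rec)
  out <- istft(sf, silence_lead_s = rec$silence_lead_s)
  expect_length(out$samples, length(rec$samples))
  expect_lt(max(abs(out$samples - rec$samples)),
            1e-6 * max(abs(rec$samples)))

  # zero signal -> all-zero frames
  z <- raw_recording(numeric(4000), 8000, 0.2)
  expect_equal(max(Mod(stft(z)$frames)), 0)

  # recording shorter than one frame is rejected
  expect_error(stft(raw_recording(numeric(64), 8000, 0.001)),
               class = "invalid_input")
})

test_that("a bin-centred sinusoid concentrates its frame power", {
  fs <- 8000
  params <- wiener_params()
  g <- bpinterp:::frame_geometry(fs, params)
  bin <- 20
  f0 <- bin * fs / g$frame_len
  t <- (0:(fs * 2 - 1)) / fs
  rec <- raw_recording(0.5 * sin(2 * pi * f0 * t), fs, 0.1)
  sf <- stft(rec, params)
  # an interior frame: fraction of power in the tone bin and neighbours
  p <- Mod(sf$frames[, ncol(sf$frames) %/% 2])^2
  expect_gt(sum(p[bin:(bin + 2)]) / sum(p), 0.95)
})

test_that("noise PSD estimation matches white-noise theory and edge cases", {
  fs <- 8000
  params <- wiener_params()
  g <- bpinterp:::frame_geometry(fs, params)
  w2 <- sum(bpinterp:::hann_periodic(g$frame_len)^2)
  sigma <- 0.05
  rel_err <- vapply(1:10, function(i) {
    rec <- make_noise_rec(i, sigma = sigma)
    psd <- estimate_noise_psd(stft(rec, params), lead_s = 1)
    # interior bins of a one-sided PSD of white noise: E|X|^2 = sigma^2*sum(w^2)
    mean(psd[5:(length(psd) - 5)]) / (sigma^2 * w2) - 1
  }, numeric(1))
  expect_lt(max(abs(rel_err)), 0.2)

  # all-zero lead: floored, never zero
  z <- raw_recording(numeric(4000 * 3), 8000, 1)
  psd0 <- estimate_noise_psd(stft(z), lead_s = 1)
  expect_true(all(psd0 > 0))

  # only frames ending within the lead are used: a loud burst right after
  # the lead must not contaminate the estimate
  x <- numeric(8000 * 3)
  x[8001:8400] <- 0.9
  rec <- raw_recording(x, 8000, 1)
  psd <- estimate_noise_psd(stft(rec), lead_s = 1)
  expect_lt(max(psd), 1e-10)

  expect_error(estimate_noise_psd(stft(make_noise_rec(1)), lead_s = 0.01),
               class = "insufficient_noise_estimate")
})

test_that("decision-directed tracking obeys its recursion and limits", {
  rec <- make_noise_rec(3)
  sf <- stft(rec)
  psd <- estimate_noise_psd(sf, 1)

  # alpha = 0: prior equals max(post - 1, 0) exactly
  tr0 <- decision_directed_snr(sf, psd, alpha = 0)
  expect_equal(tr0$snr_priori, pmax(tr0$snr_posteriori - 1, 0))

  expect_true(all(tr0$snr_priori >= 0))
  expect_true(all(is.finite(tr0$snr_priori)))

  # noise-only input: mean a-priori SNR stays small
  means <- vapply(1:10, function(i) {
    r <- make_noise_rec(100 + i)
    s <- stft(r)
    p <- estimate_noise_psd(s, 1)
    mean(decision_directed_snr(s, p, 0.98)$snr_priori)
  }, numeric(1))
  expect_lt(mean(means), 0.5)

  # stationary high-SNR tone: prior converges to the true bin SNR
  fs <- 8000
  g <- bpinterp:::frame_geometry(fs, wiener_params())
  f0 <- 24 * fs / g$frame_len
  t <- (0:(fs * 3 - 1)) / fs
  tone <- 0.4 * sin(2 * pi * f0 * t)
  tone[1:fs] <- 0
  noise <- bpinterp:::with_seed(9, rnorm(fs * 3, sd = 0.004))
  rec2 <- raw_recording(tone + noise, fs, 1)
  sf2 <- stft(rec2)
  psd2 <- estimate_noise_psd(sf2, 1)
  tr2 <- decision_directed_snr(sf2, psd2, 0.98)
  # true bin SNR from the clean components
  sf_tone <- stft(raw_recording(tone, fs, 1))
  frame_sel <- ncol(sf2$frames) %/% 2  # well past 10 frames into the tone
  bin <- 25
  true_snr <- Mod(sf_tone$frames[bin, frame_sel])^2 / psd2[bin]
  expect_lt(abs(10 * log10(tr2$snr_priori[bin, frame_sel] / true_snr)), 3)

  expect_error(decision_directed_snr(sf, psd, alpha = 1),
               class = "invalid_argument")
})

test_that("Wiener gain follows W = SNR/(SNR+1), floored and monotone", {
  expect_equal(wiener_gain(0), 0)
  expect_equal(wiener_gain(0, gain_floor = 0.05), 0.05)
  expect_equal(wiener_gain(1), 0.5)
  expect_equal(wiener_gain(3), 0.75)
  s <- seq(0, 50, by = 0.25)
  g <- wiener_gain(s, gain_floor = 0.05)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g >= 0.05 & g < 1))
  expect_error(wiener_gain(-1), class = "invalid_argument")
})

test_that("denoising preserves clean signals, length, and zero input", {
  spec <- quick_spec(2)
  env <- render_envelope(spec, duration_s = 8, rate_hz = 100, rng_seed = 1)

  # effectively clean input passes through nearly unchanged
  rec_hi <- render_acoustic(env, 60, sample_rate_hz = 8000, rng_seed = 5)
  den_hi <- denoise_recording(rec_hi)
  expect_gt(cor(den_hi$samples, rec_hi$samples), 0.99)
  expect_length(den_hi$samples, length(rec_hi$samples))
  expect_lte(max(abs(den_hi$samples)), max(abs(rec_hi$samples)) * 1.01)

  # 0 dB input: output SNR strictly exceeds input SNR in every trial here
  gains <- vapply(1:10, function(i) {
    r <- render_acoustic(env, 0, sample_rate_hz = 8000, rng_seed = 200 + i)
    d <- denoise_recording(r)
    clean <- attr(r, "clean")
    measure_snr(clean, d$samples) - measure_snr(clean, r$samples)
  }, numeric(1))
  expect_gt(mean(gains), 0)

  z <- raw_recording(numeric(8000 * 2), 8000, 1)
  expect_equal(denoise_recording(z)$samples, numeric(8000 * 2))
})
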