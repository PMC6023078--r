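# Single-channel Wiener filtering with decision-directed a-priori SNR
# tracking. Noise statistics come from the leading silence of the
# recording (the acquisition protocol guarantees a silent first second),
# under the assumption that background noise is stationary over the
# 10 s window. Enhancement runs at the native 22,050 Hz rate, before any
# sub-sampling.

#' Wiener-filter parameters
#'
#' @param alpha Decision-directed smoothing constant in `[0, 1)`
#'   (default 0.98, the canonical value for speech-band enhancement).
#' @param noise_from_lead_s Portion of the leading silence used for the
#'   noise PSD estimate, seconds (default 1).
#' @param gain_floor Minimum spectral gain in `[0, 1)` (default 0.05,
#'   about -26 dB) to suppress musical noise.
#' @param frame_ms Analysis frame length in milliseconds (default 32).
#' @param hop_frac Hop as a fraction of the frame; only 0.5 is supported
#'   (Hann analysis windows at 50% overlap satisfy constant overlap-add,
#'   so unmodified frames resynthesise the input exactly).
#' @return An object of class `wiener_params`.
#' @export
wiener_params <- function(alpha = 0.98, noise_from_lead_s = 1,
                          gain_floor = 0.05, frame_ms = 32, hop_frac = 0.5) {
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1) {
    stop_bpi("invalid_argument", "alpha must lie in [0, 1)")
  }
  if (!is.numeric(gain_floor) || gain_floor < 0 || gain_floor >= 1) {
    stop_bpi("invalid_argument", "gain_floor must lie in [0, 1)")
  }
  if (hop_frac != 0.5) {
    stop_bpi("invalid_argument",
             "only hop_frac = 0.5 (COLA-compliant Hann framing) is supported")
  }
  structure(list(alpha = alpha, noise_from_lead_s = noise_from_lead_s,
                 gain_floor = gain_floor, frame_ms = frame_ms,
                 hop_frac = hop_frac),
            class = "wiener_params")
}

# periodic Hann window: with 50% hop, shifted copies sum to exactly 1
hann_periodic <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

frame_geometry <- function(fs, params) {
  # round the nominal frame length up to an even 2-3-5-smooth number so
  # the per-frame FFTs stay fast at awkward rates (e.g. 720 at 22,050 Hz)
  frame_len <- stats::nextn(round(params$frame_ms / 1000 * fs), c(2, 3, 5))
  while (frame_len %% 2 == 1) {
    frame_len <- stats::nextn(frame_len + 1, c(2, 3, 5))
  }
  list(frame_len = as.integer(frame_len), hop = as.integer(frame_len / 2))
}

#' Short-time Fourier transform of a recording
#'
#' One-sided short-time spectra with Hann analysis windows at 50% hop.
#' The signal is zero-padded by one hop on the left and to a whole number
#' of frames on the right so that [istft()] of unmodified frames
#' reconstructs the input exactly (constant overlap-add).
#'
#' @param rec A [raw_recording()].
#' @param params A [wiener_params()].
#' @return An object of class `spectral_frames`: complex matrix `frames`
#'   (frequency bins x time frames), `frame_len`, `hop`, `window_name`,
#'   `sample_rate_hz` and bookkeeping fields.
#' @export
stft <- function(rec, params = wiener_params()) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$sample_rate_hz
  g <- frame_geometry(fs, params)
  x <- rec$samples
  n <- length(x)
  if (n < g$frame_len) {
    stop_bpi("invalid_input",
             "recording (%d samples) shorter than one analysis frame (%d)",
             n, g$frame_len)
  }
  n_frames <- ceiling((n + g$hop) / g$hop)
  padded_len <- (n_frames - 1) * g$hop + g$frame_len
  xp <- c(numeric(g$hop), x, numeric(padded_len - g$hop - n))
  w <- hann_periodic(g$frame_len)
  starts <- 1 + (seq_len(n_frames) - 1) * g$hop
  idx <- outer(seq_len(g$frame_len) - 1L, starts, `+`)
  fr <- matrix(xp[idx], nrow = g$frame_len) * w
  spec <- stats::mvfft(fr)
  nb <- g$frame_len / 2 + 1
  structure(
    list(frames = spec[seq_len(nb), , drop = FALSE],
         frame_len = g$frame_len, hop = g$hop, window_name = "hann",
         sample_rate_hz = fs, n_samples = n, pad_left = g$hop),
    class = "spectral_frames"
  )
}

#' Inverse STFT (overlap-add resynthesis)
#'
#' @param sf A [spectral_frames()] object (possibly with modified gains).
#' @param silence_lead_s Leading-silence annotation for the result.
#' @return A [raw_recording()] of the original length.
#' @export
istft <- function(sf, silence_lead_s = 1) {
  stopifnot(inherits(sf, "spectral_frames"))
  nb <- nrow(sf$frames)
  full <- rbind(sf$frames,
                Conj(sf$frames[(nb - 1):2, , drop = FALSE]))
  fr <- Re(stats::mvfft(full, inverse = TRUE)) / sf$frame_len
  n_frames <- ncol(fr)
  y <- numeric((n_frames - 1) * sf$hop + sf$frame_len)
  for (m in seq_len(n_frames)) {
    s <- 1 + (m - 1) * sf$hop
    y[s:(s + sf$frame_len - 1)] <- y[s:(s + sf$frame_len - 1)] + fr[, m]
  }
  out <- y[(sf$pad_left + 1):(sf$pad_left + sf$n_samples)]
  out <- pmax(pmin(out, 1), -1)
  raw_recording(out, sample_rate_hz = sf$sample_rate_hz,
                silence_lead_s = silence_lead_s)
}

#' Estimate the noise power spectral density from the leading silence
#'
#' Averages per-bin power over analysis frames lying wholly inside the
#' first `lead_s` seconds (stationary-noise assumption). The estimate is
#' floored at machine epsilon so downstream SNR ratios are always defined.
#'
#' @param frames A [stft()] result.
#' @param lead_s Leading-silence duration in seconds; must cover at least
#'   two frames.
#' @return Numeric vector of per-bin noise power.
#' @export
estimate_noise_psd <- function(frames, lead_s = 1) {
  stopifnot(inherits(frames, "spectral_frames"))
  n_frames <- ncol(frames$frames)
  starts <- 1 + (seq_len(n_frames) - 1) * frames$hop - frames$pad_left
  ends <- starts + frames$frame_len - 1
  sel <- which(ends <= lead_s * frames$sample_rate_hz)
  if (length(sel) < 2) {
    stop_bpi("insufficient_noise_estimate",
             "leading silence of %g s covers %d frame(s); need >= 2",
             lead_s, length(sel))
  }
  psd <- rowMeans(Mod(frames$frames[, sel, drop = FALSE])^2)
  pmax(psd, .Machine$double.eps)
}

#' Decision-directed a-priori SNR tracking
#'
#' Per frame `t` and frequency bin `f`:
#' a-posteriori SNR `post(f,t) = |X(f,t)|^2 / noise_psd(f)`, and
#' `prior(f,t) = alpha * gain(f,t-1)^2 * post(f,t-1) +
#' (1 - alpha) * max(post(f,t) - 1, 0)`, with the first frame initialised
#' to `max(post - 1, 0)` and `gain = prior / (prior + 1)`.
#'
#' @param frames A [stft()] result.
#' @param noise_psd Positive per-bin noise power (from
#'   [estimate_noise_psd()]).
#' @param alpha Smoothing constant in `[0, 1)`.
#' @return An object of class `snr_track` with matrices `snr_posteriori`
#'   and `snr_priori` (bins x frames) and the `noise_psd` used.
#' @export
decision_directed_snr <- function(frames, noise_psd, alpha = 0.98) {
  stopifnot(inherits(frames, "spectral_frames"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 1) {
    stop_bpi("invalid_argument", "alpha must lie in [0, 1)")
  }
  if (any(noise_psd <= 0)) {
    stop_bpi("invalid_argument", "noise_psd must be strictly positive")
  }
  p <- Mod(frames$frames)^2 / noise_psd
  nb <- nrow(p); nt <- ncol(p)
  prior <- matrix(0, nb, nt)
  prior[, 1] <- pmax(p[, 1] - 1, 0)
  g_prev <- prior[, 1] / (prior[, 1] + 1)
  if (nt > 1) {
    for (t in 2:nt) {
      prior[, t] <- alpha * g_prev^2 * p[, t - 1] +
        (1 - alpha) * pmax(p[, t] - 1, 0)
      g_prev <- prior[, t] / (prior[, t] + 1)
    }
  }
  structure(list(snr_posteriori = p, snr_priori = prior,
                 noise_psd = noise_psd),
            class = "snr_track")
}

#' Wiener gain function
#'
#' `W = SNR / (SNR + 1)` evaluated at the a-priori SNR, floored at
#' `gain_floor`. Monotone non-decreasing in SNR and bounded in
#' `[gain_floor, 1)`.
#'
#' @param snr_priori Non-negative a-priori SNR (scalar, vector or matrix).
#' @param gain_floor Minimum gain (default 0).
#' @return Gains with the same shape as `snr_priori`.
#' @export
wiener_gain <- function(snr_priori, gain_floor = 0) {
  if (any(snr_priori < 0)) {
    stop_bpi("invalid_argument", "snr_priori must be non-negative")
  }
  pmax(snr_priori / (snr_priori + 1), gain_floor)
}

#' Denoise a recording with the decision-directed Wiener filter
#'
#' STFT analysis, noise PSD from the leading silence, decision-directed
#' a-priori SNR tracking, per-bin Wiener gains (floored), and overlap-add
#' resynthesis at the original rate and length.
#'
#' @param rec A [raw_recording()] with a leading silence.
#' @param params A [wiener_params()].
#' @return The denoised [raw_recording()] (same length and rate).
#' @export
denoise_recording <- function(rec, params = wiener_params()) {
  stopifnot(inherits(rec, "raw_recording"))
  sf <- stft(rec, params)
  lead <- min(params$noise_from_lead_s, rec$silence_lead_s)
  psd <- estimate_noise_psd(sf, lead)
  track <- decision_directed_snr(sf, psd, params$alpha)
  gains <- wiener_gain(track$snr_priori, params$gain_floor)
  sf$frames <- sf$frames * gains
  out <- istft(sf, silence_lead_s = rec$silence_lead_s)
  peak_in <- max(abs(rec$samples))
  peak_out <- max(abs(out$samples))
  if (peak_in > 0 && peak_out > peak_in * 1.01) {
    out$samples <- out$samples * (peak_in * 1.01 / peak_out)
  }
  out
}
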