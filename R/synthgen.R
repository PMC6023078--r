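# Seeded generator of synthetic modulated breathing patterns and rendered
# acoustic recordings, mirroring the acquisition protocol: 10 s windows with
# a 1 s leading silence, 4 user-specific pattern classes, 10 training and 5
# "live" repetitions per class, with live sets temporally stretched/shifted
# relative to training and contaminated by stationary background noise.

#' Specification of one synthetic breathing-pattern class
#'
#' A breathing pattern is modelled as a train of smooth raised-cosine
#' (Hann-shaped) breath events inside the active part of the window.
#' Repetitions of the class jitter the event timings and amplitudes.
#'
#' @param class_id Integer class identifier (1-4 in the default protocol).
#' @param event_centers_s Numeric vector of event centres (seconds).
#' @param event_widths_s Numeric vector of full event widths (seconds).
#' @param event_amplitudes Numeric vector of relative amplitudes in (0, 1].
#' @param amplitude_jitter_frac Fractional amplitude jitter per repetition.
#' @param timing_jitter_s Timing jitter (seconds) per repetition.
#' @return An object of class `synth_class_spec`.
#' @export
synth_class_spec <- function(class_id, event_centers_s, event_widths_s,
                             event_amplitudes, amplitude_jitter_frac = 0.08,
                             timing_jitter_s = 0.1) {
  n <- length(event_centers_s)
  if (length(event_widths_s) != n || length(event_amplitudes) != n) {
    stop_bpi("invalid_argument",
             "event parameter lists must share one length (n_events)")
  }
  if (n > 0 && (any(event_amplitudes <= 0) || any(event_amplitudes > 1))) {
    stop_bpi("invalid_argument", "event amplitudes must lie in (0, 1]")
  }
  if (n > 0 && any(event_widths_s <= 0)) {
    stop_bpi("invalid_argument", "event widths must be positive")
  }
  structure(
    list(class_id = as.integer(class_id), n_events = n,
         event_centers_s = as.numeric(event_centers_s),
         event_widths_s = as.numeric(event_widths_s),
         event_amplitudes = as.numeric(event_amplitudes),
         amplitude_jitter_frac = amplitude_jitter_frac,
         timing_jitter_s = timing_jitter_s),
    class = "synth_class_spec"
  )
}

#' Time-warp specification for live-set mismatch
#'
#' Live repetitions differ from training ones by a temporal stretch and
#' shift of the whole pattern (or of each breath event independently when
#' `per_event = TRUE`).
#'
#' @param stretch_factor Positive stretch; 1 leaves durations unchanged.
#' @param shift_s Temporal shift in seconds (positive = later).
#' @param per_event Warp each contiguous breath event about its own centre
#'   instead of the whole pattern about its centroid.
#' @return An object of class `warp_spec`.
#' @export
warp_spec <- function(stretch_factor = 1, shift_s = 0, per_event = FALSE) {
  check_scalar_number(stretch_factor, "stretch_factor")
  check_scalar_number(shift_s, "shift_s")
  if (stretch_factor <= 0) {
    stop_bpi("invalid_argument", "stretch_factor must be > 0")
  }
  structure(list(stretch_factor = stretch_factor, shift_s = shift_s,
                 per_event = isTRUE(per_event)),
            class = "warp_spec")
}

#' Generate pairwise-distinct breathing-pattern class specifications
#'
#' Emulates a subject choosing `n_classes` distinct breathing patterns:
#' classes differ in breath-event count (1-4, shuffled) and in event
#' placement, width and amplitude. Deterministic for a fixed seed.
#'
#' @param rng_seed Integer seed.
#' @param n_classes Number of classes (>= 2; default 4).
#' @param duration_s Window length in seconds.
#' @param silence_lead_s Leading silence in seconds; events are placed
#'   strictly after it.
#' @return List of [synth_class_spec()] objects.
#' @export
make_class_specs <- function(rng_seed, n_classes = 4, duration_s = 10,
                             silence_lead_s = 1) {
  if (!is.numeric(n_classes) || n_classes < 2) {
    stop_bpi("invalid_argument", "n_classes must be >= 2")
  }
  n_classes <- as.integer(n_classes)
  with_seed(rng_seed, {
    counts <- rep_len(sample.int(4L), n_classes)
    lo <- silence_lead_s + 1.2
    hi <- duration_s - 1.8
    lapply(seq_len(n_classes), function(k) {
      n <- counts[k]
      spacing <- (hi - lo) / n
      centers <- lo + (seq_len(n) - 0.5) * spacing +
        stats::runif(n, -0.12, 0.12) * spacing
      wmax <- min(0.9, 0.7 * spacing)
      widths <- stats::runif(n, 0.5 * wmax, wmax)
      amps <- stats::runif(n, 0.6, 1)
      synth_class_spec(k, centers, widths, amps)
    })
  })
}

#' Render a breath envelope from a class specification
#'
#' Sums one raised-cosine bump per breath event on a uniform time grid.
#' With `jitter = TRUE` (one "repetition"), event centres and amplitudes
#' are perturbed by the spec's jitter parameters; jittered centres are
#' clamped so events stay inside the active window.
#'
#' @param spec A [synth_class_spec()].
#' @param duration_s Window length (s).
#' @param rate_hz Envelope sampling rate (>= 10 Hz; default 100).
#' @param silence_lead_s Leading silence (s); the envelope is zero there.
#' @param rng_seed Optional seed for the jitter draws.
#' @param jitter Apply within-class repetition jitter?
#' @return A [breath_envelope()] with `class_label` from the spec.
#' @export
render_envelope <- function(spec, duration_s = 10, rate_hz = 100,
                            silence_lead_s = 1, rng_seed = NULL,
                            jitter = TRUE) {
  stopifnot(inherits(spec, "synth_class_spec"))
  if (rate_hz < 10) stop_bpi("invalid_argument", "rate_hz must be >= 10")
  n_samp <- round(duration_s * rate_hz)
  if (spec$n_events == 0L) {
    return(breath_envelope(numeric(n_samp), rate_hz = rate_hz,
                           class_label = spec$class_id))
  }
  half <- spec$event_widths_s / 2
  if (any(spec$event_centers_s - half < silence_lead_s) ||
      any(spec$event_centers_s + half > duration_s)) {
    stop_bpi("invalid_spec",
             "breath events must fit inside (silence_lead_s, duration_s)")
  }
  draw <- function() {
    if (jitter) {
      tj <- spec$timing_jitter_s
      aj <- spec$amplitude_jitter_frac
      centers <- spec$event_centers_s + stats::runif(spec$n_events, -tj, tj)
      centers <- pmin(pmax(centers, silence_lead_s + half + 1e-3),
                      duration_s - half - 1e-3)
      amps <- spec$event_amplitudes *
        (1 + stats::runif(spec$n_events, -aj, aj))
      amps <- pmin(pmax(amps, 0.01), 1)
      list(centers = centers, amps = amps)
    } else {
      list(centers = spec$event_centers_s, amps = spec$event_amplitudes)
    }
  }
  par <- if (is.null(rng_seed)) draw() else with_seed(rng_seed, draw())
  t <- (seq_len(n_samp) - 1) / rate_hz
  v <- numeric(n_samp)
  for (k in seq_len(spec$n_events)) {
    w <- spec$event_widths_s[k]
    d <- t - par$centers[k]
    sel <- abs(d) <= w / 2
    v[sel] <- v[sel] + par$amps[k] * 0.5 * (1 + cos(2 * pi * d[sel] / w))
  }
  breath_envelope(v, rate_hz = rate_hz, class_label = spec$class_id)
}

#' Apply a temporal stretch/shift warp to a breath envelope
#'
#' Resamples the envelope content inside the fixed window: the pattern is
#' stretched about its amplitude centroid by `stretch_factor` and shifted
#' by `shift_s`, with zero-padding outside the original support. Output
#' length, rate and non-negativity are preserved. An identity warp
#' (stretch 1, shift 0) returns the input exactly.
#'
#' @param env A [breath_envelope()].
#' @param warp A [warp_spec()].
#' @return A warped [breath_envelope()].
#' @export
apply_time_warp <- function(env, warp) {
  stopifnot(inherits(env, "breath_envelope"), inherits(warp, "warp_spec"))
  if (warp$stretch_factor == 1 && warp$shift_s == 0) return(env)
  v <- env$values
  n <- length(v)
  if (sum(v) <= 0) return(env)
  t <- (seq_len(n) - 1) / env$rate_hz
  warp_about <- function(vals, anchor) {
    src <- anchor + (t - anchor - warp$shift_s) / warp$stretch_factor
    out <- stats::approx(t, vals, xout = src, yleft = 0, yright = 0)$y
    pmax(out, 0)
  }
  if (warp$per_event) {
    r <- rle(v > 1e-9)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    out <- numeric(n)
    for (s in which(r$values)) {
      seg <- numeric(n)
      idx <- starts[s]:ends[s]
      seg[idx] <- v[idx]
      out <- out + warp_about(seg, sum(t[idx] * v[idx]) / sum(v[idx]))
    }
  } else {
    out <- warp_about(v, sum(t * v) / sum(v))
  }
  expected_mass <- warp$stretch_factor * sum(v)
  if (sum(out) < 0.98 * expected_mass) {
    stop_bpi("invalid_warp",
             "warp pushes breath events outside the recording window")
  }
  breath_envelope(out, rate_hz = env$rate_hz, class_label = env$class_label)
}

#' Render an acoustic recording from a breath envelope
#'
#' Multiplies a broadband noise carrier (white Gaussian noise band-limited
#' to 200-4000 Hz, approximating breath sound at a microphone) by the
#' upsampled envelope and adds stationary white background noise scaled so
#' that the ratio of breath-band power to noise power equals `snr_db`.
#' The leading silence contains background noise only (the envelope is
#' zero there). The mixture is peak-limited to [-1, 1].
#'
#' @param env A [breath_envelope()] (non-negative).
#' @param snr_db Target signal-to-noise ratio in dB (finite).
#' @param sample_rate_hz Audio sampling rate (default 22050 Hz).
#' @param silence_lead_s Leading-silence annotation (default 1 s).
#' @param rng_seed Optional seed for carrier and noise draws.
#' @return A [raw_recording()] with the clean breath component and the
#'   noise component attached as attributes `"clean"` and `"noise"`.
#' @export
render_acoustic <- function(env, snr_db = 20, sample_rate_hz = 22050,
                            silence_lead_s = 1, rng_seed = NULL) {
  stopifnot(inherits(env, "breath_envelope"))
  if (!is.numeric(snr_db) || length(snr_db) != 1L || !is.finite(snr_db)) {
    stop_bpi("invalid_argument", "snr_db must be a single finite number")
  }
  if (any(env$values < 0)) {
    stop_bpi("invalid_argument", "envelope must be non-negative")
  }
  n <- round(env$duration_s * sample_rate_hz)
  tt <- (seq_len(n) - 1) / sample_rate_hz
  t_env <- (seq_along(env$values) - 1) / env$rate_hz
  e <- stats::approx(t_env, env$values, xout = tt, rule = 2)$y
  render <- function() {
    # band-limited white Gaussian carrier via spectral masking
    hi <- min(4000, 0.45 * sample_rate_hz)
    freqs <- (seq_len(n) - 1) / n * sample_rate_hz
    freqs <- pmin(freqs, sample_rate_hz - freqs)
    mask <- freqs >= 200 & freqs <= hi
    carrier <- Re(stats::fft(mask * stats::fft(stats::rnorm(n)),
                             inverse = TRUE)) / n
    carrier <- carrier / stats::sd(carrier)
    s <- e * carrier
    n0 <- stats::rnorm(n)
    p_s <- mean(s^2)
    if (p_s < 1e-20) {
      noise <- 0.05 * n0
    } else {
      noise <- n0 * sqrt(p_s / (mean(n0^2) * 10^(snr_db / 10)))
    }
    x <- s + noise
    peak <- max(abs(x))
    if (peak > 0.95) {
      sc <- 0.95 / peak
      x <- x * sc; s <- s * sc; noise <- noise * sc
    }
    rec <- raw_recording(x, sample_rate_hz = sample_rate_hz,
                         silence_lead_s = silence_lead_s)
    attr(rec, "clean") <- s
    attr(rec, "noise") <- noise
    rec
  }
  if (is.null(rng_seed)) render() else with_seed(rng_seed, render())
}

#' Generate a full synthetic subject dataset
#'
#' Reproduces one subject's acquisition session: `n_classes` pattern
#' classes with `n_train` training repetitions (within-class jitter only)
#' and `n_live` live repetitions per class, where live patterns are
#' additionally time-warped with stretch drawn from `warp_range` and shift
#' from `shift_range` before acoustic rendering. Fully reproducible from
#' `rng_seed`; every recording gets its own derived RNG substream.
#'
#' @param rng_seed Integer seed.
#' @param n_classes,n_train,n_live Protocol sizes (defaults 4, 10, 5).
#' @param warp_range Length-2 stretch range for live sets (default
#'   `c(0.85, 1.2)`).
#' @param shift_range Length-2 shift range in seconds (default
#'   `c(-0.3, 0.3)`).
#' @param snr_db Background-noise level of the rendered audio (default 20).
#' @param sample_rate_hz,duration_s,silence_lead_s Acquisition geometry.
#' @param env_rate_hz Rate of the generator's ground-truth envelopes.
#' @param subject_id Identifier stored with the dataset.
#' @return An object of class `subject_dataset` with per-class lists
#'   `train_recordings` and `live_recordings`, ground-truth envelopes,
#'   `true_labels`, `outlier_flags` (all `FALSE`), warp draws and seeds.
#' @export
generate_subject_dataset <- function(rng_seed, n_classes = 4, n_train = 10,
                                     n_live = 5, warp_range = c(0.85, 1.2),
                                     shift_range = c(-0.3, 0.3), snr_db = 20,
                                     sample_rate_hz = 22050, duration_s = 10,
                                     silence_lead_s = 1, env_rate_hz = 100,
                                     subject_id = 1L) {
  if (any(c(n_classes, n_train, n_live) < 1)) {
    stop_bpi("invalid_argument", "protocol sizes must be positive")
  }
  if (length(warp_range) != 2 || warp_range[1] > warp_range[2]) {
    stop_bpi("invalid_argument", "warp_range must be c(min, max) with min <= max")
  }
  if (length(shift_range) != 2 || shift_range[1] > shift_range[2]) {
    stop_bpi("invalid_argument", "shift_range must be c(min, max) with min <= max")
  }
  specs <- make_class_specs(derive_seed(rng_seed, 0), n_classes,
                            duration_s, silence_lead_s)
  train_recordings <- vector("list", n_classes)
  live_recordings <- vector("list", n_classes)
  train_envelopes <- vector("list", n_classes)
  live_envelopes <- vector("list", n_classes)
  live_warps <- vector("list", n_classes)
  for (k in seq_len(n_classes)) {
    train_recordings[[k]] <- vector("list", n_train)
    train_envelopes[[k]] <- vector("list", n_train)
    for (j in seq_len(n_train)) {
      ctr <- k * 10000 + j
      env <- render_envelope(specs[[k]], duration_s, env_rate_hz,
                             silence_lead_s,
                             rng_seed = derive_seed(rng_seed, ctr))
      train_envelopes[[k]][[j]] <- env
      train_recordings[[k]][[j]] <-
        render_acoustic(env, snr_db, sample_rate_hz, silence_lead_s,
                        rng_seed = derive_seed(rng_seed, ctr + 1000))
    }
    live_recordings[[k]] <- vector("list", n_live)
    live_envelopes[[k]] <- vector("list", n_live)
    live_warps[[k]] <- vector("list", n_live)
    for (j in seq_len(n_live)) {
      ctr <- k * 10000 + 5000 + j
      env <- render_envelope(specs[[k]], duration_s, env_rate_hz,
                             silence_lead_s,
                             rng_seed = derive_seed(rng_seed, ctr))
      w <- with_seed(derive_seed(rng_seed, ctr + 2000), {
        warp_spec(stats::runif(1, warp_range[1], warp_range[2]),
                  stats::runif(1, shift_range[1], shift_range[2]))
      })
      env <- apply_time_warp(env, w)
      live_envelopes[[k]][[j]] <- env
      live_warps[[k]][[j]] <- w
      live_recordings[[k]][[j]] <-
        render_acoustic(env, snr_db, sample_rate_hz, silence_lead_s,
                        rng_seed = derive_seed(rng_seed, ctr + 1000))
    }
  }
  structure(
    list(subject_id = subject_id, specs = specs,
         train_recordings = train_recordings,
         live_recordings = live_recordings,
         train_envelopes = train_envelopes,
         live_envelopes = live_envelopes,
         live_warps = live_warps,
         true_labels = rep(seq_len(n_classes), each = n_live),
         outlier_flags = rep(FALSE, n_classes),
         n_classes = n_classes, n_train = n_train, n_live = n_live,
         sample_rate_hz = sample_rate_hz, duration_s = duration_s,
         silence_lead_s = silence_lead_s, env_rate_hz = env_rate_hz,
         snr_db = snr_db, warp_range = warp_range,
         shift_range = shift_range, rng_seed = rng_seed),
    class = "subject_dataset"
  )
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf(
    "<subject_dataset> subject %s: %d classes x (%d train + %d live) @ %g Hz\n",
    x$subject_id, x$n_classes, x$n_train, x$n_live, x$sample_rate_hz))
  invisible(x)
}

#' Write a subject dataset to disk as WAV files plus manifest
#'
#' Lays out `subject_<id>/train/class<k>_rep<j>.wav`,
#' `subject_<id>/live/class<k>_rep<j>.wav`, a `manifest.json` with labels,
#' seeds and warp parameters, and a `specs.csv` of class-event parameters.
#'
#' @param ds A [generate_subject_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return The subject directory path, invisibly.
#' @export
write_subject_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "subject_dataset"))
  root <- file.path(dir, sprintf("subject_%s", ds$subject_id))
  dir.create(file.path(root, "train"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "live"), recursive = TRUE, showWarnings = FALSE)
  manifest <- list(subject_id = ds$subject_id, rng_seed = ds$rng_seed,
                   sample_rate_hz = ds$sample_rate_hz,
                   duration_s = ds$duration_s,
                   silence_lead_s = ds$silence_lead_s,
                   snr_db = ds$snr_db, warp_range = ds$warp_range,
                   shift_range = ds$shift_range,
                   outlier_flags = ds$outlier_flags,
                   train = list(), live = list())
  spec_rows <- list()
  for (k in seq_len(ds$n_classes)) {
    sp <- ds$specs[[k]]
    spec_rows[[k]] <- data.frame(
      class_id = sp$class_id, event = seq_len(sp$n_events),
      center_s = sp$event_centers_s, width_s = sp$event_widths_s,
      amplitude = sp$event_amplitudes)
    for (j in seq_len(ds$n_train)) {
      f <- sprintf("class%d_rep%02d.wav", k, j)
      write_wav(ds$train_recordings[[k]][[j]], file.path(root, "train", f))
      manifest$train[[length(manifest$train) + 1L]] <-
        list(file = file.path("train", f), class_id = k, rep = j)
    }
    for (j in seq_len(ds$n_live)) {
      f <- sprintf("class%d_rep%02d.wav", k, j)
      write_wav(ds$live_recordings[[k]][[j]], file.path(root, "live", f))
      w <- ds$live_warps[[k]][[j]]
      manifest$live[[length(manifest$live) + 1L]] <-
        list(file = file.path("live", f), class_id = k, rep = j,
             stretch_factor = w$stretch_factor, shift_s = w$shift_s)
    }
  }
  jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(do.call(rbind, spec_rows), file.path(root, "specs.csv"),
                   row.names = FALSE)
  invisible(root)
}
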