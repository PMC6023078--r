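---
title: "Breathing-pattern interpretation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breathing-pattern interpretation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpinterp)
```

## The problem

Some augmentative and alternative communication (AAC) users cannot speak
or gesture reliably but can modulate their breathing at will. A
microphone close to the nose and mouth records a fixed window of breath
sound; the user has previously trained the system with repetitions of a
few self-chosen breathing patterns, each mapped to a phrase. At use
time, a live breath window is matched to the closest trained pattern and
the corresponding phrase is emitted as text (and optionally handed to a
speech synthesiser).

`bpinterp` implements this whole chain — denoising, envelope
extraction, template matching, evaluation — plus a seeded generator of
synthetic breathing recordings, so every stage is testable without human
recordings.

## Acquisition geometry

A recording is a mono window of `duration_s = 10` s at
`sample_rate_hz = 22050` Hz whose first `lead_silence_s = 1` s is
silence. The protocol emulated by the generator uses 4 pattern classes
per subject, 10 training repetitions per class (40 training patterns)
and 5 live repetitions per class (20 live patterns per subject; over 23
subjects, 92 live sets and 460 live classifications per metric).

## Wiener denoising

Background noise is assumed stationary over the window, so its power
spectral density is estimated by averaging short-time spectra of frames
lying wholly inside the leading silence. Per frequency bin $f$ and frame
$t$, the a-posteriori SNR is $\gamma(f,t) = |X(f,t)|^2 / \lambda(f)$ and
the a-priori SNR $\xi$ is tracked by the decision-directed recursion

$$\xi(f,t) = \alpha\, G(f,t-1)^2 \gamma(f,t-1)
  + (1-\alpha) \max(\gamma(f,t) - 1,\, 0),$$

with the Wiener gain $G = \xi / (\xi + 1)$ applied to each bin before
overlap-add resynthesis. Tunables, with defaults:

* `alpha = 0.98` — the canonical decision-directed smoothing constant;
  larger values suppress musical noise at the cost of slower tracking.
* `frame_ms = 32`, 50% hop, Hann analysis window — standard for
  speech-band enhancement. The frame length is rounded up to an even
  2-3-5-smooth sample count (720 samples at 22,050 Hz) so the FFTs stay
  fast; with a periodic Hann window at half-frame hop the analysis
  windows sum to exactly one, making the unmodified analysis–synthesis
  loop an identity to machine precision.
* `gain_floor = 0.05` (about −26 dB) — floors the spectral gain to
  avoid musical noise; the recursion itself uses the unfloored gain.
* `noise_from_lead_s = 1` — the noise estimate uses only frames that
  end inside the leading silence, so breath onsets never contaminate it.

Denoising runs at the native rate, before any sub-sampling.

## Envelope extraction

The denoised audio is reduced to the unit of classification, a 100 Hz
non-negative envelope, in four steps:

1. **Downsample to 1000 Hz.** A linear-phase windowed-sinc FIR low-pass
   (Hamming design; stopband opening below the 500 Hz target Nyquist,
   passband flat to roughly 450 Hz, stopband attenuation above 50 dB)
   applied zero-phase with mirror-padded edges, followed by resampling
   on the target grid. 10 s of audio becomes exactly 10,000 samples.
2. **Rectify.** Full-wave rectification demodulates the breath-band
   carrier; a low-pass alone would annihilate a zero-mean audio signal.
3. **Low-pass at `cutoff_hz = 2`, order-4 Butterworth, zero-phase**
   (forward–backward, so the envelope has no lag). Resting breathing
   occupies 0.2–0.8 Hz; 2 Hz keeps the modulation harmonics of
   deliberately shaped patterns while rejecting carrier ripple, and
   guarantees anti-aliasing for the final step. Residual negative
   ringing after filtering is clipped to zero.
4. **Decimate to 100 Hz** (plain 1-in-10 selection — the 2 Hz low-pass
   already band-limits) and **normalise**: subtract the minimum, divide
   by the remaining peak. Every envelope is 1000 samples in $[0,1]$
   with maximum exactly 1; an all-zero envelope stays zero.

Each envelope is normalised independently (live inputs use their own
minimum and peak, not training-set statistics): each pattern is
described per-window, and self-contained normalisation keeps the live
path identical to the training path.

## Template matching

Training envelopes are stacked row-wise into an $M \times L$ matrix
($40 \times 1000$ in the default protocol) with class labels and a
class-to-phrase vocabulary. A live envelope is classified by
1-nearest-neighbour under either distance:

* **Euclidean (ED):** $d(U,V) = \left(\sum_i (u_i - v_i)^2\right)^{1/2}$
  on equal-length envelopes. Mismatched lengths are an error by design —
  the pipeline guarantees fixed lengths, so a mismatch signals a bug,
  and silent resampling would mask it.
* **Dynamic time warping (DTW):**
  $D(i,j) = d(u_i, v_j) + \min\{D(i,j{-}1), D(i{-}1,j), D(i{-}1,j{-}1)\}$
  with $D(1,1) = d(u_1,v_1)$ and local cost $|u_i - v_j|$ (a
  squared-cost variant is available but off by default). The optimal
  warp path is recovered by backtracking, preferring the diagonal on
  ties; paths satisfy the boundary, monotonicity and continuity
  constraints with length $\max(a,b) \le K \le a+b-1$. The recurrence is
  implemented in C++; an optional Sakoe–Chiba band (`band_width`)
  bounds $|i-j|$ for speed but is disabled in validation runs, which use
  unconstrained DTW on full 1000-sample envelopes.

Ties in the 1-NN argmin break to the lowest template index —
deterministic and stable under template reordering. 1-NN always answers:
a pure-noise input is still assigned some class, with the full distance
vector available for inspection.

## The synthetic generator

The generator emulates the acquisition protocol so the pipeline can be
exercised end to end:

* A **class** is a train of raised-cosine (Hann-shaped) breath events —
  smooth, non-negative, compactly supported bumps. A subject's four
  classes differ in event count (1–4, shuffled per subject) and in
  event placement, width (0.45–0.9 s) and relative amplitude (0.6–1).
  Event amplitudes are kept above 60% of the class maximum so every
  event survives half-maximum peak counting.
* **Repetitions** jitter event centres by ±0.1 s and amplitudes by ±8%
  — the within-class variability of a cooperative subject.
* **Live mismatch:** each live repetition is additionally stretched by
  a factor drawn uniformly from 0.85–1.2 and shifted by up to ±0.3 s,
  reproducing the observation that live patterns spread differently
  over the window than training ones. The stretch is anchored at the
  envelope's amplitude centroid, which minimises boundary excursions
  and keeps a lone bump's peak in place under pure stretch.
* **Acoustics:** the envelope multiplies a broadband carrier (white
  Gaussian noise band-limited to 200–4000 Hz — breath sound at a
  microphone is broadband), and stationary white background noise is
  added, scaled so the realised breath-to-noise power ratio equals
  `snr_db` exactly. The default of 20 dB reflects a quiet room with a
  close directional microphone. The mixture is peak-limited to
  $[-1, 1]$ for 16-bit WAV export.
* **Reproducibility:** one base seed per dataset is split into
  per-recording substreams by counter, so any single recording can be
  regenerated independently of ordering.

What the generator does **not** model: physiological airflow dynamics,
nasal/oral routing, inter-subject microphone placement differences,
non-stationary background noise, or the inter-pattern confusability of
real user-invented patterns. Passing tests on synthetic data therefore
establish the correctness and the directional behaviour of the
algorithms (warping robustness of DTW versus ED), not clinical
performance on human recordings.

## Evaluation

Per subject, a confusion matrix (true × predicted) is built from the 20
live classifications and the percent correct is `100 × trace / total`.
Outlier omission is metadata-driven: a live *set* (all 5 repetitions of
one class for one subject) can be flagged and is then excluded exactly
once from the cumulative matrix — flagging mimics the human judgement
that a subject failed to recall a pattern, and no automatic outlier
detector is invented. Aggregates report both the mean of per-subject
percentages and the pooled trace/total percentage, since "average rate"
is ambiguous between the two; on balanced data without omissions they
coincide.

`run_experiment()` streams subjects one at a time (generate → process →
classify → discard audio), so memory stays bounded by a single
subject's recordings.

## Numerical choices and degenerate inputs

* STFT framing pads one hop of zeros on the left and to a whole frame
  on the right; reconstruction trims them, so round trips are exact.
* The noise PSD is floored at machine epsilon: an all-zero lead still
  yields finite SNRs downstream.
* A constant envelope normalises to all zeros (offset removal leaves
  nothing), and all-zero envelopes pass through every stage unchanged.
* Warps that would push more than 2% of the envelope mass outside the
  window raise an error rather than silently clipping.
* `identity` warps (stretch 1, shift 0) return the input object
  unchanged, exactly.

## Problem sizes used in the validation suite

The full synthetic experiment (23 subjects, 460 live classifications
per metric, unconstrained DTW on 1000-sample envelopes) runs in about
five and a half minutes on one CPU. Unit tests use a reduced geometry —
8 s windows at 8 kHz audio — which preserves every rate relationship of
the standard chain (audio → 1000 Hz → 100 Hz) while keeping the suite
fast; the full 22,050 Hz geometry is exercised by the shape-contract
and experiment-level tests. The DTW dynamic program is checked exactly
against exhaustive enumeration of all monotone warp paths for 200
seeded pairs of short series (lengths ≤ 8).

## Known limitations

* Breath onset is not detected; recordings are assumed aligned to the
  fixed window (shorter/longer files are zero-padded/truncated).
* The Wiener filter assumes stationary noise; competing speech or music
  in the background violates this.
* ED requires the fixed-length pipeline; it is not defined for
  variable-length inputs here.
* No statistical test accompanies the DTW-vs-ED comparison; the
  package reports rates and their difference.
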