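---
title: "Methods: stimulus-specific speech tracking, cross-frequency coupling, and their statistics"
author: "speechMI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimulus-specific speech tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(speechMI)
```

# Overview

`speechMI` quantifies how rhythmic brain activity tracks the temporal
structure of speech, and whether that tracking matters for comprehension.
The pipeline has five stages:

1. **Stimulus-specific bands.** Instead of generic delta/theta bands, the
   analysis bands are derived from the corpus itself: for each linguistic
   category (phrase, word, syllable, phoneme) the per-sentence event rate
   is the reciprocal of the mean inter-onset interval, and the band edges
   are the minimum and maximum rates across sentences, rounded to one
   decimal. On corpora like the one the synthetic generator emulates this
   yields phrase 0.6–1.3 Hz, word 1.8–3.0 Hz, syllable 2.8–4.8 Hz and
   phoneme 8–12.4 Hz. Dividing the syllable band by three (every third
   syllable stressed) gives a "stress timescale" of 0.9–1.6 Hz.
2. **Wideband envelope.** Speech audio is filtered into 8 bands between
   100 and 8000 Hz, equidistant on the Greenwood cochlear map, with
   zero-phase third-order Butterworth filters; the analytic-signal
   magnitudes are averaged and resampled to 150 Hz.
3. **Tracking MI.** Envelope and source-level neural series are filtered
   to an analysis band, Hilbert-transformed, and the dependence between
   the two-dimensional analytic representations (real and imaginary
   parts) is measured with Gaussian-copula mutual information, at five
   stimulus-to-brain lags (60–140 ms in 20-ms steps) whose MI values are
   summed.
4. **Nulls and contrasts.** Chance levels come from surrogate data (trial
   shuffling, repeated 50 times, or time reversal of the speech series).
   Perceptual relevance comes from comparing correct against incorrect
   trials with equalised trial counts (80% of the smaller sample, redrawn
   20 times and averaged).
5. **Group statistics.** Per-grid-point dependent t tests are corrected by
   cluster-based permutation (sign-flipping of participant difference
   maps, max-cluster statistic, summed t as effect size) and post-hoc
   peak tests use Benjamini–Hochberg FDR.

Phase–amplitude coupling (PAC) reuses the same estimator: the phase
channel is the unit phasor (cos, sin) of the slow band, the power channel
the squared analytic magnitude of the fast band, and PAC is their
2-D × 1-D copula MI. The canonical pair is phrasal phase (0.6–1.3 Hz)
× beta power (13–30 Hz); controls are phrasal × alpha (8–12 Hz),
phrasal × theta (4–8 Hz) and word (1.8–3 Hz) × beta.

# The estimator

For copula-normalised data (each margin mapped through its ranks to
standard-normal scores, ties broken by first occurrence so results are
bit-reproducible), the MI in bits is

$$ I(X;Y) = \tfrac12 \log_2 \frac{\det \Sigma_X \,\det \Sigma_Y}{\det \Sigma_{XY}} $$

with sample covariances of the transformed data. The estimator is
invariant to any strictly monotone marginal transform — which is why
amplitude versus squared amplitude (power) is immaterial for PAC, and why
z-scoring the analytic parts "separately" is harmless (it is kept because
it stabilises covariance conditioning).

**Bias correction.** The expected log-determinant of a Wishart sample
covariance is known in closed form (digamma terms); subtracting it makes
the estimate unbiased for Gaussian data. The flag defaults to on.
Negative corrected values are clamped to zero by default since MI is
non-negative; the clamp biases null distributions slightly upward, so
calibration checks use `clamp = FALSE`.

**Dependent samples.** The correction assumes independent observations.
Band-limited series are autocorrelated, so a small positive offset
remains under independence whatever the series length (bias and sampling
noise shrink at the same rate). This is not a defect to be corrected by a
longer recording — it is the reason the pipeline never interprets raw MI
against an analytic zero, but always against surrogate or
condition-matched references, which share the autocorrelation structure.
The package's test suite follows the same logic: the estimator-level
"MI is zero under independence" calibration uses i.i.d. draws; the PAC
independence check compares against a matched cross-realisation null.

# Numerical choices

* **Cochlear map.** "Equidistant on the cochlear map" is implemented with
  the Greenwood position function $F(x) = 165.4\,(10^{2.1x} - 0.88)$ and
  its inverse; the map is exposed (`greenwoodFrequency`,
  `greenwoodPosition`) so another map can be substituted.
* **Filters.** Third-order Butterworth, forward and reverse
  (`signal::filtfilt`), for every analysis band including the phoneme
  band. The first and last 0.5 s of each filtered trial are discarded
  before MI to suppress filter transients (configurable). Because the
  filter routine pads only one end, zero-phase filtering is
  time-reversal-symmetric only away from the trial edges; the
  time-reversal surrogate therefore agrees with the ideal symmetric
  operation to well under a percent once edges are trimmed.
* **DC removal.** Series are demeaned before band-pass filtering: an
  offset is a step at the series edges and rings through narrow
  low-frequency bands far beyond the usual trim.
* **Lag convention.** Neural activity lags the stimulus: speech at time
  $t$ is paired with the neural sample at $t + \tau$, $\tau > 0$; the
  overhang is trimmed within each trial so no cross-trial pairs exist.
* **Lag resolution.** The copula MI of complex analytic pairs is
  invariant to a phase rotation, so the MI-versus-lag profile decays on
  the timescale of the band's inverse *bandwidth*, not its period. In the
  phrase band (~0.7 Hz wide) the profile is essentially flat across
  60–140 ms — one reason the analysis sums MI over lags rather than
  interpreting a single-lag peak. Ground-truth lag recovery is therefore
  validated in the phoneme band, whose ~4.4-Hz bandwidth gives sharp
  temporal discrimination.
* **Resampling.** Envelopes are computed at the audio rate and then
  polyphase-resampled to 150 Hz (`signal::resample`).
* **Welch spectra.** Hann window, 50% overlap, segments of up to 10 s
  zero-padded so the native resolution matches the 0.1-Hz reporting grid
  (0.1–12 Hz).
* **Cluster adjacency.** Neighbours are grid points within 1.01 × the
  lattice spacing (face adjacency); the radius is configurable. Connected
  components use union-find; the permutation null sign-flips participant
  difference maps and uses the maximal cluster |T_sum| (two-sided) or
  maximal signed T_sum (one-sided, used for the directional PAC
  whole-grid test). p values use the add-one convention. Zero-variance
  grid points get t = 0 with a message rather than ±Inf.
* **Coefficient of variation.** Population SD over mean of the pooled
  event durations.
* **Surrogate shuffles.** Permutations of the speech-to-brain trial
  assignment are redrawn until they have no fixed point; length
  mismatches after shuffling are handled by pairing the first
  min(length) samples. Shuffling is repeated (default 50×) because
  structurally similar sentences leave residual dependence in any single
  shuffle.

# The synthetic-data generator

The generator provides ground truth for every pipeline stage without any
external data. Its defaults are the study conditions the package targets:

* **Corpus.** 90 sentences built on a fixed 7-element structure
  (2 opening phrases, then name–verb–numeral–adjective–noun; 11 word
  slots, 18 syllables, 48 phonemes). Per sentence and category a rate is
  drawn from the stated normals (1.0 ± 0.1, 2.4 ± 0.3, 3.8 ± 0.4,
  10.4 ± 0.8 Hz); inter-onset intervals are log-normal, rescaled so the
  per-sentence rate is exact. Durations are 85% of the interval;
  log-normal duration jitter makes word durations roughly twice as
  variable as phrase durations (coefficients of variation near 0.27 and
  0.48), as in natural material of this kind. Log-normal timing is used
  because speech unit durations are positive and right-skewed.
* **Envelope.** A weighted sum of smoothed pulse trains (20-ms half-sine
  attack, half-cosine decay). The two opening phrases gate the faster
  material with a pause between them (floor 0.25 of the gate), which is
  what carries the phrasal rhythm into the spectrum — the average corpus
  spectrum shows a low-frequency peak inside the phrase band, plus word-
  and phoneme-rate structure. In rare pulse collisions the summed
  envelope could fail to rise at an annotated onset; a minimal onset
  burst (sized just above the local decay) restores the
  annotation–envelope consistency guarantee exactly.
* **Neural data.** Per participant and trial, every grid point carries
  unit-variance 1/f noise (spectral exponent 1; a more realistic null
  than white noise for band-limited MI). Inside a compact effect region
  (default: central 3×3×3 cube of an 8×8×8, 6-mm lattice) the
  standardised envelope, delayed by 100 ms, is added with an amplitude
  ratio of 0.6 on correct trials and 0.2 on incorrect ones — tracking is
  present in both conditions but stronger when comprehension succeeds,
  with labels Bernoulli(0.7). In the PAC region a band-limited carrier
  is added whose amplitude is $1 + d \cos\phi$ with $\phi$ the
  phrasal-band phase of that point's own series and depth $d$ = 0.8
  (correct) / 0 (incorrect). The carrier occupies 16–25 Hz: inside the
  beta analysis band but clear of the alpha band's filter skirt, so the
  coupling is beta-specific the way it is in the data being emulated
  (a 13–30 Hz carrier would leak ~15% of its power into an order-3
  alpha filter).
* **What it does not emulate.** Acoustic realism (formants, background
  noise, the adaptive noise titration), item difficulty structure in the
  labels (independent Bernoulli only), inter-regional connectivity, and
  realistic source leakage. Passing tests therefore demonstrate that the
  pipeline recovers what it is supposed to recover under controlled
  conditions, not that real MEG effects of a given size would be
  detected.

# Problem sizes in tests and the acceptance script

The statistical machinery is exercised at desk scale, chosen once as
realistic miniatures: null-calibration lattices are 6×6×6 with 20 virtual
participants, 500 permutations and 200 simulation rounds; effect-region
recovery uses 12 participants, 30 trials, a 6×6×6 grid with a 3×3×3
effect and 3 subsample repeats; PAC detection uses 50 simulated
experiments of 5 participants on a 2×2×2 grid (the acceptance script
reports 10); estimator checks use n = 10,000 averaged over 10
replicates. Paper-fidelity settings (1000 permutations, 20/50 repeats,
50 shuffles, 12,337-point grids) remain the package defaults via
`pipelineConfig()` and `synthConfig()`.

# Known limitations

* MI values from concatenated band-limited samples are biased upward in
  absolute terms; only comparisons (surrogate, condition, permutation)
  are interpretable, as designed.
* The permutation unit is the sign-flip of participant difference maps;
  condition relabelling within participant is a noted alternative.
* `filtfilt` edge handling makes extreme low-frequency bands usable only
  on trials several cycles long; `analyticTrials` enforces a two-cycle
  minimum and trims edges.
* The generic 0–2 Hz band is implemented as a low-pass filter (a 0-Hz
  band edge cannot be realised as a band-pass).
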