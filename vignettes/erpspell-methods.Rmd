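---
title: "Simulating and decoding ERP matrix spellers with erpspell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decoding ERP matrix spellers with erpspell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpspell)
library(dplyr)
```

## The problem

A P300 matrix speller lets a user select one of 36 symbols (A–Z, 1–9 and
underscore, laid out in a 6 × 6 grid) by attending to one of them while
groups of symbols flash in rapid succession. Flashes that contain the
attended symbol are rare, attended events and therefore evoke an oddball
response — most prominently the P300, a positive deflection over central
electrodes roughly 300 ms after the flash. A classifier trained to detect
that response can, by accumulating evidence over flashes, recover which
symbol the user intended.

`erpspell` implements an offline analysis of three stimulus-presentation
paradigms for such a speller:

* **RC** — the classic row–column paradigm: the 6 physical rows and 6
  physical columns of the matrix each flash once per sequence.
* **RASP** — random set presentation: before each sequence the 36 symbols
  are shuffled into a fresh *virtual* 6 × 6 arrangement, and the 12 flash
  groups are that arrangement's rows and columns. Neighbors of the target
  rarely co-flash with it, which mitigates adjacency-distraction errors.
* **RASP-F** — RASP with semi-transparent face overlays: symbols in a
  virtual row flash together with the user's own face, symbols in a
  virtual column with other faces. Face stimuli additionally evoke the
  N170, and familiar (own) faces an N400f, adding class-discriminative
  signal beyond the P300.

In every paradigm a *sequence* is 12 flashes in which each symbol appears
exactly twice; a *trial* (one letter) is a 2 s countdown followed by a
fixed number of sequences, flashed at 135 ms per flash plus a 50 ms
inter-stimulus interval (185 ms stimulus-onset asynchrony).

Because no recorded EEG is distributed with this package, every stage is
driven by a forward model (`simulate_recording()`) that generates
multichannel recordings with exactly the ERP structure the analysis
assumes. That makes each stage testable end to end: properties the decoder
should recover are *put into* the synthetic data, and the tests verify
they come back out.

## The forward model

A recording is a 29-channel (10–20 montage) signal at 500 Hz, in
microvolts. For every flash event and every enabled component the model
adds

amplitude × polarity × kernel(t − onset) × spatial weight(channel),

on top of 1/f background noise. The pieces:

* **Kernels** (`erp_kernel()`): unit-peak half-sine bumps supported
  exactly on the component's canonical window — P300 280–370 ms (positive,
  peak at Cz), N170 130–200 ms (negative, PO7), N400f 400–550 ms
  (negative, Cz). Real ERP waveshapes are not half-sines, but only the
  windowed means enter the analysis, so any unimodal bump with the right
  support serves; the half-sine is the simplest such choice.
* **Spatial weights**: Gaussian decay `exp(-d²/2s²)` over schematic 2-D
  electrode coordinates around the peak channel, with spreads 0.70 (P300),
  0.45 (N170) and 0.60 (N400f) in head-radius units — broad central P300,
  a more focal occipito-temporal N170. This is a descriptive topography,
  not a volume-conduction model.
* **Class structure** (all amplitudes configurable via `sim_config()`):
  every *target* flash evokes a P300 (default 5 µV); every *face* flash
  evokes an N170 (3 µV, +1 µV when the flash contains the target); target
  face flashes evoke an N400f that is larger for the self face (4 µV) than
  for other faces (2 µV). These defaults reproduce the qualitative
  ordering the analysis should detect (face > highlight, self > non-self);
  no µV effect sizes were available to fit, so they are free parameters of
  the generator, stated once and not tuned.
* **Refractoriness**: the P300 of a target flash is scaled by the
  target-to-target interval (TTI) — the number of non-target flashes since
  the previous target flash — with multipliers 0.4, 0.6, 0.8 and 1.0 for
  TTI 0, 1, 2 and ≥ 3. A trial's first target flash, preceded by the
  countdown, gets the full amplitude. This produces the rise-and-plateau
  accuracy profile over TTI that motivates minimum-TTI constraints in
  other paradigms.
* **Noise**: per-channel 1/f^α noise (α = 1) with σ = 6 µV plus a
  common-mode term of 0.3 σ shared across channels for spatial
  correlation. σ = 6 µV against a 5 µV single-trial P300 puts single-flash
  discriminability in the range where accuracy grows visibly with the
  number of sequences, which is the regime of interest; the 1/f shape
  concentrates power below the analysis band's midpoint like resting EEG.
  Noise is synthesized spectrally at the next 2-3-5-smooth FFT length and
  truncated (R's mixed-radix FFT degrades badly on lengths with large
  prime factors).

A simulated *study* for one subject (`generate_study()`,
`run_speller_study()`) comprises, per paradigm, a training run
(copy-spelling `BRAIN_COMPUTER_INTERFACE`, 24 trials) and a test run
(`KOREAUNIVERSITY`, 15 trials) with independent noise; test-run amplitudes
are scaled by 0.95 to emulate session-to-session transfer between
recording days.

What the generator deliberately does **not** emulate: eye blinks and
muscle artifacts, latency jitter and habituation of components,
non-stationary background spectra, inter-subject topography differences,
and volume conduction. Passing tests therefore show the pipeline is
correct and sensitive under its own assumptions — not that it would reach
any particular accuracy on recorded EEG.

## The analysis pipeline

1. **Decimation** (`resample_recording()`): 500 → 100 Hz via a zero-phase
   Chebyshev type-I low-pass (order 8, 0.05 dB ripple, cutoff 0.8 × the
   new Nyquist) before taking every 5th sample; event marker indices are
   rescaled.
2. **Band-pass** (`bandpass_filter()`): zero-phase Butterworth 0.1–30 Hz.
   The filter is applied as an order-5 high-pass/low-pass cascade rather
   than a directly designed band-pass: with a 0.1 Hz edge the direct
   design's poles are so close to the unit circle that forward–backward
   filtering is numerically unstable in double precision, while the
   cascade has the same passband and is well conditioned. Zero-phase
   application avoids latency shifts in the component windows; both orders
   are arguments.
3. **Epoching** (`extract_epochs()`): one epoch per flash over
   [−200, 800) ms — half-open, the t = 0 sample counts as post-stimulus —
   giving 100 samples per epoch at 100 Hz, with target labels and TTI
   metadata attached.
4. **Baseline correction** (`baseline_correct()`): per epoch and channel,
   the mean over [−200, 0) ms is subtracted.
5. **Discriminability map** (`signed_r_squared_map()`): at every
   (channel, time) point the signed squared point-biserial correlation
   between amplitude and the target label, with the population
   (divide-by-N) pooled standard deviation, which makes the value exactly
   the signed squared Pearson correlation against a 0/1 indicator — an
   unambiguous oracle that the tests exploit. Points with zero variance
   are defined as 0.
6. **Interval selection** (`select_discriminative_intervals()`): 8
   disjoint intervals within (100, 600] ms, by a greedy peak-growing rule
   on the channel-summed r² score: pick the unmasked maximum, grow the
   interval while the score stays above half that peak, mask, repeat. If
   the remaining score is everywhere zero the leftover intervals tile the
   unoccupied window left-to-right with equal widths (an all-zero map
   yields 8 equal 62.5 ms tiles); if the greedy pass consumes the whole
   window early, the widest intervals are split at sample boundaries until
   8 remain. The procedure is deterministic given the map. Intervals are
   selected on training data only and stored inside the model, so test
   data can never influence them.
7. **Features** (`interval_mean_features()`): mean amplitude per (channel,
   interval) — 29 × 8 = 232 dimensions, channel-major column order.
8. **Classifier** (`train_rlda()`): binary LDA with Schäfer–Strimmer
   analytic shrinkage of the pooled within-class covariance toward ν·I (ν
   = mean diagonal variance, trace-preserving). The closed-form intensity
   γ* is clamped to [0, 1] and defined as 1 when the covariance already
   equals the target. With 232 features and a few thousand epochs the
   empirical covariance alone would be ill-conditioned; shrinkage makes
   the solve stable without cross-validating a regularizer. Pooled (not
   per-class) covariance is standard LDA practice; the bias is the
   balanced midpoint −wᵀ(μₜ+μₙₜ)/2 — decoding uses only score ranks, so
   class priors would not change any argmax decision.
9. **Decoding** (`decode_characters()`): the evidence for a symbol is the
   sum of scores over flashes (within the first n sequences) whose letter
   set contains it; the argmax decides, ties breaking to the smallest
   (row, column) in row-major order. The same rule serves all three
   paradigms; on RC it reduces exactly to intersecting the best row with
   the best column (a tested invariant).
10. **Evaluation**: accuracy-vs-sequences curves; the Wolpaw information
    transfer rate B(P, N) × 60/duration with B clamped to 0 at or below
    chance and 0·log 0 ≡ 0; and 8-fold *chronological* cross-validation of
    per-flash accuracy (temporally contiguous folds, earlier folds taking
    the remainders — random folds would leak the strong temporal
    correlation of EEG noise across train/test). The selection duration is
    explicit: countdown + n × 12 × SOA; every reported ITR states the
    duration it used, since timing accounting, not classification, often
    dominates ITR comparisons.

## Statistics

`stats`-backed wrappers with the conventions fixed as follows:

* `paired_sign_test()`: exact two-sided binomial test, ties dropped — no
  normal approximation at n = 15 subjects.
* `two_sample_t()`: pooled-variance t (not Welch), two-sided; the
  degenerate zero-variance equal-means case is defined as t = 0, p = 1.
* `bonferroni_adjust()`: min(1, m·p) with a caller-specified family size.
* `repeated_measures_anova_2way()`: fully within-subject two-factor ANOVA
  where each effect is tested against its own effect-by-subject
  interaction; dfs for a 15 × 3 × 10 design are (2, 28), (9, 126),
  (18, 252). No sphericity correction is applied. A zero effect sum of
  squares is reported as F = 0 even when its error stratum is also
  degenerate.
* `component_window_mean()`: per-epoch window means at the canonical
  (channel, window) pairs — N170 at PO7 over 130–200 ms, P300 at Cz over
  280–370 ms, N400f at Cz over 400–550 ms (closed windows).
* `tti_accuracy_profile()`: accuracy per TTI bin 0–4 plus ≥ 5; empty bins
  are `NA`, not 0.
* `adjacency_error_map()`: an 11 × 11 count matrix of decode offsets with
  the target centered; its total equals the trial count and the center
  cell the correct selections.

## Problem sizes and determinism

All randomness flows through R's global RNG: seed once with `set.seed()`
and every schedule, recording and downstream result is reproducible
byte-for-byte. The package's own verification uses cohorts of 10–12
simulated subjects with the full study layout (24 training / 15 test
trials, 10 sequences per trial) — large enough that the qualitative
orderings (RASP-F above the highlight paradigms at one sequence; self-face
above non-self-face strata; the TTI rise-and-plateau) are stable across
seeds, and chance-level checks use pooled binomial bands. Where a test
targets a *topographic* property (the target contrast peaking at Cz), the
noise amplitude is reduced so the channel argmax reflects the configured
topography rather than residual background at feasible trial counts.

## Known limitations

* The generator's amplitudes and the TTI attenuation are plausible but
  invented; magnitudes of simulated accuracies track those choices and
  only directional comparisons are meaningful.
* The interval-selection heuristic is one concrete instance of
  r²-based interval picking; other variants (per-channel sign constraints,
  weighted channel sums) would select slightly different intervals.
* Whether the original random-set paradigm re-randomized the virtual
  matrix per flash or per sequence is ambiguous; the per-sequence reading
  is implemented (it is the only one that keeps "each letter flashes
  twice per sequence" and the row/column face assignment simultaneously
  true). A per-flash variant would break the exactly-twice invariant and
  is therefore not offered.
* Recordings live in memory and serialize to text (event-log TSV, JSON
  configurations and models); no binary EEG container format is written.

## A worked example

```{r example, eval = FALSE}
set.seed(7)
study <- run_speller_study()
study$accuracy |>
  filter(n_sequences == 1)
study$cv
prof <- tti_accuracy_profile(study$target_flashes)
plot_tti_profile(prof)
```

The `accuracy` tibble holds one row per paradigm and sequence count with
the selection accuracy, the selection duration used, and the resulting
ITR; `cv` holds the chronological cross-validation accuracies with
self-face/non-self-face strata for RASP-F. At the default configuration,
RASP-F reaches higher single-sequence accuracy than RC or RASP, and the
self-face stratum classifies better than the non-self-face stratum —
the effects the face overlays are designed to produce.
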