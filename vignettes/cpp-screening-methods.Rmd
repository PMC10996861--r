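---
title: "Methods: CPP-based screening of Smith–Magenis syndrome voices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CPP-based screening of Smith-Magenis syndrome voices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smsvoice)
```

## The problem

Smith–Magenis syndrome (SMS) is a rare genetic neurodevelopmental disorder
whose vocal phenotype includes hoarseness and dysphonia, plausibly linked to
excess laryngeal tension. Because the syndrome is underdiagnosed and genetic
confirmation (FISH) is invasive and slow, an acoustic screen based on
sustained-vowel recordings is attractive: it is cheap, fast and tolerable
for young children. `smsvoice` builds that screen around a *single* acoustic
measure — the cepstral peak prominence (CPP) — and an evaluation protocol
designed for very small, imbalanced cohorts.

This vignette documents the model, every tunable parameter, the numerical
choices, what the synthetic generators do and do not emulate, and the known
limitations. It states no result that the package's tests and acceptance
script do not themselves compute.

## The CPP model

A voice is periodic to the extent that its log-magnitude spectrum has a
regular harmonic ripple; the cepstrum (real part of the inverse FFT of the
log-magnitude spectrum) turns that ripple into a peak at the quefrency of
the fundamental period. CPP quantifies how much that peak stands out.

Per frame:

1. **Framing.** 1,024-sample frames, hop 128 (87.5% overlap). At the 16 kHz
   reference rate this is a 64 ms window every 8 ms — long enough to hold
   several glottal cycles of a child's voice, short enough to track
   fluctuation. Trailing samples that do not fill a frame are dropped; no
   padding, no pre-emphasis, no amplitude normalisation.
2. **Cepstrum.** `c = Re(IFFT(log(max(|FFT(x ⊙ w)|, ε))))` with `w` a
   Hamming window. The logarithm is natural; any other base rescales CPP by
   a constant and cannot affect classification, so the convention is
   harmless. `ε` (`log_floor`, default 1e−10) guards silent frames from
   `-Inf`: an all-zero frame yields a clean `log ε` impulse at quefrency 0
   and CPP 0.
3. **Quefrency smoothing.** A causal 7-tap FIR whose coefficients follow a
   Hamming shape normalised to unit sum, suppressing spurious single-bin
   peaks while keeping true ones. The same filter form is used for the
   temporal smoothing below; the two lengths are independently configurable
   (`smooth_len_cepstral`, `smooth_len_temporal`).
4. **Band-limited prominence.** The smoothed cepstrum is restricted to
   quefrencies 22–400 samples — fundamental periods from 727 Hz down to
   40 Hz at 16 kHz, bracketing the study population's f0 range. CPP is the
   band maximum minus the mean of the remaining `tmax − tmin` band values
   with exactly that one maximum removed. This makes CPP ≥ 0 by
   construction, which the tests assert.
5. **Temporal smoothing.** The per-frame CPP sequence is smoothed with a
   7-tap filter of the same form — 56 ms at the default hop and rate —
   reducing frame noise while preserving the large swings dysphonic voices
   show.

### Numerical and edge choices

* **Causal FIR edges.** At output indices with fewer than `l` history taps,
  the filter renormalises over the taps actually available instead of
  zero-padding. Constants are then preserved *everywhere*, which keeps the
  DC level of the cepstrum and of short CPP series unbiased; both smoothers
  satisfy this exactly (tested).
* **Rest-average definition.** Exactly one copy of the maximum is excluded
  from the "rest" mean (not a whole peak lobe); with the divisor
  `tmax − tmin` this reproduces a constant-plus-spike band height exactly.
* **No dB conversion.** CPP is left in linear log-magnitude units (typical
  sustained-vowel values ~0.05 after temporal pooling of windowed tables);
  no rescaling is applied anywhere.
* **No voicing detection.** The extractor assumes curated sustained
  phonation (minimum 500 ms) and processes every frame; quality control is
  the caller's job.
* **Non-16 kHz input** is accepted — `tmin`/`tmax` are quefrencies in
  samples at whatever rate the signal has — but a warning notes that the
  defaults encode the 40–727 Hz f0 range only at 16 kHz.

## Prime windowing

Speakers contribute CPP streams of unequal length, but classifiers need
fixed-width rows. The windowing stage chooses one subgroup size for the
whole cohort: among all primes `p` in `[3, nmin]` (`nmin` = smallest
per-speaker count), it picks the `p` minimising the total discarded
remainder `Σᵢ sᵢ mod p`. Each speaker's stream is then cut into
`floor(sᵢ/p)` consecutive groups in original temporal order, the tail is
discarded, and rows are named `speaker.k` with `k` from 1. Conservation
(`p·rows + discarded = sᵢ` per speaker) and loss minimality are tested on
randomised cohorts.

Two genuinely open choices, decided once:

* **Tie-break.** Equal-loss primes are resolved toward the *larger* prime
  (richer feature rows per sample); a message is logged whenever this
  fires.
* **Forced sizes.** `force_nprime()` lets a caller reproduce a fixed
  published configuration (e.g. `nprime = 7`) even when the minimiser
  differs; the plan still records the full candidate loss map for audit.
  This matters because a worked three-speaker example with counts
  14/21/24 selects 3 under the loss-minimisation rule (losses
  {3:2, 5:9, 7:3, 11:15, 13:20}), while fixed-width tables of width 7 are
  also in circulation for that cohort shape; the package computes the rule
  and leaves overrides explicit.

The restriction to primes is taken as a protocol given; composite sizes are
not offered.

## SMOTE balancing

Windowed cohorts are typically imbalanced. `balance_training_fold()`
computes the minority class per fold (never assumes it), and generates
`round(target_ratio × majority) − minority` synthetic rows: each is
`seed + λ(neighbour − seed)` with `λ ~ U[0,1]` and the neighbour drawn
uniformly among the seed row's `k = 5` (capped at `n−1`) nearest minority
rows in Euclidean feature space. Seed rows are cycled so generation spreads
uniformly. Only CPP features are interpolated; `Sex`/`Group` metadata are
copied from the seed row, and every synthetic row carries a `synthetic`
flag so the evaluation layer can prove none is ever scored. A fixed `k`
with an explicit config knob was chosen over a sample-size-dependent
schedule, which has no canonical formula; neighbourhoods are not stratified
by sex/group.

## Classifiers

Four supervised methods run behind one `fit_model()`/`predict()` contract:
random forest (`randomForest`, 100 trees), SVM (`e1071`, RBF kernel, cost 1,
with linear/poly/sigmoid selectable), LDA (`MASS`), and k-NN (`class`,
k = 5, uniform votes; an inverse-distance weighted vote is provided as a
small internal predictor since no installed implementation offers it).
Hyperparameter values for the published comparisons are not recoverable, so
library defaults are the baseline and `grid_search()` reproduces an
exhaustive sweep when wanted. Features are the CPP columns only; sex and
age-group remain metadata. Stochastic fits take a seed so evaluation runs
are bit-reproducible.

## Evaluation protocol

* **Leave-one-speaker-out.** One fold per speaker; all of a speaker's
  subgroups form the validation set together, preventing the leakage that
  would arise if subgroups of one child appeared on both sides. Folds whose
  training partition is single-class are an error, not a silent skip.
* **Iterations.** Each fold is scored `n_iterations = 10` times. Without
  SMOTE and with deterministic models the repeats are identical (tested);
  with SMOTE each iteration re-balances the training fold with that
  iteration's seed, so repeats vary and the per-speaker mean ± sd is
  meaningful. Accuracy is the fraction of the held-out speaker's rows
  classified correctly.
* **Pairwise comparison.** Per speaker, every pair of methods is compared
  by a Mann–Whitney rank-sum test on the two 10-value accuracy vectors:
  midranks for ties, `U = ΣR₁ − n₁(n₁+1)/2`, two-sided. The p-value is
  exact by complete enumeration when `n₁+n₂ ≤ 20` and tie-free (10 vs 10
  iteration vectors practically always contain ties, so they take the
  normal approximation with continuity and tie correction, matching the
  standard reference implementation to 1e−10 in tests). When every pooled
  value is identical the rank distances carry no information and the result
  is `NA` — exactly the convention seen when two methods sit at a constant
  100%. The two-sided alternative reflects the symmetric "do the methods
  differ" question; the independent-samples test is used, following the
  protocol's naming, although iterations are seed-paired — a signed-rank
  variant would be a defensible alternative and is deliberately not mixed
  in.

## Synthetic data: what it does and does not emulate

Two generator paths are decoupled on purpose:

* **Signal level** (`synth_vowel`): harmonics with 1/h roll-off built cycle
  by cycle, per-cycle f0 jitter and amplitude shimmer, white noise at a
  requested HNR, peak-normalised to 0.9. This controls exactly the
  periodicity properties CPP measures — tests verify peak localisation at
  `round(rate/f0)` and strictly decreasing mean CPP from 30 dB to 0 dB
  HNR — but it is *not* a physiological voice: no formants, no vocal-tract
  filter, no breath group dynamics.
* **Table level** (`synth_cohort`): per-speaker CPP values drawn i.i.d.
  from Gaussian cells per label × sex × age-group. Defaults mirror the
  study layout: 24 speakers (12 SMS / 12 normative, 3 per cell), 90–130
  values per speaker (a 24-speaker cohort of ~2,600 values), normative
  cells at mean 0.050, SMS cells at 0.030 with two higher-overlap cells
  (young girls 0.040, older boys 0.038), common sd 0.004. These magnitudes
  match the ~0.05 scale of windowed CPP tables, and the overlap structure
  reproduces the qualitative subgroup pattern reported for real cohorts.
  An audio-derived cohort path (`synth_audio_cohort`) confirms both
  generators agree on class ordering.

Because cells are well-separated Gaussians with no within-speaker
autocorrelation, classifier accuracies on the default cohort sit near
ceiling; passing the end-to-end test (balanced LDA ≥ 90% overall) shows the
pipeline is wired correctly, *not* that real SMS detection reaches such
rates. Real recordings add session effects, intra-speaker drift, and much
heavier class overlap for some subgroups.

## Problem sizes

Test and acceptance runs use the default 24-speaker cohort (~2,600 CPP
values, ~870 windowed rows), 10 iterations, and 0.5–1 s synthetic vowels;
these sizes make the whole suite run in well under a minute on one core
while keeping every protocol property observable at the study's own scale.

## Known limitations

* Only the max-minus-mean-of-rest CPP variant is implemented; no
  regression-line baseline, pitch tracking, jitter/shimmer measures or
  MFCCs.
* The WAV codec is minimal by design: mono PCM16/float32 only.
* GMM and K-means are out of scope (they cluster on metadata, not CPP, in
  this problem), as are deep models and ROC/AUC analysis.
* The windowing stage assumes streams are long enough (`nmin ≥ 3`) and
  offers no overlapping or adaptive windows.
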