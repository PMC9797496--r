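---
title: "Methods: pool-based active learning for sEMG grip decoder recalibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pool-based active learning for sEMG grip decoder recalibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

A myoelectric grip decoder maps short windows of multichannel surface EMG to
one of a small set of movement classes (here five grips plus rest). Decoders
trained in one session degrade in later sessions because the signal
distribution drifts. `emgal` implements an offline benchmark of
*pool-based active learning* for recalibration: the decoder trained on a
small initial labeled set repeatedly chooses, from the pool of unlabeled
first-session windows, the sample(s) whose annotation it expects to be most
valuable, a simulated annotator reveals the true labels, and the decoder is
refit. Test performance is always measured on a second, drifted session that
never influences training.

The decoder is deliberately simple: per-feature z-scoring (statistics learned
from the current labeled set only) followed by multiclass linear discriminant
analysis — Gaussian class conditionals with class means, one pooled
covariance, and class-frequency priors. Its assumptions are the usual LDA
ones: roughly Gaussian class clusters of a shared covariance on the feature
scale. Waveform length of band-limited EMG is amplitude-like and
right-skewed, so these assumptions hold only approximately; that is part of
the point — query strategies must help a plain decoder, not a tuned one. The
posterior `P(y | x)` from the Gaussian model drives the uncertainty scores.

Features are the waveform length `WL(w) = sum_i |w[i+1] − w[i]|` of each
channel in each window. A single feature per channel keeps the dimension at
the channel count (16 by default), which matters because the initial model is
fit on only 300 windows.

## The query strategies

For posteriors `p = P(y | x)`:

* least confidence `1 − max(p)` (pool argmax),
* smallest margin `p[1st] − p[2nd]` (pool argmin),
* entropy `−sum(p log p)` with natural log and `0 log 0 = 0` (pool argmax),
* random (passive baseline),

plus two batch modes: *naive* (top-n of a single-instance criterion;
for the random strategy the benchmark instead draws one window per class,
giving a class-balanced i.i.d. baseline) and *ranked batch-mode* (RBMAL).
RBMAL builds the batch greedily by

```
score(x) = alpha * (1 - Phi(x, D_estimate)) + (1 - alpha) * U_score(x)
alpha    = |U| / (|U| + |L'|)
```

where `D_estimate` is the labeled set plus the batch selected so far and
`Phi` is the candidate's highest similarity to it. Early in a run
(`alpha` near 1) selection favors samples unlike anything already labeled
(exploration); as the pool depletes it shifts toward raw uncertainty
(exploitation), and within a batch the growing `D_estimate` suppresses
near-duplicate picks.

Three choices here were genuinely open and are fixed as follows:

* **Similarity.** `sim(x, d) = 1 / (1 + euclidean(x, d))` on z-scored
  features: bounded in (0, 1], monotone in distance, and scale-free because
  the features are normalized with the current training statistics.
* **Uncertainty normalization.** `U_score` is min-max normalized over the
  current pool each iteration so both terms of the score share the [0, 1]
  scale. If every pool sample has identical uncertainty the normalized score
  is defined as 0 and selection is driven by dissimilarity alone.
* **Tie-breaking.** Deterministic everywhere: lowest pool index, except the
  first RBMAL step from an empty labeled set, where all `Phi` are 0 and ties
  are broken by higher raw uncertainty (so the first pick degenerates to
  pure uncertainty sampling, then by index).

## The experiment loop

Defaults mirror the standard offline design: classes are balanced by
under-sampling the rest windows (rest separates every grip repetition and
would otherwise dominate); the initial labeled set is the *chronologically
first* 50 windows of each class (300 total), mimicking a user annotating the
start of each cue; 1,500 single-instance queries or 250 batches of 6 (the
same annotation budget); a fresh normalizer + LDA fit every iteration; and
evaluation of every refit model on the full second session (`eval_every`
raises the evaluation stride when the learning curve is not needed at every
iteration, which is the main runtime lever). Per-class query counts are
logged so the class-wise demand profile of each strategy can be inspected.

Conventions worth stating: the averaged F1 is computed per class one-vs-all
and averaged unweighted; a class with no true members and no predictions has
undefined F1, which is scored 0 and reported via a message. If grip classes
arrive with unequal window counts, exact balance by removing rest alone is
impossible; the pool is then balanced to the largest grip class with a
warning (an off-by-one spread from windows clipped at the recording edges is
tolerated silently). Priors are estimated from training frequencies, which
under the balanced design are equal. The decoder is refit stateless each
iteration rather than updated incrementally, so every evaluated model is a
pure function of its labeled set.

## The synthetic data generator

No public dataset accompanies this design, so the package ships a seeded
generator whose defaults *are* the study conditions. Each channel carries
unit-variance Gaussian noise band-limited to 30–400 Hz (the surface-EMG
band), amplitude-modulated by the protocol: five grips plus rest, ten
repetitions per grip, 5 s of activation followed by 3 s of rest, 16 channels
at 2 kHz (optionally synthesized at a lower native rate such as 1,111 Hz to
exercise the up-sampling path). A grip's amplitude is the product of

* its `class_snr` (default 1 for all grips, relative to the unit carrier),
* the subject's per-channel gain profile for that grip (drawn once per
  subject from U(0.85, 1.15), normalized to mean 1 — the spatial signature
  that makes classes decodable),
* a per-repetition lognormal gain jitter (`trial_jitter_sd = 0.35`), and
* a slow (~2 Hz) lognormal drive-intensity fluctuation shared across
  channels (`envelope_noise_sd = 0.45`),

with 100 ms linear onset/offset ramps producing the transition windows a
cued protocol inevitably contains (retained by default, as a real pipeline
must cope with them). Rest is the same carrier at amplitude
`rest_sd = 0.1`.

Between-session drift applies per-class amplitude factors drawn from
U(0.75, 1.25), a 0.2 rad rotation mixing adjacent channel pairs (electrode
shift), and additive noise of sd 0.05. The two sessions of a subject share
the gain profiles but not the noise realizations.

The variability and drift magnitudes were calibrated once, before any
acceptance measurement, to a single target: the initial 300-window decoder
should score roughly 0.55–0.85 on the drifted test session across subjects —
the regime reported for real recordings of this kind — rather than saturate
near 1.0, where no query strategy could matter. They were not revisited
afterwards.

What the generator does *not* emulate: motor-unit physiology, muscle
synergies or correlated channel noise, force levels, electromechanical
artifacts, label noise from an imperfect human annotator, or inertial data.
Passing tests therefore demonstrate correct bookkeeping and the expected
*qualitative* behavior of the strategies under amplitude-profile class
structure and mild drift — not performance claims about any real cohort.

## Signal conditioning

The fixed chain is up-sample → Hampel → band-pass → window → waveform
length:

* **Up-sampling** by polyphase band-limited interpolation
  (`signal::resample`); linear interpolation would distort the 30–400 Hz
  band. Output length is exactly `round(n · fs_out / fs_in)`.
* **Hampel despiking** (half-window 5 samples, 3 robust sigmas — common
  practice; the windowed median/MAD is computed exactly, in compiled code,
  with windows truncated at the edges). A constant signal passes through
  unchanged because the zero MAD threshold is never strictly exceeded.
* **Band-pass**: 4th-order Butterworth, 30–400 Hz, applied
  forward–backward (zero phase) so filtering never displaces window labels
  in time. The signal is extended by odd reflection (five time constants of
  the low corner) before `filtfilt` and trimmed after, which suppresses the
  edge transient that would otherwise leak DC.
* **Windowing**: 128 ms windows (256 samples at 2 kHz), 50 ms step; window
  label is the majority class, ties to the class appearing earliest in the
  window; a `drop_transitions` switch discards impure windows for users who
  want clean-segment pools.

## Numerical choices and degenerate inputs

* The pooled covariance may be shrunk toward `mean(diag(S)) · I`; shrinkage
  defaults to 0 and the smallest power-of-ten intensity restoring a usable
  condition number (`rcond > 1e-10`) is applied automatically, with a
  message, if the covariance is singular — possible when the labeled set is
  small relative to the feature dimension.
* Posteriors are computed from discriminants with the row maximum subtracted
  before exponentiation, so they are finite for any input and sum to 1 to
  within 1e-9.
* Zero-variance features make z-scoring undefined and raise an error rather
  than being silently dropped.
* Every generator and the experiment loop consume randomness only through an
  explicit seed, and restore the caller's RNG state.

## Problem sizes used by the shipped tests and script

The test suite and `scripts/acceptance.R` run the full signal path at 3
repetitions per grip (about 1,800 balanced windows per session) with 200
queries, 10 subjects in the script and 20 seeds in the stochastic dominance
test — sizes chosen so a complete run is a coffee-break, not an afternoon,
while leaving several hundred pool windows per class for the strategies to
disagree over. Feature-space Gaussian pools (`generate_feature_pool()`)
stand in wherever signal realism is irrelevant, e.g. selector-vs-brute-force
equivalence and convergence checks.

## Known limitations

* The annotator is the stored true label: annotation is instantaneous,
  error-free, and per-window, which flatters all strategies equally but
  especially uncertainty sampling (a human would struggle to label single
  128 ms windows).
* Strategies are compared at equal query counts, not equal wall-clock or
  interaction cost; RBMAL's per-batch similarity computation is quadratic in
  pool size and noticeably heavier than the single-instance criteria.
* LDA's linear boundaries cap achievable accuracy on strongly non-Gaussian
  feature distributions; the package intentionally does not include
  nonlinear decoders or rejection thresholds.
* The exhaustive-run property (all strategies converge to the same accuracy
  once the pool is consumed) holds exactly here because the final labeled
  set is then identical; it says nothing about path quality, which is the
  entire practical difference between strategies.
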