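---
title: "Window-level detection of epileptiform discharges: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-level detection of epileptiform discharges: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Continuous EEG monitoring in intensive care produces far more signal than
clinical staff can read. A large fraction of ICU seizures are
non-convulsive and visible only in the EEG, and the interictal markers
that precede and accompany them — spikes (transients of 20–70 ms) and
sharp waves (70–200 ms) — are short, rare, and easy to miss. `iednet`
implements a window-level detector for these discharges: the recording is
cut into 160 ms windows and a classifier decides, window by window,
whether a discharge onset is present.

This vignette explains the models, the preprocessing conventions, the
synthetic data the package is validated on, and the numerical and design
choices a user or reviewer would want spelled out.

## Signal path

1. **Montage.** Input is a 19-electrode referential recording in the
   10–20 system. The detector operates on the 16-channel longitudinal
   bipolar ("double banana") montage: four chains of adjacent-electrode
   differences (left/right temporal, left/right parasagittal; the midline
   chain is excluded so the model input stays 16 channels). Bipolar
   derivation cancels common-mode reference activity, and a discharge
   focused at an interior electrode produces the classic "tip to tip"
   phase reversal on the two derivations sharing it — the morphological
   signature clinicians use, and the one the synthetic generator
   reproduces.
2. **Resampling.** All recordings are brought to 125 Hz: a zero-phase
   low-pass FIR (forward–backward filtering, cutoff below the new
   62.5 Hz Nyquist) followed by sub-selection; non-integer ratios go
   through rational zero-stuff/filter/sub-select resampling. Zero-phase
   filtering matters because annotations are time points: a causal filter
   would delay signal features relative to their labels. Annotation times
   are stored in seconds and are unaffected.
3. **Windowing.** Non-overlapping 20-timestep windows (8 ms per step,
   160 ms per window) starting at time zero; a trailing partial window is
   dropped. Each window row (channel) is min–max normalized to [0, 1]
   within the window; a constant row maps to 0.5. Per-window (rather than
   per-recording) scaling bounds the model input regardless of slow
   amplitude drift; the alternative is deliberately not mixed in.
4. **Labels.** A window is positive iff a positive annotation onset falls
   inside it (half-open interval, 0-based window indices). With the
   k-windows-early scheme, window *i* instead receives the label of
   window *i + k*, so a trained model fires *k* windows (0.16 s·k) ahead;
   the last *k* windows of each recording are dropped. Labeling uses the
   marked time point only, matching how clinicians annotate discharges;
   an any-overlap rule is available (`rule = "overlap"`) but off by
   default.
5. **Split.** Windows pooled over recordings are split per class 8:2 into
   pseudo-train/test and the pseudo-train again 8:2 into train/validation
   — 64/16/20 overall, preserving prevalence in every partition. Floors
   go to the smaller share, remainders to train. The split seed is
   recorded in the run manifest.
6. **Class weights.** weight_i = (total training count)/(training count
   of class i), no normalization; each class then contributes equal total
   weight to the loss. At the default ~8% prevalence this weights the
   anomaly class ≈ 12×.

## Models

Both classifiers map a normalized 16 × 20 window to two softmax
probabilities; the positive class is index 1 and a window is flagged iff
P(anomaly) ≥ 0.5 (the exact tie goes to the positive class, documented
and tested).

**GRU model (primary).** The window is read as a 20-step sequence of
16-channel observations by two stacked 64-unit GRU layers (standard
update/reset gating, h' = (1−z)∘h + z∘h̃). Only the final hidden state of
layer 2 feeds the head: a 64→32 fully-connected layer with ReLU, then
32→2 with softmax. Input kernels are Glorot-uniform, recurrent kernels
random orthogonal (the conventional recurrent initialization — an
orthogonal recurrent matrix preserves state magnitude across the 20
steps, where a sub-unit-spectral-radius random matrix would wash early
timesteps out), biases zero.

**CNN comparison model.** The window is treated as a 16 × 20 one-channel
image: two blocks of [3×3 convolution, 64 filters, stride 1, same
padding → batch normalization → ReLU], no pooling (the plane is only
16 × 20), flattened into the same 32-unit ReLU head. Batch statistics are
used in training; exponential running statistics (momentum 0.9) at
inference.

**Training.** Adam (learning rate 1e-4 by default), batch size 512,
class-weighted cross-entropy averaged over the batch. After every epoch
the validation partition is scored; the checkpoint with the best
validation metric — balanced accuracy by default, plain accuracy as the
alternative — is kept, ties resolved to the earliest epoch. The faithful
epoch budget for a full study is 500; package defaults use a desk-scale
30 (see "Problem sizes" below). Training is deterministic given the
seed: weight initialization and all per-epoch shuffle orders are drawn in
R before the compiled training loop runs. The GRU core is C++
(RcppArmadillo) with input projections and gradient reductions batched
across timesteps into single GEMMs; gate nonlinearities use a rational
tanh approximation accurate to ~1e-7, an order of magnitude faster than
the libm call and equally deterministic. The CNN is base R over BLAS
matrix products (shift-decomposed convolution). Cross-platform floating
point drift can move individual metrics at the 1e-3 level; within one
platform runs reproduce exactly.

## Evaluation

Counts TP/FN/FP/TN are tallied exactly; accuracy, sensitivity,
specificity are the standard ratios and balanced accuracy their
arithmetic mean (of sensitivity and specificity), all reported as
percentages, printed to two decimals. A ratio with an empty denominator
is NaN with a warning, never silently zero. The zero-rule baseline (the
constant majority-class predictor) scores accuracy = majority prevalence,
sensitivity 0, specificity 100, BA 50 on any two-class data — a floor
every model must clear under class imbalance.

The early-detection sweep retrains the class-weighted, BA-selected GRU
from scratch for every k (relabel → re-split with the same seed policy →
train → test); reusing a k = 0 model with shifted labels would conflate
label shift with model reuse and is deliberately not done.

## The synthetic generator

The clinical recordings the detector was designed around are private, so
the package ships a seeded generator whose output has the statistical and
morphological structure the detector assumes:

- **Background**: per-electrode colored noise with amplitude ∝ 1/f
  (power ~ 1/f², the empirical scaling of scalp EEG; flat below 1 Hz),
  6 µV RMS by default, plus a shared 8–12 Hz posterior-dominant rhythm at
  half that amplitude with slow envelope modulation and per-electrode
  gain jitter. The steep spectrum gives smooth traces at 125 Hz, as in
  real EEG — against which short transients are salient "at a glance".
- **Events**: a renewal process (exponential gaps plus the previous
  event's duration as dead time) at 31 events/min, chosen so the
  probability that a 160 ms window contains an onset is ≈ 8% — matching
  the ~92% zero-rule accuracy regime the detector is meant for. Event
  type is spike or sharp wave with equal probability; durations are
  uniform in 20–70 ms and 70–200 ms respectively.
- **Morphology**: each event is a smooth biphasic pulse — a difference of
  two raised cosines with a steep rise to a dominant apex at 18% of the
  event duration and a smaller opposite rebound (the after-going slow
  wave). Epileptiform discharges are apiculate: the fast upstroke and
  early apex are the feature clinicians react to. The sampled pulse is
  rescaled so the configured amplitude (uniform 120–180 µV at the focus)
  is the realized peak even for spikes a few samples long. The focus
  electrode receives the full pulse, its chain neighbours 50% — the
  minimal spatial model that guarantees a bipolar phase reversal whose
  peak deflections exceed 3× the background RMS of those derivations.
- **Annotation semantics**: the annotation marks the apex time, not the
  latent physical start of the transient. This mirrors clinical
  annotation practice — a reader clicks on the discharge where it is most
  prominent — and it matters quantitatively: with start-time annotations
  and onsets uniform relative to the window grid, any event beginning
  late in a window has its apex (almost all of its evidence) in the
  following, negatively-labeled window, which caps the achievable
  window-level sensitivity near 75% no matter how well the model is
  trained. Marking the apex guarantees the labeled window contains the
  event's most salient samples.
- **Persistence**: EDF(+) files (16-bit, 1 s records, physical units µV,
  annotations as EDF+ TALs) plus a ground-truth CSV. Everything is a
  deterministic function of the configuration, including its seed.

What the generator deliberately does **not** emulate: artifacts (eye
blinks, EMG, electrode pops), ictal rhythms, electrode drift,
inter-patient variability, or any temporal clustering of discharges
(arrivals are memoryless). Consequences for interpreting results on
synthetic data: specificity here is not challenged by artifacts, which
are the dominant false-positive source in real EEG; and with memoryless
arrivals there is no predictive signal k windows ahead of an onset, so
early-detection (k > 0) performance on synthetic data reflects only
boundary spillover, not the pre-ictal structure real EEG may carry.
Passing tests demonstrate that the pipeline and models are wired
correctly and that the detector learns the morphological signature it
was designed for — not that these numbers transfer to clinical data.

## Numerical choices and degenerate inputs

- Constant rows normalize to 0.5 (the map is undefined at max = min).
- Window/label boundaries are half-open with a 1e-9 relative epsilon in
  the floor, so an onset exactly on a boundary belongs to the window it
  opens.
- Undefined metric ratios are NaN + warning; the all-zero confusion
  table is an error.
- EDF quantization uses a symmetric per-channel physical range (whole
  microvolts); round trips are exact to one quantization step.
- Resampling refuses rates below 125 Hz (upsampling is out of scope).
- Softmax is computed with the max-subtraction trick; probabilities of
  the true class are floored at 1e-12 inside the log.
- A non-finite training loss aborts with a diagnostic rather than
  continuing.

## Problem sizes

Package defaults and the bundled acceptance/test runs use desk-scale
sizes chosen so a full end-to-end experiment (45 minutes of EEG,
~16,900 windows, 30 training epochs) completes in a few minutes on one
CPU core: three 15-minute recordings at 250 Hz, 30 epochs. The
early-detection sweep in the test suite uses a 15-minute corpus and 12
epochs per k. The faithful full-study settings (500 epochs, hours of
EEG) are plain configuration changes (`epochs`, `duration`,
`n_recordings`).

## Known limitations

- The desk-scale default training budget (30 epochs of ~21 batches at
  learning rate 1e-4, i.e. a few hundred Adam steps) is far short of
  convergence for this task — the loss is still falling at the last
  epoch and the best-epoch checkpoint is typically the final one — so
  metrics obtained under it substantially understate the architecture.
  Separately, a ~45-minute corpus at 8% prevalence contains under a
  thousand positive windows spread over twelve focus electrodes, two
  event types and every window phase, which limits generalization even
  under long training. Both are visible in `training_history()`; larger
  corpora and the faithful 500-epoch budget are plain configuration
  changes (`duration`, `n_recordings`, `epochs`).
- Window-level metrics are not event-level metrics: an event detected in
  the window after its onset counts as both a miss and a false alarm.
- The stratified split pools windows across recordings, so windows from
  one recording appear in train and test; subject-level generalization
  is deliberately not claimed (`per-recording` splitting would be the
  tool for that and is out of scope here, matching the pooled design).
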