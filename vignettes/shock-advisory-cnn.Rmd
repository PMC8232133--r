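---
title: "Shock-advisory ECG analysis during chest compressions: models, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shock-advisory ECG analysis during chest compressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ccshock)
```

## The problem

During cardiopulmonary resuscitation (CPR), automated external defibrillators
must decide whether the underlying rhythm is shockable — coarse ventricular
fibrillation (VF) — or non-shockable — organized rhythms (OR) or asystole —
while chest compressions (CC) are ongoing. Compressions couple large
quasi-periodic artifacts into the single defi-pad ECG lead, often burying the
rhythm. `ccshock` implements an end-to-end approach: a fully convolutional
network reads the raw 10 s compression-corrupted strip (125 Hz, 5 µV/LSB,
1–30 Hz band) and outputs the probability `pSh` that the rhythm is shockable,
with no artifact pre-filtering and no auxiliary sensor channel.

Real out-of-hospital cardiac-arrest (OHCA) recordings of this kind are
restricted, so the package also ships a synthetic CC-ECG simulator that
reproduces the *statistical structure* of such data — amplitude-defined
rhythm classes, compression artifacts at realistic rates, and controlled
corruption levels — making every pipeline stage testable end to end.

## The network

For a 1250-sample input, the model applies `N` convolutional blocks. Block
`i` holds `F_i` filters of kernel size `K_i` applied with valid padding
(output length `L - K_i + 1`), a ReLU, a non-overlapping max-pool of size 2
(length halved, floor), and dropout at rate 0.3 (training only; inference is
a pass-through). After block `N`, global max pooling (GMP) reduces each
filter's activation to its temporal maximum, and a one-unit dense layer with
a sigmoid maps the `F_N` features to `pSh ∈ [0, 1]`. A strip is called
shockable when `pSh ≥ pTHR`, the boundary inclusive.

The trainable-parameter count has the closed form

    Params = Σ_i F_i (K_i F_{i-1} + 1) + (F_N + 1),   F_0 = 1,

which `count_params()` evaluates and which every `build_model()` result must
match exactly (`n_trainable()` counts the allocated arrays independently).
`shape_trace()` propagates the temporal lengths; both contracts are enforced
by property tests over hundreds of random configurations.

`cnn3_preset()` is the selected three-block network: filters (5, 25, 50),
kernels (10, 20, 20), 27,681 parameters, shapes
1250 → 1241 → 620 → 601 → 300 → 281 → 140 → GMP(50). The published
description of this network prints a first-block kernel of 5 alongside a
first-block parameter count of 55 and shape (620, 5); under the parameter
formula and valid padding these are mutually inconsistent, and only
K = (10, 20, 20) reproduces *both* the printed counts and the printed
shapes, so the preset adopts that internally consistent reading.

Two further conventions resolve ambiguities in the width formulas: pooling
drops a trailing odd sample (`floor`), validated by the printed chain
1241 → 620 and 281 → 140; and the valid-convolution output length is
`L − K + 1` (the printed index range has an off-by-one). With seven blocks
of minimal kernel 5, the terminal feature length is exactly 5 samples — the
depth limit of the search space.

### The engine

No deep-learning framework is declared: the network, its exact backward
pass, Adam, and binary cross-entropy are implemented in base R, with the
convolution realized as an indexed im2col gather feeding one BLAS matrix
product per block. This keeps the dependency surface minimal and every run
bit-reproducible given its seeds. The backward pass is verified against
central finite differences (relative error below 1e-7 in tests of every
parameter group). Weights initialize uniformly on [-0.05, 0.05], biases at
zero. Inputs are fed at their native 5 µV/LSB resolution (microvolts divided
by 5) with **no normalization**: absolute amplitude is class-defining
(asystole < 100 µV peak-to-peak, coarse VF > 200 µV), so standardizing
per-strip would destroy signal the classifier needs.

## Training protocol

`train_cnn()` follows the fixed protocol: shuffled batches of 256, Adam with
learning rate 0.001, β₁ = 0.9, β₂ = 0.999, binary cross-entropy, at most 400
epochs. After every epoch the full validation set is scored at threshold 0.5
and balanced accuracy BAC = (Se + Sp)/2 recorded; the best-epoch weights are
retained and training stops once `patience` (default 150) epochs pass
without a strict improvement. Class imbalance is handled by
`oversample_balance()`: the shockable minority is replicated `factor` times
(the protocol's factor 6 encodes a ≈ 1:6.4 imbalance; for differently
balanced synthetic sets the factor that equalizes the classes is the
faithful choice). The operating threshold `pTHR` is *not* the training
monitor's 0.5: it is chosen afterwards on the validation ROC at maximal BAC
(`select_threshold()`, ties towards higher sensitivity, then the lower
threshold), and only then applied to test data.

Two unstated details are fixed as follows: the per-epoch monitor is computed
on the full validation set (not batchwise), and when a degenerate validation
set contains one class the monitor falls back to plain accuracy so early
stopping still terminates with the majority behaviour.

## Architecture search

`sample_hp()` draws depth uniformly from {2, …, 7} and filter/kernel vectors
from the grids F ∈ {5, 10, 15, 20, 25, 30, 40, 50},
K ∈ {5, 10, 15, 20, 25, 30, 40, 50, 60, 70, 85, 100}. Each vector must
follow one of seven depth trends — constant; strictly increasing;
constant-then-increasing; increasing-then-constant; and the three decreasing
mirrors (`validate_trend()`). The sampler draws a scenario uniformly, then
values uniformly among grid subsets compatible with it, and rejects
candidates that are shape-infeasible for 1250 samples or exceed the 250,000
parameter budget; the budget is enforced at sampling time (before any
training cost is paid). F- and K-trends are sampled independently. Constant
minimal-kernel vectors are always feasible, so rejection terminates.
`run_search()` trains every candidate under identical conditions and ranks
by validation BAC; all per-model seeds derive from one master seed, making
the search reproducible bit for bit.

## The simulator

Only amplitude and rate constraints of the rhythm classes are specified by
the study setting; the waveform morphologies are this package's stand-ins
and claim no physiological fidelity:

* **VF** (`gen_vf()`): white noise filtered into a narrow band whose centre
  performs a slow random walk inside ≈ 4–7 Hz (three cross-faded segments),
  plus a weak 1–30 Hz floor; scaled so the post-quantization peak-to-peak
  equals the requested amplitude (> 200 µV, default 500 µV; dataset draws
  U(300, 900) µV).
* **OR** (`gen_or()`): a PQRST template (sum of Gaussian deflections, R-wave
  normalized) convolved with a beat train at 30–180 bpm with 3% RR jitter,
  plus baseline wander; default R amplitude 800 µV.
* **Asystole** (`gen_asystole()`): low-pass noise plus slow drift, scaled to
  a peak-to-peak in [5, 100) µV (dataset draws ≈ U(30, 85) µV).
* **CC artifact** (`gen_cc_artifact()`): a four-harmonic series on a
  per-cycle jittered phase (period jitter 1.5%, amplitude jitter ±15%) at
  80–160 compressions/min; a `spiky` mode adds one narrow biphasic pulse per
  compression (the morphology class that mimics QRS- or VF-like patterns and
  drives classification errors); `30:2` inserts a ~4 s ventilation gap with
  tapered edges. The default is continuous compressions, matching the
  inclusion criterion of ≥ 10 s of CC over the analysis window.

All strips are band-limited to 1–30 Hz with a zero-phase Butterworth filter,
generated natively at 125 Hz, and quantized to the 5 µV grid.

### SNR calculus

The corruption level is `SNR = 10·log10(P_clean / P_corrupted)` with power
the variance of each 10 s signal about its mean (`compute_snr()`), binned as
very strong (≤ −9 dB), strong (−9, −6], moderate (−6, −3], weak (> −3 dB).
Because the corrupted strip *contains* the clean signal, an additive mixture
cannot reach SNR ≥ 0: `mix_at_snr()` therefore removes the artifact's
projection onto the centred clean signal and scales the orthogonal remainder
to power `P_clean(10^(−SNR/10) − 1)`, which meets negative targets exactly
before quantization (tests require 0.2 dB after quantization). For requested
SNR ≥ 0 dB the artifact's own power is set to `P_clean·10^(−SNR/10)` and the
achieved metric value is recorded on the strip — one metric, reported
honestly. Default per-rhythm target distributions mirror the study's
corruption profile: VF −6.7 ± 4.8 dB, OR −6.3 ± 6.4 dB, asystole
−22.4 ± 10.1 dB (compressions dominate asystole's tiny intrinsic power).

Compression rate is estimated from the dominant peak of a Hann-windowed,
zero-padded periodogram in 1.33–2.67 Hz (`estimate_cc_rate()`; a peak must
exceed ten times the in-band median power, otherwise the rate is declared
undetectable), and binned as slow (< 100), normal (100–110 and 110–120,
boundary 110 assigned upward to the metronome bin), rapid (> 120 min⁻¹).
Rate distributions default to Normal(110, 15) truncated to [80, 160],
centred on the metronome rate.

## Evaluation

`evaluate_model()` applies a threshold fixed on validation data and reports
confusion counts, Se over shockable strips, Sp overall and separately for OR
and asystole, BAC, the ROC with trapezoidal AUC (equal to the Mann–Whitney
pair statistic with ties counted one half — a property test), and Se/Sp
stratified by SNR level and compression-rate range. Proportions carry Wilson
95% confidence intervals (the interval method is otherwise unspecified;
Wilson behaves well at the small per-stratum counts these tables produce).
Strata without strips are omitted rather than reported as zero. Display
rounding is one decimal in percent.

## Problem sizes and what the tests show

The test suite exercises the full pipeline at desk scale, chosen so the
whole suite runs on a single CPU in well under half an hour:

* architecture/metric arithmetic: closed form, instant;
* parameter/shape contracts over 200 random configurations; ROC oracles over
  100 random score sets; SNR round-trips over [−20, −1] dB; 1000 sampler
  draws;
* an end-to-end run: the preset trained on a 600-strip weak-artifact
  dataset (400 training / 200 validation, targets at −2 dB, minority
  replication factor 2) reaching validation BAC ≥ 0.90 within 100 epochs;
* a miniature search: 10 candidates, ≤ 50 epochs each (patience 5) on a
  90-strip set, run twice to demonstrate bit-identical ranking.

Passing these shows the machinery is correct and the training dynamics
behave on separable synthetic data. It does **not** show clinical
performance: synthetic waveforms lack the morphological diversity of real
OHCA recordings (rescuer-dependent artifact shapes, electrode artifacts,
rhythm transitions, ventricular tachycardia), and headline numbers from the
restricted real-data study are not reproducible here. The stratified
machinery, however, reproduces the expected qualitative behaviour: accuracy
degrades as artifacts strengthen, and the spiky artifact morphology is the
error-prone one.

## Known limitations

* Waveform realism is intentionally limited; see above.
* The engine is CPU-bound R + BLAS: adequate for desk-scale experiments,
  not for searches of hundreds of models.
* Only the 125 Hz native path is implemented; a 500 Hz acquisition chain
  with anti-alias decimation is out of scope.
* No significance testing across strata is provided, and no calibration
  analysis of `pSh`.
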