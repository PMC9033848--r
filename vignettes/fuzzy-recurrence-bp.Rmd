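---
title: "Estimating blood pressure from pulse waveforms with fuzzy recurrence plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating blood pressure from pulse waveforms with fuzzy recurrence plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Continuous, cuffless blood-pressure monitoring from a single optical pulse
waveform (a photoplethysmogram, PPG) requires learning a nonlinear map from
short waveform windows to scalar systolic (SBP) and diastolic (DBP) pressures.
The PPG is pseudo-periodic: its beat-to-beat recurrence structure carries
information that a purely sequence-based 1-D convolutional model uses only
implicitly. `frpbp` makes that structure explicit by converting each window
into a **fuzzy recurrence plot** (FRP) — a grayscale image of pairwise state
similarities in reconstructed phase space — and feeding the raw 1-D window and
its 2-D FRP into a two-stream convolutional regressor whose feature maps are
fused before the dense head.

## From a window to a fuzzy recurrence plot

1. **Delay embedding.** A window $x_1,\dots,x_L$ becomes trajectory states
   $r(p) = (x_p, x_{p+\tau}, \dots, x_{p+(m-1)\tau})$, $p = 1..N$,
   $N = L-(m-1)\tau$. The source material never states $m$ or $\tau$; we default
   to $m = 3$, $\tau = 5$ samples (40 ms at 125 Hz), standard practice for pulse
   waveforms. Both are configurable.
2. **Decimation.** The trajectory is thinned to the configured plot side $S$ by
   uniform index selection `round(seq(1, N, length.out = S))`. This keeps the
   plot a genuine state-similarity matrix; we deliberately avoid image
   interpolation, which would blur similarity semantics.
3. **Fuzzy c-means.** States are clustered into $c$ overlapping clusters by
   minimising $J(U,Z)=\sum_i\sum_k \mu_{ik}^{\omega} d(x_i,z_k)^2$ with the
   classical alternating updates, $\omega = 2$, stopping when
   $\max|U(t)-U(t+1)| \le \alpha$. The cluster count is never stated in the
   source; we default to $c = 3$, the common choice in the FRP literature,
   which yields the coarse cluster texture the plots are known for.
   $\alpha = 10^{-5}$ and at most 300 iterations; initialisation is a seeded
   uniform random row-normalised membership matrix, so runs are reproducible.
   A state coinciding with a center receives crisp membership in the first
   zero-distance cluster (ties broken by lowest index). A cluster whose
   membership column collapses keeps its previous center, which lets degenerate
   inputs (e.g. a constant window, where all states coincide) converge to the
   correct all-ones plot instead of erroring.
4. **Max–min composition.** The plot entries are
   $M_{ij} = \max_k \min(\mu_{ik},\mu_{jk})$ with $M_{ii}=1$ imposed
   explicitly as the reflexivity axiom. $M$ is symmetric with entries in
   $[0,1]$: a grayscale, threshold-free recurrence image. The classical binary
   plot ($R_{ij} = 1$ iff the state distance is below $\varepsilon$, strict
   inequality at exactly $\varepsilon$) is kept as a baseline in
   `binary_rp()`.

The network consumes $M$ directly; `frp_image(..., invert = TRUE)` is a
rendering option only (the source never states a polarity convention).

The default plot side is 88, the optimum of the source's size sweep. The
source elsewhere mentions 89 × 89 inputs without explanation; 89 remains
reachable via configuration, and we default to the sweep optimum.

## The two-stream regressor

* **1-D stream** (raw window): six convolutional blocks, kernel length 25 in
  every conv layer, default filters 32, 32, 64, 64, 128, 128, each block conv →
  batch-norm → ReLU; average pooling (factor 2) after blocks 1–4; dropout 0.25
  after blocks 5 and 6; flatten.
* **2-D stream** (FRP): exactly seven 3 × 3 convolutional layers (default
  filters 16, 32, 32, 64, 64, 128, 128), each followed by batch-norm and ReLU;
  2 × 2 average pooling after every ReLU except the last two (sides
  88→44→22→11→5→2); flatten. Sides below 32 cannot survive the five poolings
  and are rejected.
* **Fusion.** Four operators are implemented (`fuse()`): elementwise sum,
  elementwise max, channel concatenation, and conv fusion (stacking followed
  by a 1 × 1 convolution). Concatenation is the default, as in the reference
  architecture. In the full model the fusion operates on the flattened stream
  outputs: the two streams cannot share spatial shape, and co-located stacking
  of flat feature vectors immediately ahead of the dense layers is exactly
  what the architecture diagrams describe. Sum/max/conv fusion therefore
  require equal stream widths in the model.
* **Head**: dense 256 → ReLU → dropout 0.25 → dense 64 → ReLU → dense 1
  (linear). One model per target: SBP and DBP are estimated by separately
  trained networks.

Per-layer filter counts are read from an architecture figure that is not fully
legible in text form; the defaults above are monotone-widening and small
enough for CPU training, and every count is configurable. The "30 consecutive
layers" total given for the 1-D model is treated as descriptive because the
layer-counting convention (input/output/flatten included or not) is unstated.

### Training

Loss is mean squared error (the source reports MSE/MAE but never names its
training loss; MSE is the simplest consistent choice). Optimiser is Adam with
learning rate 0.001 and batch size 100. Targets are z-scored internally from
the training set and mapped back to mmHg at prediction time, keeping the loss
surface well scaled for that learning rate. Maximum 300 epochs with early
stopping on validation loss (patience 30, best weights restored) — the source
observes overfitting beyond roughly 300 epochs but states no stopping rule, so
we added a standard one. Everything (weight init, shuffling, dropout masks) is
seeded; identical seeds give identical training histories.

The layer engine itself (shift-and-GEMM convolutions with hand-written
backpropagation, batch normalisation with running statistics, Adam) is part of
the package and is verified against central finite differences in development
and against independent shape/fusion oracles in the test suite.

## Evaluation

`compute_metrics()` reports MAE, MSE, ME (bias), $R^2$, Pearson's $R$, and
STD over paired targets/predictions. STD is the **population standard
deviation of the estimation errors**: that is the quantity the AAMI criterion
and "MAE ± STD" reporting require, and it gives the exact identity
$\mathrm{MSE} = \mathrm{STD}^2 + \mathrm{ME}^2$, which the test suite asserts
on random vectors. (A literal reading of the printed STD formula would measure
the spread of the reference values instead; we document and depart from that.)
$R$ and $R^2$ are undefined for constant inputs and are returned as `NA` with
explicit flags, never silently as zero.

`bhs_grade()` implements the BHS bands — a grade requires **all three**
cumulative thresholds simultaneously (A: 60/85/95% of absolute errors within
5/10/15 mmHg; B: 50/75/90; C: 40/65/85; otherwise D). Band boundaries are
inclusive; boundary samples are measure-zero for continuous errors.
`aami_check()` passes when $|\mathrm{ME}| \le 5$ mmHg, STD $\le 8$ mmHg and
more than 85 subjects were used. `bland_altman()` takes differences as
estimate − reference, bias ± 1.96 · SD limits of agreement, and reports the
fraction of points inside the limits.

## The synthetic generator

Clinical waveform databases cannot ship with a package, so `generate_record()`
emulates the study conditions: 125 Hz pseudo-periodic pulse trains in which
each beat is a two-Gaussian template — a systolic wave of amplitude
$a_0 + a_1(\mathrm{SBP}-120)/40$ and a dicrotic wave of amplitude
$b_0 + b_1(\mathrm{DBP}-80)/30$ ($a_0{=}1, a_1{=}0.5, b_0{=}0.4, b_1{=}0.3$) —
with per-beat heart-rate jitter (75 ± 3 bpm), additive white noise
(SD 0.02), and sinusoidal baseline wander (amplitude 0.1 at 0.2 Hz). SBP and
DBP follow per-beat bounded random walks (SBP start 120, step SD 2 mmHg,
bounds 95–180; DBP start 80, step SD 1.5, bounds 50–90 — the bounds are kept
disjoint so systolic always exceeds diastolic). Labels are aligned per sample;
a window's target is the mean label inside it.

The coupling coefficients are artifact choices: real PPG–BP relationships have
no closed form, and the generator only needs to make blood pressure
recoverable *in principle*. What passing end-to-end tests show is therefore
that the pipeline — embedding, FRP, two-stream network, training loop — can
extract a morphology-encoded pressure signal; they say nothing about accuracy
on clinical recordings, where the PPG–BP relationship is subject-specific,
nonstationary and confounded by medication, illness and measurement artefacts.
The generator also does not emulate sensor saturation, motion artefacts, missing
data, or inter-subject morphology differences.

Records are split chronologically **within each record** — first 70% of
segments to training, next 10% to validation, last 20% to test (floor counts,
remainder to test) — mirroring the per-record-length split of the reference
protocol and preventing within-window leakage across splits. Whether segments
of one subject may span train/test is not specified there; the chronological
per-record split is the literal reading, and a strict subject-held-out split
can be had by simply training on a separate set of generated records.

## Problem sizes used by the checks

The packaged end-to-end checks (acceptance test and `scripts/acceptance.R`)
use a desk-scale configuration chosen once: 15 records of 410 s (~3000
non-overlapping 256-sample windows), 32 × 32 plots, a narrow concat model
(filters 8–32 in the 1-D stream, 8–64 in the 2-D stream), batch 100, learning
rate 0.001, at most 10–12 epochs with patience 4. On one CPU core this trains
in a few minutes and recovers SBP with a held-out MAE far below half of the
constant-mean-predictor baseline. The spec-scale defaults (window 1024, side
88, full filter widths) remain the package defaults for real use.

## Known limitations

* The clustering restarts from one seeded initialisation per segment; fuzzy
  c-means is only locally convergent, and different seeds can give slightly
  different plots. The max–min composition is relabel-invariant, which removes
  the label-permutation part of that ambiguity.
* The training engine is plain R + BLAS; it is deliberately narrow (the layer
  kinds this architecture needs, stride-1 same-padded convolutions, factor-2
  average pooling) and CPU-oriented. It is not a general deep-learning
  framework.
* Headline clinical accuracies require the original ICU waveform corpus and
  are out of scope here; the package's evidence is oracle agreement for every
  primitive plus parameter recovery on its own generator.
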