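---
title: "Detecting knee instability in squat exergaming: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting knee instability in squat exergaming: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squatstab)
```

## The problem

Repeated squatting under load can provoke *dynamic knee instability*:
involuntary, oscillatory mediolateral movement around the knee joint. In an
exergaming setting the movement is recorded by two unsynchronized devices —
a depth camera tracking the mediolateral (ML) position of each knee and the
vertical torso position at roughly 60 Hz, and a force plate sampling the
center of pressure (CoP) at 50 Hz. squatstab implements the full analysis
chain from these two raw streams to a per-squat binary classification:
knee instability (KI, label 1) versus none (NKI, label 0).

The chain is: synchronize the two streams by linear interpolation onto a
common 50 Hz grid; low-pass filter (4th-order Butterworth, 5 Hz, zero
phase); segment squat cycles from the torso trajectory with
spurious-detection rejection; compute five features per squat; label each
squat by a dimensional knee-shakiness threshold; rank features by Spearman
rho and phi correlation with the labels; and train/evaluate an LSTM sequence
classifier and an RBF-kernel SVM on the benchmark feature sets.

## Features and labeling

With `x_lk`, `x_rk` the ML knee positions, `y_torso` the vertical torso
position, and `CoPx`, `CoPy` the CoP coordinates (all meters on the common
grid with step $\Delta t$):

1. **Knee shakiness (KS, m/s)** — backward-difference knee velocities
   $V_l(t) = (x_{lk}(t)-x_{lk}(t-1))/\Delta t$, $V_r$ likewise. The default
   statistic is $|V_l|+|V_r|$: a plain signed sum cancels exactly when the
   knees oscillate in antiphase (the valgus-like pattern), which is the
   phenomenon of interest; the signed variant is kept as a mode flag.
2. **Knee distance (KD, m)** — $|x_{lk}-x_{rk}|$. The absolute value makes
   the feature independent of the axis orientation convention.
3. **Squat depth (SD, m)** — baseline standing torso height $y_{t1}$ minus
   the torso height; the per-squat scalar is $y_{t1}-\min y_{torso}$
   (positive depth; the raw minimum-minus-baseline difference is exposed by
   a sign flag).
4. **Sway velocity (SV, m/s)** — CoP step displacement
   $\delta(t)=\sqrt{\Delta CoPx^2+\Delta CoPy^2}$ divided by $\Delta t$.
5. **Sway area (SA, m²)** — origin-anchored shoelace increments
   $|CoPx(t{+}1)CoPy(t)-CoPx(t)CoPy(t{+}1)|/2$, summed per squat and divided
   by the window duration by default.

For SV and SA the product forms $\delta\cdot\Delta t$ and
$a(t)\cdot\Delta t$ that appear in some formulations are dimensionally
inconsistent with standard posturography (division by the time step is the
norm); the package defaults to the standard rate forms and reproduces the
product forms under `as_printed = TRUE`. Both are tested.

A squat is labeled KI when its peak $|KS|$ reaches **0.03 m/s** (boundary
inclusive). Two ordering decisions matter here:

* the threshold is dimensional, so it is applied to **physical-unit,
  pre-min-max-normalization** series;
* it is applied to the **full-rate (50 Hz) filtered window**, not the
  20-sample time-normalized cycle. The 20-sample grid of a 4 s squat has an
  effective rate of ~4.8 Hz and aliases oscillations in the 1–4 Hz band,
  biasing peak velocities down; at 50 Hz the backward difference of a
  sinusoid recovers its true derivative amplitude to about 1%.

The per-squat statistic is the max of $|KS|$ (a mean mode is provided); the
choice of statistic is otherwise unconstrained, and max is the conservative
reading of "instability occurred at some point during the squat".

## Preprocessing choices

**Grid.** The common grid runs at the lower nominal rate (50 Hz) over the
intersection of the two recordings, so no data is invented by upsampling and
no extrapolation occurs. Start-time offsets of a few seconds between the
recorders are absorbed by starting the grid at the later stream.

**Filter.** Zero-phase (forward–backward) filtering is used because
segmentation timing feeds the cycle boundaries; a single-pass filter would
lag the torso trajectory by tens of milliseconds. The default implementation
applies the exact analytic Butterworth magnitude
$|H(f)|^2 = (1+(f/f_c)^{2n})^{-1}$ (two-pass) in the frequency domain after
odd reflective padding. At a 50 Hz sampling rate a classical
bilinear-transform IIR design warps the frequency axis noticeably above
~half the Nyquist rate (at 10 Hz it attenuates ~2.4× more than the analytic
magnitude), so the frequency-domain form keeps the filter's attenuation
exactly on the textbook Butterworth curve; a bilinear `signal::filtfilt`
mode is available via `method = "iir"`. Note the filter is a smoothing step,
not outlier rejection; a spike pre-clean is deliberately out of scope.

**Segmentation.** The standing baseline is estimated iteratively as the
median torso height over non-squat samples (depth below 25% of its 95th
percentile). Candidate squats are maximal runs of depth above
`max(0.05 m, 0.2 × run peak)`, extended outward to `max(1% of peak, 5 mm)`
so boundaries approximate the true movement onset; candidates shallower than
0.15 m or outside 1–10 s are rejected and counted. The hold phase is where
depth is at least 90% of the peak — a kinematic proxy, since no joint angles
exist in the data model. Time normalization resamples each cycle to 20
points (onset to end inclusive) by linear interpolation, rescaling `dt` to
`duration/19` so velocity-type features stay dimensionally correct.

**Amplitude normalization** is min-max per channel, by default within
subject (preserving subject-specific biomechanics; a global scope
reproduces pooled scaling), applied to the feature channels after labeling.
The per-group min/max record is stored and inverts exactly.

## The synthetic cohort generator

No subject recordings are distributed, so the package ships a generator that
emulates the study conditions and carries per-squat ground truth: 28
subjects × 130 squats, camera 60 Hz / plate 50 Hz, start offsets up to 3 s,
raised-cosine descent–hold–ascent torso profiles (depth 0.25–0.45 m, cycles
3–5 s, 30% hold), and 6.5% instability prevalence. Unstable squats add a
zero-mean ML sinusoidal knee oscillation (antiphase by default; in-phase by
flag), partially coupled into the ML CoP channel; CoP is generated in
millimeters (force-plate convention) and converted to meters at ingest.

**Calibration.** The peak shakiness of an antiphase oscillation of amplitude
$a$ and frequency $f$ is $2\,(2\pi f a)$. With $f \sim U(1,4)$ Hz the
defaults are derived analytically from the 0.03 m/s threshold: stable squats
draw $a \le 4\times10^{-4}$ m (peak ≤ 0.020 m/s even at 4 Hz), unstable
squats draw $a \in [2.5\times10^{-3}, 8\times10^{-3}]$ m (peak ≥ 0.031 m/s
even at 1 Hz). Camera noise defaults to 0.2 mm (tracker-grade jitter);
after the 5 Hz low-pass its contribution to peak KS is roughly 0.007 m/s,
which keeps both populations on their own side of the threshold. The 1–4 Hz
band sits below the 5 Hz cutoff by construction — instability that the
pipeline's own filter removed would be undetectable by any downstream
method.

**What the generator does not emulate:** fatigue drift, inter-squat
correlation, non-sinusoidal instability waveforms (the sinusoid is an
assumption; no published characterization of the waveform exists),
skin-marker artifacts, or force-plate drift. Passing tests on this cohort
therefore demonstrate the pipeline's internal consistency — segmentation
recovery, label fidelity, ranking behavior, classifier learnability — not
clinical validity on human data.

## Feature ranking

Spearman's rho is computed between per-squat scalar summaries (KS → peak
$|KS|$, KD → mean, SD → scalar depth, SV → mean, SA → total) and the binary
label; the phi coefficient uses a median-split binarization of each summary
(the binarizer is injectable). Because the label is itself a threshold on
peak KS, KS attains the maximum attainable rank correlation for the class
imbalance — at prevalence $p$ a perfectly separating summary reaches
$\rho = \sqrt{3 p (1-p)}$ (≈ 0.44 at $p = 0.07$), which is worth knowing
when reading absolute rho values on imbalanced labels. No multiple-testing
correction is applied: this is ranking, not inference.

## Classifiers

**LSTM.** A single-cell LSTM over the 20-step sequences: sigmoid input,
forget and output gates in (0,1), tanh input node in (−1,1), cell update
$C_t = F_t \odot C_{t-1} + X_t \odot \tilde{C}_t$, hidden state
$H_t = Y_t \odot \tanh C_t$, final hidden state through a fully connected
layer and softmax over the two classes. Forward pass, backpropagation
through time and Adam are implemented in the package and verified against
numerical gradients (1e-5 relative on a 2-unit cell). Defaults: 32 hidden
units, 100 epochs, batch 32, learning rate 1e-3, stratified 80/20 split —
small-data defaults, all recorded in the training config. The forget-gate
bias is initialized at 1, a standard device so early training retains
memory. Some formulations use distinct symbols for the input gate across
equations; here it is one gate throughout.

**SVM.** Sequences are flattened to `20 × F` vectors; the soft-margin RBF
SVM is solved by libsvm's SMO-type decomposition (e1071). The kernel width
default is `1 / (20 F × mean feature variance)` (the kernel is usually
written without its width; it is restored as a parameter), C defaults to 1.
The model contract is the returned KKT residual: the solver runs at
tolerance 1e-4 and every trained model's maximum KKT violation is checked
against 1e-3. No class reweighting by default (the reference protocol uses
none); a flag is provided.

**Evaluation.** The positive class is KI everywhere. Precision, recall,
binary (per-positive-class) F1 and accuracy come from the confusion counts;
ROC curves sweep all score thresholds with ties grouped, and the
trapezoidal AUC equals the pairwise Mann–Whitney statistic exactly. The
held-out protocol (a stratified split, not resubstitution or
cross-validation) is recorded in every report, since reported headline
accuracies are sensitive to this unstated choice.

## Numerical and degenerate-input policy

* Linear interpolation is exact on affine signals; both synchronization and
  time normalization are tested against that identity.
* Constant channels min-max normalize to 0 with a warning rather than NaN.
* A flat torso trace yields zero detected cycles, not an error; undefined
  precision (no positive predictions) is reported as 0 with a warning.
* Adjacent candidate squats cannot claim the same sample; the earlier run
  keeps the boundary.
* All randomness flows from explicit integer seeds; per-subject generator
  substreams are derived from `(seed, subject_id)` so cohorts are
  reproducible and order-independent, and RNG state is restored after every
  seeded operation.

## Problem sizes used in the test suite

Module tests run on 2–3 subject cohorts of 8–30 squats. The end-to-end
acceptance check runs the full 28 × 130 cohort twice (noise-free for
segmentation-count recovery, default noise for labeling/ranking/
classification) with reduced classifier sizes (16 hidden units, 60 epochs,
batch 64) — at roughly 2,900 training squats the additional gradient steps
compensate for the smaller network, and the whole suite completes in a few
minutes on one CPU.

## Known limitations

* The instability waveform is an assumed sinusoid; real instability is
  likely broadband and asymmetric between knees.
* Labels are a deterministic function of one feature (peak KS), so
  classifier performance on synthetic data is an upper bound; the
  interesting observable is the margin over the majority-class baseline and
  the behavior of feature sets that exclude KS.
* Per-subject min-max normalization discards absolute scale, so a subject
  with no unstable squats has their noisiest stable squat mapped near 1;
  with 130 squats at 6.5% prevalence such subjects are rare, but the global
  scope is available where absolute comparability matters.
* The 20-sample representation aliases oscillations above ~2.4 Hz; the
  labeling path avoids this (full-rate statistics), the classifier tensor
  does not.
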