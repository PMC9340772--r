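---
title: "Noncontact shock prediction from thermal video: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noncontact shock prediction from thermal video: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(thermoshock)
```

## The problem

Hemodynamic shock redistributes blood away from the periphery: in the
"cold shock" phenotype common in infants and young children, systemic
vascular resistance rises, extremities cool, and the temperature gap between
the trunk and the feet widens hours before overt decompensation. A
ceiling-mounted thermal camera sees this gap without touching the patient.
`thermoshock` implements the full decision pipeline from raw 1 Hz thermal
frames to a probability of shock up to six hours ahead:

1. **Frame screening** — classify each frame as blanket-covered or
   uncovered; only uncovered frames expose abdomen and feet.
2. **Person masking** — detect person bounding boxes, keep the largest-area
   box (the patient, who occupies the bed), and fill all other boxes with
   the background intensity so a caregiver's warm silhouette cannot leak
   into the temperature statistics.
3. **Segmentation and CPD** — segment abdomen / feet / background with a
   compact U-shaped encoder–decoder and compute the center-to-peripheral
   difference
   \[
   \mathrm{CPD} = \frac{A - F}{A}\times 100,
   \]
   where \(A\) and \(F\) are the modal intensities of the abdomen and foot
   regions. The ratio form makes CPD invariant to global intensity gain, so
   no absolute temperature calibration is needed; the mode resists outlier
   pixels (diapers, probes, edges).
4. **Labeling** — the shock index \( \mathrm{SI} = \mathrm{median\ HR} /
   \mathrm{median\ SBP} \) over trailing windows of 30 points on the 15-s
   vitals grid, binarized by the age-adjusted pediatric cutoff (SIPA):
   1.22 for 4–7 years, 1.0 for 7–13, 0.9 above 13. A label is *shock* iff
   SI strictly exceeds the cutoff.
5. **Cohort building** — 256-point (256 s) windows of (CPD, heart rate) at
   1 Hz; heart rate forward-filled from the 15-s grid; windows missing
   ≥ 10% of heart-rate points rejected, smaller interior gaps linearly
   interpolated; long uncovered stretches split with 50% overlap; the
   training split SMOTE-balanced.
6. **Sequence classification** — an LSTM encoder over the window, dense
   layers with dropout 0.2, a sigmoid output.
7. **Evaluation** — patient-wise stratified 60:20:20 splits, 10-fold
   cross-validation, AUROC/AUPRC plus confusion metrics at the Youden
   threshold, aggregated as mean ± SE (sd/√k).

## Why a synthetic generator is first-class

The clinical recordings this method targets are bedside ICU data that are
not publicly deposited, so the package ships a synthetic thermal-scene and
vitals generator (`scene_params()`, `render_frame()`, `generate_session()`,
`render_training_set()`) that plants the full causal structure the pipeline
is supposed to recover:

* a patient silhouette (body ellipse + two foot discs) on a background near
  room temperature, with the abdomen warmer than the feet by a controlled
  percent gradient — **the foot intensity is derived**, `F = A(1 −
  CPD/100)`, so applying the CPD formula to ground-truth regions returns the
  planted value exactly on noiseless frames;
* blanket-covered episodes (near-uniform texture over the body, no abdomen
  or foot pixels), caregiver silhouettes with their own bounding boxes,
  additive Gaussian sensor noise with integer quantization;
* a two-state Markov shock process at the 15-s tick scale (mean dwell 2.5 h
  out of shock, 1.5 h in shock — shock evolves on the hour scale), an AR(1)
  CPD path whose mean shifts from 6% to 14% with state, and linked vitals
  whose state-conditional means reproduce the published shock/non-shock
  contrast (heart rate 106.16 vs 143.17 bpm; arterial systolic pressure
  131.94 vs 128.09 mmHg);
* heart-rate dropouts in contiguous runs (5% of ticks by default), the way
  real sensors fail;
* vitals that keep running 0–6 h (drawn per session) after the video ends,
  which is what thins the cohorts at long lead times.

Ages default to the 84–155-month SIPA band. With the published vital-sign
contrasts, the planted shock index moves from ≈ 0.80 (non-shock) to ≈ 1.12
(shock) across that band's cutoff of 1.0; in the younger and older bands the
same contrasts would not cross the cutoffs (1.22 / 0.9), so those bands are
available but not the default. The planted CPD levels are free parameters of
the generator, not estimates of clinical values — no quantitative CPD levels
for shock are published.

**What passing tests do and do not show.** The synthetic scenes are
intensity-separable ellipses with mild geometric jitter; they exercise the
*contracts* of every stage (masks recover planted gradients, screening
separates texture classes, the sequence model recovers a planted
state–physiology association under patient-wise validation) but say nothing
about cluttered real scenes, diapers and tubing, emissivity variation, or
patients whose physiology departs from the planted model. Held-out dice of
≈ 0.97 here is an analogue of — not evidence for — performance on clinical
video.

## The networks

No deep-learning framework is assumed: the convolution, pooling and LSTM
primitives (with full backward passes and Adam) are implemented in the
package, with the convolution inner loops in C++. All three vision models
are deliberately compact — the synthetic scenes are desk-scale, and depth is
configurable where more capacity is wanted.

* **Screening**: 4 conv blocks (3×3, ReLU, 2×2 max-pool; 8–32 filters),
  global average pooling, a sigmoid head; inputs resized to 64×64 and
  normalized by the training pixel mean/sd (stored with the model).
  Augmentation: horizontal flips, ±10° rotations, Gaussian noise. The
  decision threshold is 0.5; screening feeds a robust downstream
  aggregation, so threshold tuning buys little.
* **Person detector**: an anchor-free per-pixel objectness net (two 3×3
  conv layers + 1×1 sigmoid head at half resolution). Connected components
  above a pixel threshold of 0.5 become boxes; confidence is the mean
  component probability; candidates pass a confidence filter (0.4) and
  greedy NMS at IoU 0.5. It is trained on pixel-wise person silhouettes
  rather than filled rectangles: two disjoint people whose *rectangles*
  overlap would otherwise merge into a single component by construction.
  The masking fill value is the scene background intensity — masking to
  zero would cut a cold hole the segmenter has never seen. Pixels inside
  the patient box always survive masking, so overlap with a caregiver box
  never deletes patient signal.
* **Segmenter**: a 4-level U-shaped encoder–decoder with residual
  double-conv blocks (8–64 filters), skip connections, softmax over
  {abdomen, feet, background}, trained on an equally weighted sum of soft
  dice loss and cross-entropy (the published work reports both losses but
  no weights). Frames are scaled uniformly to 40% and padded bottom-right
  to a multiple of 16, so the aspect ratio is untouched. At inference the
  class probabilities are resized back, a foreground pixel keeps its argmax
  class only if that probability reaches the cutoff (default 0.5, never
  stated in the source work), and weakly predicted pixels fall back to
  background — raising the cutoff can only shrink foreground regions.
* **Sequence model**: 1 LSTM layer (64 hidden units by default; layer count
  and sizes configurable), dense stack [32] with dropout 0.2, sigmoid
  output. The padding mask gates the recurrence: hidden state carries
  through padded steps unchanged, so the zero-fill under the padding can
  never influence the probability (a tested invariant). Early stopping
  selects the checkpoint with the best validation AUPRC (patience 10);
  the stopping rule is unreported in the source work and AUPRC is the
  metric of record for this imbalanced problem.

## Ambiguities resolved (and why)

* *"Mode of the detected probabilities"* for temperature extraction is read
  as the **mode of pixel intensities within the predicted region** — the
  only reading that yields a temperature, and robust to outliers, which is
  the stated motive for a mode. Intensities are binned (default: native
  integer sensor levels); ties take the lower bin; the representative value
  is the mean of raw values in the winning bin, which for integer data is
  exactly the modal value.
* **Trailing, not centered, shock-index windows**: prediction must not peek
  forward. At a series start, windows shorter than 30 points use all
  available points down to a minimum of 5 — discarding the first 7.5
  minutes of every session costs more than a slightly noisier early median.
* **Strict inequality at the SIPA cutoff** (boundary → non-shock): an
  arbitrary but fixed and recorded rule; every output row carries
  `cutoff_used`.
* **Lead labels** take the label at the vitals grid point nearest
  `t0 + lead`, missing if nothing lies within ±7.5 min — whether the
  published outcome is instantaneous or aggregated over the lead hour is
  unstated; nearest-grid-point is the simplest causal choice.
* **Window emission**: stride 128 (50% overlap — the smallest overlap that
  never discards trailing data) plus a right-anchored final window;
  padding at the window start so the most recent physiology abuts the
  prediction point; the 10% missingness rule is applied per window (the
  unit fed to the classifier), not per session.
* **SMOTE inside each fold's training set only**, with a provenance flag on
  every window; tests assert that no synthetic window ever reaches a
  validation or test set. The Youden threshold, and the confusion metrics
  at it, are computed on each fold's test scores.
* **AUPRC** is the step-wise average-precision integral, not a trapezoid —
  trapezoidal PR interpolation is optimistic.
* **Stratification tolerance**: each of train/validation/test must sit
  within ±10 percentage points of the global shock prevalence, re-drawn up
  to 100 times, then error. Folds whose test set collapses to one class
  are skipped and excluded from mean and SE.

## Numerical and scale choices

Training sizes are chosen for a single CPU: the segmenter trains on 200
frames of 156×206 (the native sensor grid of the emulated camera) in a few
minutes; the screening and detection nets in under a minute each; the
cross-validated sequence experiment uses 20 patients × 2 h sessions
(≈ 650 windows at lead 0) with a reduced (32-unit) LSTM. At that cohort
scale the planted effect is recovered with mean test AUROC ≳ 0.99 and the
label-shuffled control sits at chance — the *contrast*, not the absolute
number, is the meaningful result. The cohort-scale experiments read the
generator's planted CPD path directly (the idealized output of a perfect
vision stack) because rendering and segmenting 20 × 7200 frames is not a
sensible desk-scale computation; the vision stages are validated separately
on rendered frames, including exact CPD recovery through ground-truth masks
and ≤ 2-point recovery through the trained segmenter.

Determinism: every stochastic step (rendering noise, vitals, SMOTE,
batching, dropout, splits) draws from R's RNG under an explicit seed;
identical seeds give bit-identical results throughout, which the test suite
asserts.

## Known limitations

* The generator's scenes are geometric and intensity-separable; there is no
  photorealistic thermal rendering, device drift, or ambient fluctuation
  (explicit non-goals).
* Absolute temperature is never computed; everything downstream of the
  frames operates on relative intensities.
* The detector handles one caregiver well and degrades gracefully beyond
  two people (largest-area selection still holds, but component merging
  becomes more likely in crowded frames).
* SIPA cutoff values ship as an editable table; the defaults follow the
  standard age bands but any deployment should confirm them against local
  practice.
* 16-bit frames are written as TIFF; 8-bit PNG is used for masks.
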