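# thermoshock

Noncontact prediction of hemodynamic shock in pediatric intensive care from
single-channel thermal video.

Shock redistributes blood away from the periphery: in the cold-shock
phenotype typical of infants and young children, vasoconstriction cools the
extremities while the trunk stays warm. A ceiling-mounted thermal camera
sees that gap continuously and without contact. `thermoshock` implements the
full pipeline from raw 1 Hz thermal frames to a probability of shock up to
six hours ahead:

* **screen** frames as blanket-covered vs uncovered (small CNN);
* **mask** non-patient persons: detect boxes, keep the largest-area box as
  the patient, fill the rest with background;
* **segment** abdomen / feet / background (compact residual U-Net) and
  extract the center-to-peripheral difference, `CPD = (A − F)/A × 100`, from
  the modal region intensities — a relative gradient, so no absolute
  temperature calibration is needed;
* **label** each 15-s tick with the shock index, `SI = median(HR) /
  median(SBP)` over trailing 30-point windows, binarized by the pediatric
  age-adjusted cutoff (SIPA: 1.22 / 1.0 / 0.9 by age band, shock iff
  SI > cutoff);
* **build windows**: 256-s (CPD, heart-rate) sequences at 1 Hz, with linear
  interpolation of small heart-rate gaps (<10% missing, else rejected),
  start-padding with a mask, 50%-overlap splitting, SMOTE balancing of the
  training split only;
* **classify** windows with an LSTM + dense + dropout + sigmoid sequence
  model, one model per lead time (0–6 h);
* **evaluate** with patient-wise stratified 60:20:20 splits, 10-fold CV,
  AUROC/AUPRC and confusion metrics at the Youden threshold, mean ± SE.

Because the clinical recordings such a system targets are not publicly
deposited, the package ships a first-class synthetic generator
(`render_frame()`, `generate_session()`) that plants the entire causal
chain — scene geometry, blanket cover, caregivers, sensor noise, a Markov
shock process, CPD and vitals that shift with it — so every stage is
trainable and testable offline. The neural primitives (convolution,
pooling, LSTM, Adam, with full backward passes) are implemented in the
package with the convolution inner loops in C++; no external deep-learning
framework is required.

## A worked example

Train the segmenter on synthetic scenes, check it on held-out frames, and
recover the planted temperature gradient end to end:

```r
library(thermoshock)

tr <- render_training_set(200, covered_frac = 0, caregiver_frac = 0.3, seed = 31)
te <- render_training_set(50,  covered_frac = 0, caregiver_frac = 0.3, seed = 32)
seg <- train_segmenter(tr$frames, tr$masks, seed = 1)

dice <- sapply(seq_along(te$frames), function(i)
  dice_coefficient(segment_frame(seg, te$frames[[i]]), te$masks[[i]]))
mean(dice)
#> [1] 0.9739672

nl  <- render_training_set(50, covered_frac = 0, caregiver_frac = 0,
                           noise_sd = 0, seed = 33)
cpd <- extract_cpd_series(nl$frames, model = seg)
median(abs(cpd$cpd - nl$planted_cpd[cpd$valid]))
#> [1] 3.552714e-15
```

A mean dice of about 0.97 on held-out frames and a median CPD error at
floating-point precision mean the segmenter finds the regions and the modal
intensities reproduce the planted gradient essentially exactly (with
ground-truth masks the recovery is exact by construction).

The sequence experiment at cohort scale — 20 synthetic patients, 2-h
sessions, lead 0, 10-fold patient-wise CV with a compact LSTM:

```r
sessions <- lapply(1:20, function(i)
  generate_session(session_config(duration_s = 7200), seed = 100 + i,
                   patient_id = sprintf("P%02d", i)))
ws  <- cohort_from_sessions(sessions, leads = 0:6)
co  <- cohort_at_lead(ws, 0)
cfg <- seq_model_config(lstm_hidden = 32, dense_sizes = 16,
                        epochs = 15, patience = 5, batch_size = 64)
rep0 <- cross_validate(co, cfg, k = 10, seed = 7)
subset(rep0$aggregate, metric %in% c("auroc", "auprc"))
#>   metric      mean          se
#>    auprc 0.9906583 0.005968040
#>    auroc 0.9961787 0.002138871
```

The planted shock effect is recovered almost perfectly; shuffling the
labels collapses the same experiment to chance (AUROC ≈ 0.53). The
contrast between the two — not the absolute number on these separable
synthetic scenes — is the meaningful result. Per-lead window counts shrink
with the horizon (674 at 0 h down to 15 at 6 h in this draw) because each
session's vitals coverage ends at a different time after the video.

A command-line dispatcher over the same functions is installed at
`inst/cli/thermoshock.R` (subcommands `synth`, `screen`, `mask`, `cpd`,
`label`, `cohort`, `train`, `predict`, `evaluate`).

## Documentation

The methods vignette (`vignettes/thermoshock-methods.Rmd`) describes the
models, every ambiguity the implementation had to resolve (mode semantics,
window boundary rules, stratification tolerances), what the synthetic
generator does and does not emulate, and known limitations.
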