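# squatstab

Classification of dynamic knee instability during repeated squats, from
multimodal sensor recordings: a depth camera tracking the mediolateral (ML)
position of both knees and the vertical torso position (~60 Hz), and a force
plate sampling the center of pressure (CoP) at 50 Hz.

Repeated squatting with improper technique provokes involuntary oscillatory
ML movement around the knee joint — *knee instability* (KI) — a clinically
visible indicator of compromised joint control and injury risk. squatstab
implements the complete analysis chain that turns the two raw streams into a
per-squat binary KI/NKI decision, for researchers in biomechanics and
exercise-based rehabilitation who want a tested, reproducible reference
implementation, together with a calibrated synthetic cohort generator with
per-squat ground truth for validating every stage.

## The method

1. **Synchronize** the dual-rate streams by linear interpolation onto a
   common 50 Hz grid over the overlap of the two recordings (start offsets
   of a few seconds are absorbed).
2. **Filter** all channels with a zero-phase 4th-order Butterworth low-pass
   at 5 Hz.
3. **Segment** squat cycles from the torso trajectory (raised-cosine
   descent–hold–ascent morphology), rejecting spurious detections
   (depth < 0.15 m, duration outside 1–10 s), and time-normalize each cycle
   to 20 samples.
4. **Featurize** each squat with five series (channel order is a format
   contract):

   | id | feature | definition |
   |----|---------------|------------------------------------------------|
   | 1 | knee shakiness KS (m/s) | `|Vl| + |Vr|`, backward-difference ML knee velocities |
   | 2 | knee distance KD (m) | `|x_lk − x_rk|` |
   | 3 | squat depth SD (m) | `y_t1 − y_torso(t)`, scalar `y_t1 − min(y_torso)` |
   | 4 | sway velocity SV (m/s) | `√(ΔCoPx² + ΔCoPy²) / Δt` |
   | 5 | sway area SA (m²) | origin-anchored shoelace increments `|CoPx(t+1)CoPy(t) − CoPx(t)CoPy(t+1)|/2` |

5. **Label** each squat KI (1) when its full-rate peak `|KS| ≥ 0.03 m/s`
   (boundary inclusive), on physical units before min-max normalization.
6. **Rank** features by Spearman ρ and the φ coefficient against the labels.
7. **Classify** with two models on min-max-normalized tensors
   (squats × 20 × features): an LSTM sequence network (hand-implemented
   forward/BPTT/Adam, gradient-checked) and an RBF-kernel soft-margin SVM
   (libsvm SMO backend, KKT-residual contract ≤ 1e-3).
8. **Evaluate** with precision, recall, binary F1, accuracy and
   threshold-sweep ROC/AUC (equal to the pairwise Mann–Whitney statistic),
   across the benchmark feature sets `{1,2,3,4,5}`, `{1,2,3}`, `{1,3,5}`,
   `{4,5}`, `{2,4}`.

The methods vignette (`vignettes/knee-instability-pipeline.Rmd`) documents
every design decision: filter implementation, segmentation thresholds,
labeling order, generator calibration against the 0.03 m/s threshold, and
what synthetic-data results do and do not show.

## Worked example

```r
library(squatstab)

cfg <- synth_config(n_subjects = 4, squats_per_subject = 40, seed = 42)
cohort <- generate_cohort(cfg)

feats <- list()
for (s in seq_along(cohort$sessions)) {
  sess <- cohort$sessions[[s]]
  session <- lowpass(synchronize(sess$camera, sess$plate, subject = s))
  bounds <- detect_squats(session)
  for (i in seq_len(nrow(bounds))) {
    cyc <- extract_window(session, bounds[i, ],
                          y_t1 = attr(bounds, "y_t1"), squat = i)
    feats[[length(feats) + 1]] <- squat_features(cyc)
  }
}
dataset <- build_dataset(feats, ground_truth = cohort$ground_truth)
dataset
#> <labeled_dataset> 160 squats x 20 steps x 5 channels (1,2,3,4,5); 12 KI / 148 NKI

rank_features(dataset)[, c("name", "rho", "phi", "rho_rank")]
#>   name    rho    phi rho_rank
#> 1   ks 0.4562 0.2847        1
#> 2   kd 0.0128 0.0000        5
#> 3   sd 0.0930 0.0949        4
#> 4   sv 0.4012 0.2847        3
#> 5   sa 0.4562 0.2847        2
```

All 160 generated squats are recovered by segmentation and every label
matches the generator's ground truth. KS tops the ρ ranking — and its
ρ = 0.456 is in fact the *maximum attainable* rank correlation for a
perfectly separating summary at this class imbalance (√(3·p·(1−p)) ≈ 0.456
at p = 0.075), a useful caution when reading correlation magnitudes on
imbalanced labels. The sway features rank next because unstable knee
oscillation is mechanically coupled into the CoP; knee distance and depth
carry no label information by construction.

```r
tc <- train_config(hidden = 16, epochs = 60, batch = 32, lr = 3e-3, seed = 1)
report <- compare_feature_sets(dataset, sets = default_feature_sets()[c(1, 2, 4)],
                               cfg = tc)
format_report(report)
#>  model feature_sets  auc recall   f1 precision accuracy_pct
#>   lstm    1,2,3,4,5 1.00   1.00 1.00      1.00       100.00
#>   lstm        1,2,3 1.00   1.00 1.00      1.00       100.00
#>   lstm          4,5 1.00   1.00 1.00      1.00       100.00
#>    svm    1,2,3,4,5 1.00   1.00 1.00      1.00       100.00
#>    svm        1,2,3 1.00   1.00 1.00      1.00       100.00
#>    svm          4,5 1.00   1.00 1.00      1.00       100.00
majority_baseline(dataset$labels)
#> [1] 92.5
```

Perfect held-out scores are expected here, not impressive: synthetic labels
are a deterministic function of peak KS and the generator's amplitudes are
calibrated to straddle the threshold cleanly. The meaningful reading is the
margin over the 92.5% majority baseline and the pipeline's internal
consistency, not clinical performance.

Or run everything (including model serialization and a manifest) from one
config:

```r
run_pipeline(pipeline_config(seed = 1), "out/")
```

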