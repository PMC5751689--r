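# fnirsnet

Classify subjects from the topology of their functional brain networks.

`fnirsnet` implements a complete analysis chain for multichannel functional
near-infrared spectroscopy (fNIRS) case-control studies, of the kind used to
discriminate schizophrenia patients from healthy controls with a 52-channel
prefrontal probe set during a working-memory task:

1. **Preprocessing** — per-channel FFT spectrum inspection and a zero-phase
   order-4 Butterworth low-pass at 0.5 Hz (fNIRS hemodynamics live in
   0–0.5 Hz; cardiac and instrument noise above), plus optional extraction
   of the task block from a 5/25/70/50 s block design.
2. **Network construction** — the Pearson correlation matrix
   *r<sub>ij</sub>* = cov(*X<sub>i</sub>*, *X<sub>j</sub>*) /
   (σ<sub>i</sub> σ<sub>j</sub>) over all channel pairs, binarized by
   *e<sub>ij</sub>* = 1 iff |*r<sub>ij</sub>*| ≥ *T*, with *T* controlled by
   network **sparsity** (realized edges over *M* = *C*(*C*−1)/2 possible;
   default grid 1%–50% in 1% steps, i.e. 50 networks per subject).
3. **Nodal graph metrics** — degree *k<sub>i</sub>*, Watts–Strogatz
   clustering coefficient 2*t<sub>i</sub>* / (*k<sub>i</sub>*(*k<sub>i</sub>*−1)),
   and Latora–Marchiori nodal global and local efficiency (mean inverse
   shortest-path length; efficiency of the neighbour-induced subgraph).
4. **Feature selection** — a per-channel Welch two-sample *t*-test at every
   (metric, sparsity) combination; the combination with the most significant
   channels becomes the per-subject feature vector (one value per channel).
5. **Classification** — a radial-basis-function SVM (libsvm via `e1071`,
   default cost *C* = 1, γ = 1/features) evaluated by leave-one-out
   cross-validation: with *n* subjects, *n* rounds each holding out one
   subject. Reported as ACC = (TP+TN)/(TP+FP+TN+FN),
   sensitivity SS = TP/(TP+FN) and specificity TNR = TN/(TN+FP), with
   patients coded +1 and controls −1.

Because clinical fNIRS recordings are rarely shareable, the package also
ships a **synthetic cohort generator** with known ground truth:
block-structured inter-channel correlations that are attenuated in the
patient group, a task-locked double-gamma hemodynamic response with reduced
patient amplitude, slow physiological drift, and broadband measurement
noise. Every downstream stage is validated against it.

## Worked example

```r
library(fnirsnet)

# arithmetic on a published-style confusion table
performance_metrics(c(TP = 39, FN = 3, FP = 8, TN = 26))
#> <fnirs_performance> ACC 85.5% | sensitivity 92.9% | specificity 76.5% (TP 39, FN 3, FP 8, TN 26)

# a small synthetic cohort with a strong planted group difference
spec <- cohort_spec(n_patients = 12, n_controls = 10,
                    connectivity_attenuation = 0.3,
                    hrf_amplitude_patient = 0.5, seed = 42)
cohort <- simulate_cohort(spec)
cohort
#> <fnirs_cohort> 12 patients + 10 controls | 52 channels x 1500 samples @ 10 Hz (seed 42)

result <- suppressWarnings(run_pipeline(cohort = cohort, selection = "fold"))
result
#> <fnirs_pipeline> selection = fold, 50 sparsity levels
#> <fnirs_loocv> 22 folds | ACC 100.0% | sensitivity 100.0% | specificity 100.0%
#>   confusion: TP 12, FN 0, FP 0, TN 10

glance(result$scan)
#> # A tibble: 1 × 4
#>   chosen_metric     chosen_sparsity n_significant alpha
#>   <chr>                       <dbl>         <int> <dbl>
#> 1 global_efficiency             0.5            34  0.05

head(tidy(result), 4)
#> # A tibble: 4 × 6
#>   subject_id truth predicted decision_value chosen_metric     chosen_sparsity
#>   <chr>      <int>     <int>          <dbl> <chr>                       <dbl>
#> 1 S001           1         1          0.338 global_efficiency            0.49
#> 2 S002           1         1          0.264 degree                       0.45
#> 3 S003           1         1          0.422 global_efficiency            0.49
#> 4 S004           1         1          0.264 global_efficiency            0.49
```

The pipeline report says: all 22 leave-one-out folds classified their
held-out subject correctly; the whole-sample scan would have picked nodal
global efficiency at sparsity 0.50, where 34 of 52 channels differ
significantly between groups; and per-fold records show which (metric,
sparsity) each training fold selected on its own — the leakage-free
`selection = "fold"` default.

Every stage is also callable on its own (`lowpass_filter()`,
`correlation_matrix()`, `threshold_sweep()`, `metric_profile()`,
`group_difference_scan()`, `loocv_svm()`), takes and returns tibbles or
small S3 objects with `tidy()` / `glance()` / `autoplot()` methods, and can
be driven from files on disk via `read_manifest()` / `read_recording()`.

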