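---
title: "Functional brain network classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional brain network classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsnet)
```

## The analysis model

`fnirsnet` treats a multichannel fNIRS acquisition as a sample of a
functional brain network and asks whether network topology separates two
clinical groups. The chain is:

oxy-Hb time series → low-pass filter → Pearson correlation matrix →
sparsity-thresholded binary network → nodal graph metrics → channel-wise
group-difference scan → RBF-SVM with leave-one-out cross-validation.

The underlying assumptions are worth stating explicitly:

* **Stationarity within the analysis window.** Pearson correlation over the
  whole recording (or the task block) summarises coupling by a single
  number per channel pair; transient connectivity is averaged out.
* **Binary, unweighted topology.** After thresholding, edge strength is
  discarded; all graph metrics are computed on hop counts. Strong
  *negative* correlations also form edges, because the edge rule is
  |r| ≥ T.
* **Node identity is channel identity.** Channels are assumed comparable
  across subjects (same probe layout), which is what makes per-channel
  feature vectors and per-channel tests meaningful.
* **Independence across subjects**, required by both the Welch tests and
  the cross-validation.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `cutoff_hz` | 0.5 | Hz | hemodynamic fNIRS signal is concentrated in 0–0.5 Hz; cardiac (~1 Hz) and instrument noise above |
| `order` | 4 | — | standard compromise between rolloff (−48 dB at 2 Hz after two passes) and transient length |
| window | full recording | — | whether correlation uses the whole 150 s or the 70 s task block is a genuinely open choice; both are provided (`window_mode`) and the full recording is the default because it uses all data |
| sparsity grid | 0.01–0.50 step 0.01 | fraction of M = C(C−1)/2 | 50 levels spanning the sparse regime in which brain networks are usually analysed; above 50% the network saturates, below 1% it fragments |
| `alpha` | 0.05 | — | per-channel Welch test level; the selection score is the count of channels with p < α |
| `cost`, `gamma` | 1, 1/features | — | canonical libsvm defaults; no tuning, so reported accuracies are not optimised post hoc |
| `standardize` | TRUE | — | nodal degree ranges 0…C−1 while efficiencies live in [0, 1]; the RBF kernel is scale-sensitive, so features are z-scored with training-fold statistics only |

## Numerical and procedural choices

* **Sparsity, not raw threshold.** The thresholds are interpreted as
  sparsity levels: T is the k-th largest |r| with k = round(S·M), so every
  subject's network has (up to ties) the same edge count and nodal degree
  differences reflect *redistribution* of edges, not global correlation
  strength. A `mode = "raw"` escape hatch applies the grid directly to |r|.
  Rounding of k is `round()` by default and `floor` by option.
* **Ties at the threshold are all included.** This keeps binarization
  deterministic and order-independent; the achieved sparsity (recorded on
  every network) can exceed the requested level by the tie-group size / M.
* **Zero-phase filtering.** The Butterworth filter runs forward and
  backward, squaring the magnitude response and cancelling phase, so
  hemodynamic timing is not shifted. Each pass filters the deviation from
  the segment's boundary value after odd-reflection padding of one warm-up
  length (max of 3 cutoff periods and 6 filter orders), which suppresses
  start-up transients; recordings must be longer than the padding and an
  error states the minimum length otherwise.
* **Efficiencies are nodal.** "Global efficiency" is computed per node
  (mean inverse distance to all others) so each of the four attributes
  yields one value per channel and hence a C-dimensional per-subject
  feature vector; the scalar network mean is available separately
  (`global_efficiency()`). Disconnected pairs contribute 1/∞ = 0 — no
  largest-component restriction, so vectors stay defined at sparse levels.
  Distances are computed by breadth-first level expansion with matrix
  products, validated against Floyd–Warshall and igraph in the tests.
* **Welch's t-test per channel.** Group variances and sizes differ (42 vs
  34), so the unequal-variance test is the safest simple choice. No
  multiple-testing correction is applied by default — the score is a
  selection heuristic, not an inference — but Bonferroni is available.
  Features that are constant across all subjects (common at 1–2% sparsity,
  where most nodes are isolated) get p = 1 with a warning.
* **Selection tie-breaks** are deterministic: lower sparsity first, then
  degree < clustering < local efficiency < global efficiency.
* **Selection inside the folds by default.** Scanning the whole sample
  before cross-validation leaks test labels into the feature choice and
  inflates accuracy. `selection = "fold"` reruns the scan on each
  training set of 75; `selection = "scan"`/`"forced"` perform the
  optimistic single-scan variant (or a fixed choice such as degree at
  sparsity 0.21) for comparison.
* **Prediction tie-break:** an SVM decision value of exactly 0 predicts the
  patient class (+1), documented and deterministic.
* **Metric percentages** are proportions internally; print methods show one
  decimal.

## The synthetic cohort generator

Real recordings of the target population are not redistributable, so the
generator emulates the study geometry with known ground truth: 42 patients
and 34 controls, 52 channels at 10 Hz, one 5 s pre-scan + 25 s wait + 70 s
task + 50 s post-task block (1500 samples). Each recording is

baseline + activation + drift + noise,

where the baseline is correlated Gaussian noise with a block-structured
target correlation (four blocks of 13 channels; within-block r = 0.6,
between-block r = 0.1) imposed via its Cholesky factor; activation is a
task boxcar convolved with the canonical double-gamma HRF (peak ≈ 6 s,
undershoot ≈ 16 s), applied at gain 1 to the two "anterior" blocks and 0.3
elsewhere; drift is a 0.02 Hz sinusoid with random phase; and the noise is
white with SD `hf_noise_sd`, which places measurable power above 0.5 Hz
for the filter contract to remove.

The group difference has two planted components: patients' within-block
correlation is attenuated by a factor `connectivity_attenuation`, and their
HRF amplitude is lower. Defaults (attenuation 0.12, patient amplitude 0.8
vs 1.0, `hf_noise_sd` 1.2) were calibrated once so that the full pipeline
classifies the default cohort in the **80–95%** leave-one-out accuracy
range across seeds — a regime where the signal is clearly detectable but
the problem is not trivially saturated; measured accuracies over seeds
42/1/7/99 were 0.82–0.96.

What the generator does **not** emulate: optical physics (no Beer–Lambert
forward model), motion artifacts, the oxy/deoxy anticorrelation (deoxy
channels would be simulated by the same mechanism with their own
amplitudes), spatial probe geometry, or inter-subject variability in HRF
shape. Passing the end-to-end tests therefore demonstrates that the
pipeline recovers *correlation-structure and activation-amplitude*
differences of realistic magnitude under realistic noise — not that it
would achieve any particular accuracy on clinical data.

## Statistical validation in the test suite

The suite checks calibration rather than just plumbing, at these problem
sizes (chosen to keep a full run around three minutes):

* the Welch scan's null rejection rate over 500 label permutations of a
  76 × 520 null feature matrix must lie in [0.03, 0.07] at α = 0.05;
* a planted degree-at-0.21 shift of 1.5 pooled SD on 10 of 52 channels
  (n = 20 + 20) must be recovered by the scan in ≥ 90% of 50 replicates;
* null feature matrices at the study composition (42:34) must classify at
  class-prior chance (mean over 20 seeds inside the 95% binomial band
  around 42/76);
* the default synthetic cohort (seed 42) must exceed 75% end-to-end LOOCV
  accuracy, and its zero-effect configuration must fall inside the chance
  band;
* filter probes at 2 Hz and 0.1 Hz must match the closed-form Butterworth
  magnitude bounds (≤ 1e-4 and ≥ 0.99);
* all four nodal metrics must equal brute-force oracles (Floyd–Warshall,
  exhaustive triangle counts, induced-subgraph enumeration) on 200 random
  graphs of up to 12 nodes, plus hand-derived closed forms.

## Known limitations

* **Leave-one-out on balanced cohorts is majority-biased.** Removing the
  held-out subject makes its class the training minority; on null data the
  SVM then leans toward the opposite class, so a perfectly balanced null
  cohort scores *below* chance (we measured mean ≈ 0.34 at 20 + 20). Null
  calibration checks therefore use the study's own 42:34 composition,
  where the artifact is negligible (measured mean ≈ 0.52, inside the
  chance band). This is a property of the cross-validation design, not of
  the implementation.
* The selection score (count of significant channels) ignores effect
  direction and correlation between channels.
* Achieved sparsity can exceed the requested level under ties; the sweep
  records both, and logs/artifacts report the achieved value.
* Whether correlation should use the whole recording or only the task
  block is left to the user (`window_mode`); the two can select different
  features.
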