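---
title: "Movement-data representations for accelerometer-based dyskinesia detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-data representations for accelerometer-based dyskinesia detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyskrep)
```

## The problem

Levodopa-induced dyskinesia (LID) — involuntary, irregular choreiform
movement — is a common side effect of dopaminergic overdosing in Parkinson's
disease, and its in-hospital detection guides dose titration. A wrist-worn
accelerometer recorded while the patient performs the UPDRS 3.6 item (rapid
alternating pronation/supination of the most affected hand) captures both the
near-periodic task motion and, when present, the superimposed dyskinetic
irregularity. `dyskrep` compares three ways of turning such recordings into
classifier-ready features and asks which of them generalizes across cohorts
collected at different sites with different devices:

* **SEMANTIC** — a task-informed representation: per-session PCA projection of
  the tri-axial signal onto its first principal component, segmentation of the
  trace at zero crossings, and 25 biomechanical summary features;
* **PCA_AUTO** — a generic time-series feature catalogue computed on the PC1
  trace;
* **AUTO3D** — the same catalogue computed per raw axis.

Sessions are *variable length* by design: each recording covers the full task
window as observed in clinic, and every operator in the package accepts
arbitrary durations. No resampling, truncation or padding occurs anywhere.

## Preprocessing

Different wearables use different device coordinate frames, so each session is
harmonised by a single global rotation: the session-mean acceleration vector —
the gravity estimate for this quasi-stationary task — is mapped onto +z by the
minimal (geodesic) rotation in the plane it spans with +z. The gravity
estimate is the plain session mean (no low-pass filter, which would add a
cutoff parameter with no observable benefit for a seated task). The yaw angle
about gravity remains undetermined; the per-session PCA downstream is
invariant to it, which is why the minimal rotation suffices. Sessions whose
mean acceleration is below 0.1 g carry no stable gravity estimate and are
rejected, as are sessions shorter than 5 s (configurable). Units are g
throughout; timestamps may be mildly irregular and the sample rate is the
average rate `(n − 1) / (t_last − t_first)` — only the spectral features use
it, everything else works on the irregular grid directly.

## The semantic representation

`project_pc1()` centres the tri-axial data and projects it on the top
eigenvector of its own 3×3 covariance. Fitting PCA *per session* (rather than
per cohort) makes the representation invariant to how the device was worn and
avoids any train/test information flow through a shared rotation. The loading
sign is fixed by flipping the eigenvector so its largest-magnitude entry is
positive; for the oscillatory, nearly sign-symmetric traces this task
produces, the features below are stable under the residual sign ambiguity.

The trace is split into beginning/middle/end parts (`split_parts()`; the
middle and end get `floor(n/3)` samples, any remainder goes to the beginning)
and each part is segmented at zero crossings (`segment_by_extrema()`): a
crossing sits between consecutive samples of strictly opposite sign, each
maximal constant-sign run of ≥ 2 samples becomes a segment characterised by
its largest-magnitude sample (its *extremum*), runs shorter than 2 samples are
merged into the preceding segment, and adjacent same-sign spans are then
coalesced so consecutive segments always alternate sign. A healthy
pronation/supination cycle contributes one positive and one negative segment;
dyskinetic irregularity perturbs segment counts, durations and extrema.

Nine feature kinds summarise the segmentation — one for the whole measurement
(mean absolute segment extremum) and eight per part (segment count,
positive-to-negative total-duration ratio, mean and IQR of segment durations,
mean and IQR of the positive-segment extrema, mean and IQR of the
negative-segment extrema) — 1 + 8 × 3 = 25 named features in a fixed order
(`semantic_feature_names()`).

Choices worth stating because they were genuinely open:

* The duration ratio is positive-to-negative within each part
  (pronation/supination asymmetry); a part-versus-whole ratio would be a
  constant 1/3 under equal thirds and carry no information.
* The whole-measurement feature is the mean of |extremum| (not |mean of
  extrema|), so symmetric oscillation does not cancel to zero.
* Segmentation is extremum-signed rather than fixed-length: fixed,
  "equally enduring" windows would make segment counts and mean durations
  functions of the window size alone, i.e. uninformative; for a near-periodic
  task the two readings coincide anyway.
* All IQRs use the linear-interpolation quantile definition (R type 7).
* Degenerate statistics take sentinels — 1 for an undefined duration ratio, 0
  for undefined IQRs and means of empty extremum sets — so feature matrices
  stay finite for classifiers that reject missing values; affected entries are
  reported via the `degenerate` attribute.

## The automatic representation

`ts_feature_catalogue()` computes a fixed catalogue of 62 named descriptors
per series: distributional moments and quantiles, change and energy
statistics, run and peak counts, autocorrelation at lags 1–10, linear trend,
relative band powers over 0.5–3, 3–7 and 7–12 Hz, spectral entropy/centroid,
dominant frequency, a sample-entropy estimate (m = 2, r = 0.2 sd, computed on
at most the first 512 samples to keep the quadratic pair comparison
tractable), binned entropy, and third-order statistics. Series are linearly
detrended before the FFT; features undefined on a degenerate series take the
documented floor 0. The catalogue is deliberately compact and fully specified
here rather than delegated to an external extraction tool, so its behaviour is
reproducible from this package alone; it covers the families that matter for
an oscillatory motor task.

`fresh_relevance_filter()` prunes a feature matrix by per-feature two-sample
association tests against the label (Mann–Whitney U for real features,
Fisher's exact test for binary ones) with Benjamini–Hochberg FDR control
(default 0.05). The harness applies it *inside each training fold only*: a
filter fit on pooled data would leak test-fold labels into feature selection.
If the filter rejects everything (as it should on permuted labels), the fold
falls back to the unfiltered columns rather than failing.

## Model selection

`run_grid()` evaluates classifier × selector × sampler configurations with
stratified 10-fold cross-validation, ranked by unweighted macro F1 (the
arithmetic mean of the per-class F1 scores — the natural summary under class
imbalance, where accuracy is dominated by the majority "no dyskinesia" class).
Ranking uses the *mean over folds*; pooled confusion matrices are also kept
for inspection. Ties break by mean accuracy, then config id.

The default grid crosses logistic regression (ridge, C ∈ {0.1, 1, 10}), kNN
(nn ∈ {5, 11}), random forest (100 trees, depth ∈ {5, unlimited}), RBF SVM
(C ∈ {0.1, 1, 10}) and gradient-boosted trees (100 depth-3 trees, learning
rate ∈ {0.1, 1.0}) with selector k ∈ {none, 5, 10} and sampler ∈ {none,
SMOTE} — 72 configurations. `base_grid()` keeps one base hyperparameter per
kind (30 configurations) for simulation studies. The sklearn-style
inverse-regularisation C of the logistic model maps to a glmnet ridge penalty
λ = 1/(C·n).

Within every fold the pipeline order is: median imputation → optional
relevance filter → optional SMOTE → ANOVA-F top-k selection → z-scoring (for
the scale-sensitive kinds only; tree ensembles see raw features) → classifier
fit — each stage fit on the training fold alone. SMOTE synthesises minority
rows as convex combinations `m + u(nb − m)` of a minority row and one of its
5 nearest minority neighbours, balancing classes exactly while preserving the
originals. A master seed fans out deterministically to fold assignment, SMOTE
draws and stochastic learners, so leaderboards reproduce bit-for-bit.

## Generalization evaluation

`transfer_evaluate()` refits each of the top-10 source configurations on the
*full* source cohort (refitting, rather than reusing fold estimators, is the
standard choice and is stated here because either reading of "apply the top
models" is defensible) and scores each once on the target cohort; target
labels enter only the metrics. `compare_representations()` then compares the
per-representation transfer score sets pairwise with Welch's t-test,
flagging significance at p < 0.001.

## The synthetic cohort generator

No public recording of this exact task ships with the package, so
`generate_cohort()` simulates it — a first-class, tested module, not a test
fixture. The signal model: the wrist angle follows
θ(t) = θ_A·sin(2π f t + φ) about the forearm axis; the sensor sees the
gravity vector rotated by θ about that axis, plus a tangential term
proportional to θ″(t) (peak `task_amplitude`, in g; the sign of the
proportionality — the mounting side of the sensor relative to the rotation
axis — is chosen so the two oscillations add on the tangent axis), plus white
sensor noise. Pronation/supination primarily re-orients gravity in the wrist
frame, which is the dominant effect a wrist accelerometer records; that is
the entire justification, and no claim of biomechanical fidelity is made.

Dyskinesia-positive sessions additionally receive band-limited (1–4 Hz)
Gaussian oscillation with slow amplitude modulation, scaled by
`dysk_severity × task_amplitude`, plus Poisson jerk transients — consistent
with choreiform LID phenomenology as irregular, non-stationary movement
overlaid on the task. `dysk_severity` is a separability dial: 0 makes the two
classes sample-for-sample identical; the defaults below are the study
conditions used everywhere in the tests and the acceptance script.

| parameter | default | meaning |
|---|---|---|
| `n_subjects`, `sessions_per_subject` | 60, 2–6 | ≈ 240 sessions per cohort |
| `prevalence` | 0.3 | dyskinesia-positive session fraction |
| `sample_rate` | 50 Hz | wearable-class rate |
| `duration` | 10–30 s | variable-length task windows |
| `task_freq` | 0.8–2.0 Hz | alternation rate |
| `task_amplitude` | 0.3–0.8 g | tangential peak; θ_A = 1.2 × amplitude (rad) |
| `dysk_severity` | 1.0 | overlay scale, fraction of task amplitude |
| `dysk_band` | 1–4 Hz | choreiform band |
| `dysk_am_depth`, `jerk_rate` | 0.3, 0.5 /s | modulation depth, jerk events |
| `noise_sd` | 0.02 g | white sensor noise |

Per-subject random effects (amplitude, frequency, a small gravity-direction
perturbation) are shared across a subject's sessions. The `shifted_site_params()`
preset builds a transfer target with doubled noise, 30 Hz sampling and a
gravity direction rotated by 25° — a covariate shift in exactly the nuisance
dimensions where the representations differ: the semantic features are
orientation-invariant (per-session PCA) and clock durations in seconds, while
the per-axis automatic features are tied to the device frame and, through
lag- and count-based descriptors, to the sample rate.

What the simulator does *not* emulate: real choreiform kinematics, tremor or
bradykinesia phenotypes, free-living activity, device dropouts, or annotation
noise. Tests passing on synthetic cohorts therefore demonstrate that the
pipeline is correct and that the representations behave as designed under a
controlled covariate shift — not that any particular clinical performance
level would be attained on real cohorts.

## Numerical choices and problem sizes

* Zero-valued trace samples carry the previous sign, so a touch of zero is
  not a crossing; leading zeros take the first non-zero sign.
* A part with no sign change yields one segment; extremum ties go to the
  earliest sample.
* The relevance filter uses the normal approximation of the Mann–Whitney
  test (`exact = FALSE`), making p-values deterministic and fast for n in the
  hundreds.
* kNN predictions pin the RNG state (the underlying implementation breaks
  ties at random); all stochastic learners receive seeds derived from the
  master seed.
* Simulation studies in the test suite use 10-fold CV with the 30-config
  `base_grid()` on cohorts of ~240 sessions (single cohort runs) and
  ~120 sessions × 10 generator seeds (the transfer-drop comparison) — sizes
  chosen so the full study runs in minutes on one CPU while keeping ≥ 30
  positives per cohort.

## Known limitations

* The semantic catalogue presumes an oscillatory task; on non-periodic
  activity the segmentation degenerates (single segments, sentinel values).
* The logistic model is ridge-penalised only; no elastic-net search.
* `selector_k` exceeding the available columns is clipped silently.
* Welch comparisons on 10 transfer scores have limited power; p-values are
  reported, not corrected for the three pairwise comparisons.
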