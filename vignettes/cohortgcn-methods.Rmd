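---
title: "Population-graph GCNs for connectome-based outcome prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-graph GCNs for connectome-based outcome prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortgcn)
```

## The modelling problem

`cohortgcn` classifies subjects of a partially labeled cohort into a binary
clinical outcome from their structural connectomes. The motivating setting
is neurodevelopmental risk prediction in very preterm infants: a 90-ROI
symmetric matrix of mean fractional anisotropy per subject, an outcome
defined by dichotomizing a standardized motor composite (normative mean 100,
SD 15, range 40–160) at one SD below the mean (85, boundary counted as
high-risk/positive), roughly one positive for every two negatives among the
labeled subjects, and about half the cohort unlabeled because follow-up has
not yet happened. The package consumes already-built connectome matrices;
image preprocessing, tractography and atlas registration are out of scope.

Three statistical ideas do the work:

1. **A cohort graph.** Subjects are nodes; node features are the
   `n(n-1)/2` unique connectivity weights (4005 for 90 ROIs, strict upper
   triangle in row-major order — the order is a convention, fixed so files
   are interchangeable across implementations). Edges carry a Gaussian
   similarity kernel `W_ij = exp(-d_ij^2 / (2 sigma^2))` on the Euclidean
   distance between feature vectors. The graph is fully connected — no k-NN
   sparsification or thresholding — and the features enter the distance
   unscaled, since mean-FA weights already share the [0, 1] scale
   (`standardize = TRUE` exists for other feature types). The kernel
   exponent follows the standard Gaussian affinity used in population-graph
   work; an `exp_distance` variant `exp(-d / (2 sigma^2))` is exposed as a
   config alternative for sensitivity analysis.
2. **A transductive GCN.** Each graph learning block applies the
   renormalized propagation operator `S = D~^(-1/2)(A + I)D~^(-1/2)`
   (first-order approximation to spectral graph convolution; the diagonal of
   `A` is forced to zero before `I` is added, so every self-loop contributes
   exactly 1). Blocks are ordered graph convolution → batch normalization →
   ReLU → dropout; the final block maps to **2 output channels** before
   batch normalization and a softmax. The published description of the
   optimal architecture gives all three blocks "128 graph filters", but a
   128-channel softmax cannot produce a binary label, so this implementation
   reads 128 as the final block's input width and fixes its output at the
   2 classes — the one place where the architecture description had to be
   interpreted. Training is full-batch Adam on the masked (optionally
   inverse-frequency-weighted) cross-entropy: every epoch the whole graph is
   propagated, but only `train_labeled` nodes contribute loss. Unlabeled and
   test nodes therefore influence the learned representation through their
   features only; permuting their stored labels provably changes nothing
   (this is a unit test).
3. **Repeated stratified cross-validation.** The labeled subjects are
   partitioned into 5 near-equal folds (119 subjects give sizes
   24/24/24/24/23), 50 repeats by default; unlabeled subjects are never
   tested on. Folds are stratified by class — the protocol description says
   only "partitioned into 5 portions", but at a 1:2 ratio with n = 119
   unstratified folds make fold-level sensitivity estimates unstable, so
   stratification is the default and a non-stratified mode exists. Both the
   fold assignment and the model initialization are re-randomized per
   repeat, from seeds derived deterministically from the scheme's
   `base_seed`.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `sigma` | 1.6 | kernel decay scale, in feature-space distance units; the published sweep is [0.7, 1.0, 1.3, 1.6, 1.9, 2.2] and 1.6 was optimal there |
| `n_layers` | 3 | graph learning blocks, searched over 1–4 |
| `n_filters` | 128 | hidden width, searched over {512, 256, 128, 64, 32, 16} |
| `dropout_rate` | 0.5 | unspecified in the source description; 0.5 is the conventional default |
| `learning_rate` | 0.01 | Adam step size, betas (0.9, 0.999) |
| `max_epochs` | 2000 | fixed horizon; no early stopping, matching the described protocol |
| `loss` | "weighted" | inverse-frequency class weights `beta_c = N/C_c` computed on the training mask |
| `n_folds`, `n_repeats` | 5, 50 | evaluation protocol |

Hyperparameter selection (the sigma grid, filters, layers) is exposed as an
outer sweep reported per configuration (`sigma_grid` in the run config),
mirroring how the optimal setting was chosen; note that selecting sigma on
test AUC leaks information, so for honest generalization estimates the sweep
should be read as a sensitivity analysis, or nested within the training
folds.

## Numerical choices

* **Weight initialization** is Glorot-uniform from the config seed;
  batch-norm starts as the identity (scale 1, shift 0).
* **Batch normalization** operates per channel across all graph nodes — the
  only batch available in full-graph training. After the last epoch the
  batch-norm statistics are **recalibrated**: one dropout-free pass stores
  the exact full-batch moments under the final weights. Without this, the
  exponential running moments (momentum 0.1) lag the still-moving batch
  statistics by one averaging window, and although the per-channel error is
  tiny, summing 128 slightly-shifted channels into the 2 output logits can
  shift them by tens of units and saturate the softmax. Recalibration is
  exact, cheap, and standard practice for full-batch training.
* **Probability clamping** at 1e-12 inside the logarithm avoids -Inf on
  saturated nodes; a probability row must still sum to 1 within 1e-6.
* **Ties** in `predict` (probability exactly 0.5) resolve to positive, the
  high-risk class — the conservative clinical direction. AUC uses the
  Mann–Whitney rank statistic with midranks for tied scores.
* **Symmetry tolerance**: matrices read from text are accepted as symmetric
  within 1e-8 relative error and symmetrized by averaging, because CSV
  round-trips can break exact symmetry. Validation errors name the first
  offending entry pair.
* **Degenerate inputs**: a training mask with a single class is an error
  (inverse-frequency weights are undefined); a single-class test fold
  reports AUC as `NA` and leaves the other metrics defined; missing scores
  dichotomize to `unlabeled`, never an error.
* **Paired comparisons** between models collapse each report to per-repeat
  means and apply a paired t-test (Wilcoxon signed-rank as an alternative);
  the test type is a package choice, as the source protocol does not name
  one. Degenerate all-zero differences return p = 1 rather than an error.

## The synthetic cohort generator

No public accession exists for the motivating cohort, so the generator is a
first-class module that emulates its structure: 224 subjects (119 labeled /
105 unlabeled), prevalence 37/119, 90-ROI matrices with weights in [0, 1],
and motor scores Normal(100, 15) clipped to [40, 160], with the positive
class's mean shifted down by `score_class_gap` (default 30, which makes the
generating class agree with score dichotomization for ~84% of subjects —
classes are drawn first and scores conditionally, so the same cohort
exercises both the label-based and the score-based entry points).

Connectomes are built as: one base symmetric mean connectome per cohort
(edge means `0.1 + 0.7 * Beta(3, 3)`, kept away from the [0, 1] bounds so
that post-noise clipping affects well under 1% of draws at the default
`noise_sd = 0.04`), plus a class shift of `effect_size` on a fixed random
`affected_fraction` (default 10%) of edges, plus i.i.d. Gaussian edge noise,
clipped. Because every subject shares the base connectome, between-subject
similarity is high and the Gaussian kernel produces a non-trivial weight
distribution, as with real FA connectomes.

`effect_size`, `affected_fraction` and `noise_sd` have no real-data
analogue. The default `effect_size = 0.007` was calibrated once so that
labeled-only cross-validated AUC lands in the 0.6–0.8 band typical of
connectome-based outcome prediction (a single sweep over candidate values,
averaged over three generator seeds, using the RBF-SVM baseline; the GCN at
the same setting reaches AUC ≈ 0.64), and is not adjusted per experiment.
No numeric equivalence to any published cohort is claimed.

**The manifold cohort** (`generate_manifold_cohort()`) is a separate
construction for studying the semi-supervised gain: two elongated parallel
clusters (length 3, separation 0.5, thickness `noise_sd` in feature-space
units, embedded along two fixed orthonormal directions on top of a base
connectome near 0.5). With few labeled subjects, their chance positions
along the elongation axis tilt any boundary fitted from labels alone; the
dense unlabeled subjects trace the cluster shape, so a transductive model
can smooth predictions along each cluster. The gain experiment uses
20 labeled + 200 unlabeled subjects, 12 ROIs, thickness 0.08, and
`sigma = 0.5` — at that scale the kernel is local along a cluster (adjacent
unlabeled subjects sit ~0.03 apart) while cross-cluster weights are small
(`exp(-0.25/0.5) ≈ 0.6` at the 0.5 gap, decaying quickly for the typical
larger cross-pair distances).

What the generator does **not** emulate: site effects, motion artifacts,
heavy-tailed or spatially correlated edge noise, topological constraints of
real white-matter networks, and covariate shift between labeled and
unlabeled subjects. Passing tests on these cohorts therefore demonstrate the
correctness and the qualitative behavior of the machinery — not expected
performance on real connectomes.

## Problem sizes used in the test suite

The published protocol (90 ROIs, 224 subjects, 2000 epochs, 5 × 50 CV) is
the package default, and a single full-size training takes on the order of
two minutes on one CPU core. The test suite exercises the same code paths at
reduced sizes chosen to keep the full suite in the minutes range: recovery
uses 60 + 20 subjects at 12 ROIs with a large effect (5 × 5 CV, 150 epochs);
the semi-supervised-gain and loss-ablation experiments use 20 paired
generator seeds each, 200 training epochs, with 220-node (12-ROI) and
120-node (16-ROI) cohorts respectively. The ablation cohort
(`effect_size = 0.015` at 16 ROIs, prevalence 1/3) keeps the task moderately
hard so that the loss choice can visibly move the sensitivity–specificity
balance.

## Known limitations

* Transductive inference: predicting a new subject requires rebuilding the
  graph with the training cohort present and re-running the forward pass
  with the saved weights (`cmd_predict` enforces this contract). The model
  cannot score a subject in isolation.
* The GCN, batch-norm backpropagation and Adam are implemented in plain R
  matrix algebra. This is exact and fast at cohort scale (hundreds of
  nodes), but not intended for graphs orders of magnitude larger.
* The baselines use fixed, conventional regularization (ridge penalty
  `lambda = 1/n`, variance-scaled RBF bandwidth) rather than per-fold
  hyperparameter searches; they are comparators, not tuned competitors.
* Only connectome similarity defines the edges; multi-modal or
  covariate-augmented edge weights are out of scope.
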