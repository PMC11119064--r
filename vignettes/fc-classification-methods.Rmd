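---
title: "Classifying functional connectivity networks: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying functional connectivity networks: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcnet)
```

# The problem

Resting-state fMRI yields, per subject, a symmetric N×N matrix of Pearson
correlations between regional time series — the functional connectivity
(FC) matrix. Diagnostic classification from FC faces two structural
obstacles: clinical samples are small (tens to a few hundred subjects), and
FC matrices are graphs, which convolutional architectures built for images
handle poorly. `fcnet` implements two complementary answers: a spectral
graph convolutional network (GCN) that respects the graph structure, and a
conditional auxiliary-classifier GAN that augments scarce data while its
BrainNetCNN discriminator doubles as the classifier.

# Models and assumptions

## Backbone graph

All subjects share one binary graph derived from training data only: the
mean training FC matrix is thresholded at τ (strictly greater-than; ties at
τ are dropped; the diagonal is zeroed first so self-correlations never
become edges). Only positive correlations can become edges — the retention
curve's denominator is the count of positive off-diagonal entries, so
negative and zero correlations are excluded throughout.

The published rule for τ is "the elbow of the retention curve", a visual
criterion. We operationalize it as the grid point of maximum perpendicular
distance to the chord joining the curve's endpoints (the Kneedle
construction), after mapping both axes to [0, 1] so the choice is invariant
to axis units. Ties break toward the smaller τ; a curve whose maximum chord
distance is below 1e-9 has no elbow and returns the smallest grid τ with a
warning. `buildBackbone(..., tau =)` overrides the rule, which is how the
published per-dataset cutoffs (0.15 for three of the four clinical
datasets, 0.2 for the fourth) would be reproduced.

Convolution uses S = D̃^(−1/2)(I + A)D̃^(−1/2). Self-loops guarantee every
degree ≥ 1, so isolated nodes are harmless; S is symmetric, nonnegative,
with spectral radius ≤ 1 (tested by eigendecomposition).

## The GCN

Two spectral convolutions (widths 25, 10, ReLU, no bias — the propagation
rule is H' = σ(S H W)), one self-attention pooling layer down to k = 10
nodes, then fusion and a softmax head. H⁽⁰⁾ is the subject's FC matrix
itself: each node's initial feature vector is its connectivity profile.

Pooling scores are z = tanh(S H Θ) with the same normalized operator as the
convolutions (the score filter is itself a one-filter graph convolution).
Decisions the source architecture leaves open, fixed here:

* **Top-k ties** break toward the lower node index (stable sort), so runs
  are deterministic.
* **Kept nodes are returned in ascending original order**, not score
  order, so position i of the flattened vector means the same region for
  every subject.
* **Flattening** is node-major (node 1's 10 features, then node 2's, ...).
* The length-15 projection of the flattened representation and the
  length-2 phenotype projection are **linear** (no activation stated, none
  used).

Training: Adam (learning rate 0.01), categorical cross-entropy, minibatch
32, 200 epochs by default, Glorot-uniform initialization under a derived
seed. Optional inverse-frequency class weights are off by default. When a
validation cohort is passed, the epoch with the best validation accuracy
supplies the returned parameters.

## The GAN

The generator cannot output an arbitrary matrix: FC is an inner-product
object. A latent vector of total length 50 — uniform(−1, 1) noise plus the
condition slots (one-hot label, phenotype encoding) — passes through a
small MLP (one hidden layer of width 128, LeakyReLU) to an N×d embedding
matrix X (d = 10, one row per region), and the output is A = tanh(XXᵀ):
exactly symmetric, entries in (−1, 1). Two consequences worth knowing:

* The diagonal is tanh(‖xᵢ‖²) ∈ [0, 1), not exactly 1. Generated samples
  are fed to the discriminator as-is; the unit-diagonal invariant of real
  cohorts is waived for provenance `"synthetic:GAN"`.
* In double precision tanh saturates: |XXᵀ| ≳ 19 rounds to exactly 1.0.
  The open interval is a mathematical property; numerically it holds for
  the parameter scales reached under training but not for arbitrarily
  large weights.

The discriminator is a BrainNetCNN — edge-to-edge (16 cross-shaped filters
summing over the row and column through each edge), edge-to-node (64
filters aggregating each node's incident edges), node-to-graph (128
whole-graph summaries) — each followed by batch normalization, LeakyReLU
(slope 0.2) and dropout 0.5, then dense(64), concatenation with a
dense(16) phenotype projection, dense(32), and two heads (sigmoid validity,
softmax class).

The source never writes the GAN objective; we use the standard AC-GAN
composition consistent with its cited conditional-GAN lineage: the
discriminator minimizes validity BCE (real vs generated) plus class
cross-entropy on real samples; the generator minimizes validity loss toward
"real" plus class loss toward its conditioned label. A config flag
(`class_loss_on_fake`) enables the semi-supervised variant in which the
discriminator's class loss also covers generated samples. Conditioning
pairs (label, phenotype) for generated samples are bootstrapped jointly
from the training cohort, preserving their coupling; the discriminator sees
generated matrices paired with their sampled conditioning phenotype.
Unstated hyperparameters fixed here: epochs 300, batch 16, generator hidden
width 128, batch-norm after each of ECE/ECN/NCG and after dense(64).
Optimizer per the source: Adam, learning rate 1e-4, β₁ = 0.5. Model
selection uses validation class accuracy with validity accuracy nearest 0.5
as tie-breaker. `trainBrainNetCNN()` trains the identical backbone with
only the class head — the baseline against which the augmentation benefit
is measured.

There is no automatic-differentiation framework in this stack; every
gradient is derived by hand in matrix form and checked two ways: each layer
against explicit loop oracles, and the full discriminator/generator against
central finite differences (agreement ~1e-9 relative). The discriminator's
training hot path (edge-map expansion and reduction, batch normalization,
fused LeakyReLU + dropout, Adam updates) runs through small Rcpp kernels
with identical math; random draws stay on the R side, so seed control and
reproducibility are unaffected.

## Evaluation protocol

10% of subjects (stratified by class, round-robin) are held out; the rest
form 5 cross-validation folds. Each model trains once per fold; the fold
model with the best validation accuracy is evaluated once on the test set.
Metrics: accuracy plus one-vs-rest precision, recall/sensitivity,
specificity, F1 and AUC (rank statistic, half credit for ties). Multiclass
values are unweighted macro means with zero-denominator classes dropped and
noted (published tables print "-" in those cells); the binary panel reduces
to the standard definitions for the designated positive class — the last,
non-control label — which is also the orientation of sensitivity and
specificity.

Significance: (1) the exact one-sided binomial tail
P(X ≥ n_correct | n, p₀) models the classifier as a Bernoulli process; the
source motivates p₀ = 0.5 for the binary case, and we generalize to
p₀ = 1/n_classes for multiclass (exposed as an argument). (2) one-sided
Wilcoxon rank-sum on fold accuracies, H₁: the proposed model is better.
For combined n ≤ 12 the permutation distribution of the rank sum is
enumerated exactly with tie-corrected mid-ranks (`wilcox.test` cannot do
exact-with-ties); larger samples use the normal approximation with tie and
continuity corrections. All-identical inputs return p = 1 with a
degenerate-data warning. Whether the published per-model significance used
the holdout or pooled CV predictions is unstated; this package tests the
holdout set.

# The synthetic-cohort generator

Real FC arises from correlating time series, so the generator simulates
that mechanism rather than adding noise to correlations directly — this
keeps tail behaviour and thresholding realistic. Per class, a population
correlation matrix combines a shared sparse backbone (default: 20% of
edges at correlations uniform in 0.25–0.45) with a planted set of edges
(default 5%) whose correlation differs by Δr (default 0.4) in the patient
class. Per subject, symmetric jitter (sd 0.05) perturbs the latent
covariance, any indefiniteness is repaired by eigenvalue clipping at 1e-6
followed by re-normalization to unit diagonal, and T = 150
multivariate-normal samples yield the sample Pearson matrix. Phenotypes:
age normal per class (means 34/40, sd 8, truncated to [5, 90]), sex
Bernoulli(0.5), site optional. Defaults are desk-scale (N = 20, 40 + 40
subjects) stand-ins for the published setting (N ≈ 200, hundreds of
subjects); T = 150 matches a typical resting-state scan length.

What the generator does **not** emulate: hemodynamics and deconvolution,
motion artifacts, site batch effects on the matrices themselves, negative
planted effects, non-Gaussian noise. A green test therefore establishes
that the pipeline recovers planted covariance structure of a stated size
under Gaussian sampling noise — not clinical-grade performance; the
published accuracies on restricted clinical datasets are not reproducible
from synthetic data and are not targeted.

# Numerical choices and degenerate inputs

* Symmetry tolerance on ingest 1e-6; correlations validated to [−1, 1];
  phenotype ages clamped at 100 years (with warning) to preserve the
  [0, 1] encoding bound rather than rejecting valid elderly subjects;
  missing phenotype values are refused — no imputation rule exists in the
  source.
* One-hot orders are frozen: sex (F, M); site levels lexicographic,
  recorded in the cohort manifest.
* Binary matrix container: raw little-endian doubles, row-major —
  round-trips bit-exactly. Text matrices print %.17g (round-trip ≤ 1e-12).
* Empty edge sets after thresholding are allowed (S = I, warning); a mean
  matrix with no positive entries is an error (the retention denominator
  would be zero).
* Batch normalization uses batch statistics in training and running
  moments (momentum 0.9) in evaluation, so evaluation-mode forwards are
  deterministic; dropout is inactive in evaluation. During adversarial
  training, real and generated batches are forwarded separately (each
  normalized by its own batch statistics, as in canonical GAN
  implementations) and the running moments are updated from real batches
  only — evaluation normalizes real data, and letting generated batches
  drift the moments measurably degrades the discriminator as a classifier.
* Every training loop derives named sub-seeds (`deriveSeed`) from one
  global seed — split, initialization, shuffling and sampling have
  independent streams, so adding a stage never perturbs earlier ones; all
  operations are bit-reproducible under a fixed seed.

# Known limitations

* Training is sized for desk scale (seconds for the GCN, tens of seconds
  for a full GAN run at N = 20); N = 200 cohorts of hundreds of subjects
  would need minutes-to-hours per model, not a GPU, but patience.
* The test-time behaviour of batch normalization depends on the running
  moments accumulated during training; very short trainings evaluate with
  near-initialization moments.
* The elbow rule needs a reasonably convex retention curve; on flat or
  linear curves it degenerates (by design, with a warning) to the smallest
  candidate τ.
* Weighted or directed backbone graphs, dynamic connectivity and
  population-graph variants are out of scope.
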