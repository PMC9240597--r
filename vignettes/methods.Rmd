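---
title: "Multi-label protein localization under class imbalance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-label protein localization under class imbalance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A protein's subcellular compartment constrains its function, and a single
protein may reside in several compartments at once, so localization
prediction is a multi-label classification problem. Curated benchmarks are
severely imbalanced: a few compartments (cytoplasm, nucleus) hold the bulk of
annotated proteins while others contribute a few dozen samples, and that skew
degrades classifiers precisely on the labels biologists care most about.
`mlploc` implements a three-stage pipeline for this setting:

1. **Featurization.** Each protein is represented by its PSI-BLAST
   position-specific scoring matrix (PSSM), an L x 20 table of per-position
   substitution log-odds capturing evolutionary conservation. Because L
   varies, the matrix is reduced to a fixed 20 x 20 *PSSM composition*:
   entry (a, j) is the mean score toward amino acid j over positions
   occupied by residue type a.
2. **Rebalancing.** A distance-regularized generative adversarial network is
   trained on each minority class's feature pool and synthesizes additional
   samples until the class counts match a target policy.
3. **Classification.** A multi-label DeepFM — a factorization machine and a
   deep dense network trained in parallel and summed — is fitted under a
   thresholded exponential ranking loss and evaluated with the five standard
   multi-label metrics under k-fold cross-validation.

## Feature discretization

Printed formulations of the PSSM reduction are ambiguous between a
column-mean 20-vector and a 20 x 20 matrix. Both are provided
(`pssm_features(mode = "grouped")` and `mode = "column_mean"`), with the
grouped residue-composition form as the default: it is the standard encoding
in the localization literature and is the only form that actually has the
20 x 20 shape downstream components assume. Residue types absent from a
sequence leave their row at the fill value 0, the neutral log-odds score.
Non-standard residues (X/B/Z/U) have no row of their own: they are dropped
from grouping (counted in the `n_nonstandard` attribute) but contribute to
column means. Only the first 20 numeric columns of a PSSM file (the log-odds
block) are used; the trailing weighted-percentage block is ignored.

Features are standardized per feature, with the scaler fitted on each
training fold only. Both GAN and classifier training are scale-sensitive and
fold-restricted fitting avoids information leaking from evaluation folds.
Zero-variance features keep scale 1.

## The rebalancing GAN

The discriminator maximizes

$$E[\log D(x)] + E[\log(1 - D(G(z)))] + E[\log d(G(z), \bar{x})]$$

and the generator minimizes

$$E[-\log D(G(z))] + \lambda\, E[\log d(G(z), \bar{x})],$$

where $d$ is the Euclidean distance of a generated sample to the mean
$\bar{x}$ of the real minority pool, floored at `epsilon_dist` so its
logarithm stays finite. The distance term has no discriminator parameters,
so the discriminator update reduces to the standard binary game; in the
generator it acts as a pull toward the minority centroid, with $\lambda$
(default 0.1) trading distributional fidelity against anti-stacking
diversity. The latent distribution is standard normal with dimension 64 by
default.

Both networks are fully connected dense stacks (generator: a dense stem and
three further layers up to the feature dimension; discriminator: two hidden
layers and a sigmoid head). Rows and columns of a residue-grouped
composition matrix index residue and target amino-acid *types*, which carry
no translation-invariant spatial structure, so convolution offers no
inductive-bias advantage at 20 x 20, and dense layers keep every gradient
exact and auditable in the pure-R implementation.

Two stabilizers matter on the very small pools minority classes provide
(tens of samples):

* the generator's output bias starts at the real-pool mean, so training
  shapes the spread instead of first traveling to the data region;
* Gaussian *instance noise* (config field `instance_noise`) is added to the
  discriminator's inputs, real and fake alike, preventing it from memorizing
  a handful of points.

Neither changes the objectives above. A known degenerate regime remains:
with strong regularization or instance noise comparable to the within-class
spread, the generator can concentrate near the pool centroid — prototype-like
samples that still rebalance the loss but carry little diversity. With pools
of a few hundred samples (the regime of the two-dimensional recovery test)
the generator reproduces the pool mean to well under one within-class
standard deviation.

`plan_rebalance()` counts, for every label, the samples bearing it, and tops
minority classes up to the majority count (`match_majority`) or to a
fraction of it (`ratio`). One unconditional GAN is trained per deficient
class on the samples carrying that label; synthetic samples receive that
single label (how multi-label annotations should be attached to synthetic
samples is an open question we deliberately avoid) and a `synthetic = TRUE`
provenance flag. Classes with fewer than two real samples fall back to
duplicate-with-jitter with a warning.

## The multi-label DeepFM

Scores are the elementwise sum $\hat{y} = y_{FM} + y_{Deep}$ over K labels.

**FM component.** The factorization machine scores
$\sum_i w_i x_i + \sum_{i<j} \langle v_i, v_j\rangle x_i x_j$ with latent
factors $v_i \in R^{k}$ (default k = 8); the pairwise term is computed with
the $O(nk)$ identity rather than the quadratic double sum, and the two are
verified equal in the tests. For K outputs, the FM layer emits the
per-feature first-order terms $w_i x_i$ (the addition units of the original
DeepFM) concatenated with the k per-factor pooled interaction terms, and a
dense head maps this (p + k)-vector to K scores. An earlier variant that
collapsed the first-order information into a single scalar before the head
was abandoned: the scalar bottleneck left the FM component strictly
dominated in every benchmark we ran, which contradicts the design intent
that the FM component carries the low-order signal. A head that sums its
inputs reproduces the scalar FM value exactly for every label, which the
tests assert.

**Deep component.** A ReLU chain with widths 256, 128, 64, 32 and a linear
K-unit output layer (no output activation, so scores may be negative), with
dropout 0.5 on hidden activations during training.

**Loss.** Per sample, with relevant set $R$, irrelevant set $I$ and
threshold $y_0 = 0$:

$$\log\Big(1 + \sum_{k \in I, r \in R} e^{s_k - s_r}
  + \sum_{k \in I} e^{s_k - y_0} + \sum_{r \in R} e^{y_0 - s_r}\Big)$$

summed over the batch. The leading 1 bounds the loss below by zero; without
it the loss diverges to $-\infty$ under perfect separation, which is not
optimizable. The literal form is available via `plus_one = FALSE`. All
reductions are log-sum-exp stabilized, and analytic gradients are verified
against central finite differences to 1e-4. Prediction emits every label
scoring above $y_0$; if none does, the top-scoring label is emitted alone
(every protein has at least one location), ties resolved toward the lower
label index.

## Evaluation metrics

`evaluate_multilabel()` computes Hamming loss, one-error, coverage, ranking
loss and average precision, each cross-checked against brute-force
enumeration oracles in the tests. Conventions worth noting:

* Hamming loss divides by N x K (the standard definition; magnitudes below 1
  match how these values are usually reported). `normalize = FALSE` gives
  the N-normalized literal variant.
* Coverage is the mean rank depth needed to cover all relevant labels, with
  **no** minus-one correction, so its ideal value is the mean label
  cardinality and its range is [1, K]; `minus_one = TRUE` is provided for
  comparability with the other convention.
* Ranks break ties toward the lower label index, deterministically.
* Samples whose labels are all relevant have no pairs to mis-order and are
  excluded from ranking loss with a warning.

## Cross-validation and the experiment matrix

`run_cross_validation()` evaluates arms of the form {DeepFM, FM alone, Deep
alone} x {with, without rebalancing} under k-fold cross-validation
(default 10 folds, random assignment; greedy iterative multi-label
stratification is available but off by default). Within each fold the scaler
is fitted on the training split, the rebalancer sees only the training
split, and synthetic samples never reach a test fold — applying oversampling
before splitting would place synthetic near-copies of test samples into
training and inflate every metric. GAN and classifier training budgets are
configurable down from the 1,000-epoch defaults so experiments run at desk
scale.

## The synthetic generator

`generate_multilabel_dataset()` draws class-conditional isotropic Gaussian
feature matrices: class k contributes `n_per_class[k]` samples at mean
`class_means[k, ]` with standard deviation `noise_sd`, carrying label k plus
each other label j independently with probability `cooccurrence[k, j]`. The
defaults model the imbalance structure of curated localization benchmarks: a
500/50/20 three-class skew (majority/minority ratio 25) and co-occurrence
0.02, matching data where over 80% of proteins are single-location. The
Gaussian family was chosen because the GAN's mean-pulling regularizer then
has a known target, making distribution recovery testable; it does not
emulate real PSSM score distributions, sequence-length effects, or
feature-dependent label correlations, so passing tests demonstrate correct
mechanics and the imbalance phenomenology, not benchmark-level accuracy.

## The standing imbalance experiment

`imbalance_experiment()` fixes the package's desk-scale study: five
independent 570-sample replicates (500/50/20), 20-dimensional features with
the two minority classes 4 within-class standard deviations from the
majority along orthogonal axes, 3-fold cross-validation per replicate, a
60-epoch / 2e-3 classifier budget (batch 128, latent 8, hidden 32/16) and a
400-epoch / 2e-3 GAN budget with instance noise 0.75. Two conditions are
deliberate and load-bearing:

* **Budget-limited training.** The ranking loss is additive per sample, so
  minority samples contribute full-strength gradients but only ~12% of the
  gradient mass; under the reduced budget their labels are still under-fit
  when training stops, which is exactly the failure mode oversampling
  repairs by multiplying the minority gradient share.
* **Low co-occurrence.** Because the generator's co-labels are
  feature-independent, high co-occurrence fills a minority pool with
  samples whose features belong to other classes; single-label synthetic
  copies of those poison training. At 0.02 the pools are clean.

Under these conditions rebalancing lowers coverage and raises average
precision for every classifier family (pooled across families, coverage
falls from about 1.35 to 1.28 and average precision rises from about 0.88
to 0.91; the deep-only family shows the largest single effect). One
documented limitation: the component ordering reported on real PSSM
benchmarks — FM outperforming the deep component — does not reproduce on
this generator family. On class-conditional Gaussians every function the FM
can express is also expressible by the deep network, which moves faster in
function space under a shared Adam budget and has nothing to overfit in
570 clean samples; the FM-over-Deep effect appears tied to the structure of
real evolutionary-profile features and is outside what this generator can
emulate.

## Numerical choices

* Adam with $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$
  throughout; alternating 1:1 generator/discriminator updates.
* Discriminator probabilities are clamped to $[10^{-7}, 1 - 10^{-7}]$ inside
  objective evaluations; training gradients use the numerically exact
  sigmoid-cross-entropy forms and need no clamp.
* Distances are floored at `epsilon_dist` (default $10^{-6}$) before logs.
* All training loops are deterministic given their config seeds; derived
  seeds (per class, per fold) stay within 32-bit integer range.
* Batch sizes are clipped to the pool size; a batch of one sample still
  trains (matrix shapes are preserved throughout).
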