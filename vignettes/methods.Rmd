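---
title: "Modelling compound potency from structure images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling compound potency from structure images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`molimage` models compound potency on a continuous scale from 2D
Kekulé structure drawings, benchmarked against fingerprint-based
Random Forest and fully-connected network baselines. This vignette
documents the models, the tunable parameters and their defaults, the
numerical choices made where the design was genuinely open, what the
synthetic data generator does and does not emulate, and the package's
known limitations.

## Data model and curation

The unit of modelling is the pair (compound, target) annotated with a
pIC50 = −log10 IC50 [M]. Raw activity tables are curated with a
deliberately stringent, assumption-light rule set:

* only rows with unit `"nM"` and relation `"="` are kept (exact string
  match after whitespace trimming; no unit conversion — a µg/mL entry is
  dropped, not converted, because conversion needs a molecular weight
  for a structure that has not been standardized yet);
* counterions and solvents are removed by keeping the fragment with the
  most heavy atoms among the fragments composed solely of the
  conventional organic element set {H, B, C, N, O, F, Si, P, S, Cl, Se,
  Br, I}; species with no such fragment (bare metal ions, salts of
  inorganic acids) are *rejected with a reason*, not raised as errors,
  so curation of a large table never aborts mid-way. Ties between
  fragments are broken by molecular weight and then by lexicographic
  canonical SMILES, making the choice deterministic;
* charged organic species are kept as-is: no neutralization, tautomer
  or stereochemistry canonicalization is attempted, because those
  transformations are policy decisions that belong upstream;
* replicate measurements for the same (compound, target) pair are
  averaged **on the pIC50 scale**. Averaging the log, not the
  concentration, halves the influence of a single discordant
  concentration outlier: IC50s of 10 nM and 1000 nM average to pIC50
  7.0, not to the pIC50 of 505 nM (≈ 6.3).

Curation is idempotent: feeding its output back through the pipeline
changes nothing. Parsing, canonicalization and molecular properties are
delegated to OpenBabel through ChemmineOB/ChemmineR.

Circular (Morgan-type) fingerprints use OpenBabel's
extended-connectivity implementation at radius 2 (ECFP4-style
environments) and are folded from the native 4096 bits to the requested
length (128–2048) by OR-ing equal blocks — the standard fold, which
preserves set bits at the cost of collisions. Fingerprints are
deterministic and invariant to the atom ordering of the input SMILES.

## Image representation

Molecules are drawn as Kekulé structures — explicit alternating
single/double bonds, element-colored heteroatom labels, white
background — on a 224 × 224 RGB canvas, the input size the classic
backbones expect. Two depiction defaults deserve explanation:

* **bond stroke width 3 px, atom label size 1.3×.** The first
  convolution of AlexNet has stride 4, so a hairline (1 px,
  anti-aliased) stroke contributes almost nothing to any feature map.
  With heavier strokes the drawing survives the downsampling. This is a
  style choice like any other sketching convention; all rendering
  settings are captured in a provenance hash stored with every image
  and manifest, so models are only ever compared within one style.
* **deterministic rasterization.** Identical input and settings produce
  byte-identical pixel arrays on a given platform. Hashes of the pixel
  content (not the PNG container) are recorded in the library manifest,
  and `render_library()` re-renders only when the provenance hash
  changes.

Training-time augmentation applies a horizontal flip, a vertical flip,
and a ±90° rotation (direction uniform), each independently with
probability 0.5, freshly at each epoch. Any composition of these
transforms is an element of the 8-element dihedral group of the square,
a fact the frozen-backbone training path exploits (below).

## Models

**ConvNet regressors.** A backbone feature extractor (AlexNet,
VGG-19-bn, ResNet-152, or DenseNet-201, faithful to their published
layer layouts) feeds a regression head: `standard` (one linear layer to
the task outputs) or `extended` (hidden fully-connected layers of 4096,
1000, 200, 100 rectified-linear units, 50% dropout after each, then the
linear output — five fully-connected layers in total). No output
nonlinearity exists in either head; predictions live on the open pIC50
scale. Where the original architectures disagree on details the
resolution is: four hidden widths plus the output layer (the only
reading consistent with "five fully-connected layers"), and a
rectified-linear activation after the last hidden layer (a
configuration point the architecture description leaves open; chosen
for consistency with the baseline network).

The engine underneath is the package's own: layers with explicit
forward/backward passes (convolution via im2col in C++, so each
convolution is one BLAS product), verified against numerical
differentiation in the test suite to ~1e-10 relative error. Batch
normalization computes per-image (instance) statistics during training
— images stream through the convolutional stack one at a time — while
inference uses running statistics; this is documented engine semantics,
not an approximation of some other library.

Pretrained ImageNet weights are not bundled and cannot be downloaded in
an offline installation, so `pretrained = FALSE` (He initialization) is
the default; requesting pretrained weights raises an informative error.
Consequently the frozen-backbone mode uses the backbone as a *random
feature extractor* — a classic random-projection regression — and what
the desk-scale experiments demonstrate is that the rendered images
carry recoverable structure–activity signal, not that ImageNet features
transfer.

**Baselines.** A 100-tree Random Forest (library defaults otherwise)
and a fully-connected network (input → 60 → 20 → 10 → 1,
rectified-linear, 10% dropout on the hidden layers) on fingerprints of
128–2048 bits. All model families share the same 70/15/15
train/validation/test split (sizes `floor(0.7n)`, `floor(0.15n)`,
remainder). The forest deliberately ignores the validation split — it
has no tuned parameters — but keeps it in the split so every family
sees an identical test set.

## Optimization

Stochastic gradient descent with Nesterov momentum 0.9 (the
`v ← μv + g; w ← w − lr(g + μv)` form) minimizes mean squared error per
mini-batch; validation RMSE is the monitored loss. Monitoring RMSE but
stepping on MSE changes nothing about the argmin, only the gradient
scale. The learning rate follows a cyclic step decay: within each
200-epoch cycle, `lr(e) = lr0 · decay^floor((e mod 200)/step)`,
resetting to `lr0` at each cycle start; decay ∈ {0.1, 0.6} and step ∈
{10, 25} are the tuned values, alongside lr0 ∈ {0.1, 0.01, 0.005,
0.001, 0.0001}, augmentation ∈ {off, on} and batch ∈ {4, 16, 32} — a
120-point grid searched by validation RMSE with first-in-order tie
breaking. Momentum buffers are carried across cycle boundaries.
ConvNets train up to 600 epochs with early-stopping patience 250;
the fingerprint network up to 2000 epochs, patience 200, batch size
`ceiling(0.15 · n_train)`.

Three loop details are the package's own design:

* **best-checkpoint return.** The parameters returned are those of the
  epoch with the lowest validation RMSE, never the last epoch's, and
  patience counts epochs since that global best regardless of cycles.
* **null-model warm start.** The output layer starts at zero weights
  with its bias at the training-mean label (per task), so optimization
  begins *at* the mean-predictor baseline, and the initial state is
  itself a checkpoint candidate (validation is evaluated once before
  any update). A run can therefore never return a model worse on
  validation than the null model — which also makes Y-scrambling
  behave cleanly: with no learnable signal, training tends to return
  (near-)constant predictions. When the returned predictor is exactly
  constant, squared-correlation R² is undefined and the collapse
  statistic is reported as 0, the natural value for a predictor with no
  association with the observations.
* **frozen-backbone feature path.** With `freeze_backbone = TRUE`
  features are extracted once and standardized with training-split
  statistics (a conditioning necessity for plain SGD on random
  features; the statistics are part of the model, applied identically
  to validation and test). Under augmentation, features are
  precomputed for all 8 dihedral variants of each image and the
  per-epoch draw selects a row — exactly equivalent to augmenting
  pixels, at 8× one-off cost instead of per-epoch re-extraction.

Multi-task training masks unobserved (compound, task) labels: the loss
is the mean of squared errors over observed pairs only, so a task
missing from a batch contributes exactly zero gradient. Per-task test
RMSEs are reported separately.

## Run comparison: the factorial model

Benchmark runs (one row per trained model: dataset, model, batch,
augmentation, replicate, and a scalar response) are compared by
treatment-coded ordinary least squares. The response is the run's test
RMSE in pIC50 units — the only reading under which "variance explained
in model performance" is meaningful — though any per-run scalar can be
supplied. The intercept is the mean response of the reference-level
cell; each coefficient is a level's offset from it; on balanced designs
these estimates coincide with differences of marginal cell means (a
property the tests verify against a cell-mean oracle). Per-factor
p-values use Type-II ANOVA, which on the balanced designs targeted here
coincides with the sequential decomposition (also verified). Empty
design cells make effects inestimable and raise an error naming the
cells rather than silently dropping terms. A two-factor variant with
all dataset × model interactions serves the cross-family comparison,
with `select_best_per_cell()` implementing the "best ConvNet per
dataset and replicate" selection rule (ties to the first architecture
in enumeration order).

## The synthetic data generator

The generator exists so that every stage is testable offline with known
ground truth. It emulates the *shape* of public IC50 collections:

* an imbalanced pIC50 distribution with its mode in the 4–5 band
  (base activity 4.5) and a thinner right tail of potent compounds —
  at the defaults ~44% of true values lie in [4, 5];
* measurement noise (SD 0.3 pIC50 units, the order of inter-assay IC50
  reproducibility), replicate rows (probability 0.2), counterion-bearing
  SMILES (probability 0.1), and IC50s rounded to 3 significant figures
  (pIC50 round-trip error ≤ 0.01);
* a latent additive structure–activity signal: each molecule is one of
  6 drug-like scaffolds decorated at two positions from 12 substituents
  with fixed pIC50 contributions; rarer substituents carry the large
  contributions. Because activity is planted on *substructures*, both
  fingerprint models and image models can in principle recover it.

What it does **not** emulate: realistic chemical-space coverage,
activity cliffs, assay-dependent noise structure, censored
measurements, or inter-target correlation beyond a single tunable
mixing parameter in the two-task mode. A model that passes the
synthetic recovery tests has demonstrated that the pipeline is sound —
not that it will match benchmark accuracy on real ChEMBL extracts,
which also require GPU-scale training of unfrozen pretrained backbones.

A second generator plants additive effects (optionally single-cell
interactions) plus i.i.d. noise on a balanced factorial grid, providing
exact ground truth for the linear-model machinery.

## Study sizes and presets

The `full` preset reproduces the benchmark-scale schedule (600 epochs,
patience 250, all layers trainable). The `ci` preset is the desk-scale
profile used by the tests and the acceptance script: 200-compound
library, frozen random-weight AlexNet backbone, standard head, batch
16, at most 30 epochs, patience 10, no augmentation, lr0 = 3e-5 — the
rate selected by validation RMSE across development seeds, the same
selection protocol the grid search automates. At these sizes the whole
pipeline (rendering, feature extraction, two trainings, ensemble,
scrambling, factorial fit) completes in about a minute on one CPU; the
600-compound Random Forest experiment takes a few seconds per seed.

## Known limitations

* Without pretrained weights, unfrozen ConvNet training at 224 × 224 is
  possible but slow in this engine (per-image streaming, CPU BLAS); the
  desk-scale profile freezes the backbone instead, and the extended
  head's 38M parameters are impractical at n ≈ 200 — the standard head
  is the ci default.
* OpenBabel's ECFP bit assignment differs from other toolkits'; folded
  fingerprints are internally consistent but not bit-compatible with
  fingerprints computed elsewhere.
* The depiction style is one fixed convention; models do not transfer
  across styles, which is why the provenance hash travels with every
  image.
* Batch normalization uses per-image statistics during training (see
  above); architectures relying on cross-batch statistics may behave
  differently from other implementations when trained unfrozen.
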