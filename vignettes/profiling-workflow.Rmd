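---
title: "Methods: weakly supervised profiling, sphering, and the synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weakly supervised profiling, sphering, and the synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models and
procedures it implements, the assumptions behind them, the parameters
that matter, and the design decisions taken where the method left the
design open. The companion README shows a worked run; nothing stated
here goes beyond what the test suite and the acceptance script compute.

# The causal picture

A perturbation screen has two latent drivers of image content: the
phenotype caused by the treatment, and technical variation (batch
effects) caused by plates, well positions, optics and cell-culture
drift. Both leave traces in the pixels, and because plate maps are not
fully randomized, both correlate with the treatment label. Every stage
of the workflow is a response to that structure:

* the **pretext task** (classifying single cells into treatments)
  learns whatever image features predict treatment — phenotype *and*
  confounders;
* the two **validation splits** diagnose the mixture: leave-cells-out
  keeps every plate in training, so confounder-driven accuracy
  survives validation; leave-plates-out forces generalization to unseen
  technical conditions;
* **sphering** removes, post hoc, the feature directions that vary
  among negative controls — which, being biologically neutral, can only
  express unwanted variation.

# Weakly supervised training

Single cells are cropped in fixed windows centered on the nucleus
(128 px in production; the window is `[c − s/2, c + s/2)` in 0-based
pixel coordinates, zero-padded at borders, never resized and never
masked — context is part of the signal). Classes are balanced per epoch
at the median class size m: larger classes are subsampled without
replacement, smaller ones oversampled with replacement, resampled every
epoch. The loss is categorical cross-entropy with label smoothing 0.1;
online label smoothing optionally replaces the per-example label at
each epoch end with `L = αL_prev + (1 − α)L_pred`, α = 0.03.

Augmentation: with probability 0.5 a random sub-square of 80–100% of
the crop is resized back; independent horizontal flips and 90°
rotations; per-channel brightness/contrast jitter in which all pixels
of a channel move together, followed by per-channel min-max
renormalization. The renormalization encodes an assumption worth
stating explicitly: *brightness is meaningful relative to structure
within a channel, not absolutely*. Its corollary (discovered the hard
way and now part of the input contract, `normalize_crops()`): any
purely uniform photometric confounder — a per-channel gain or offset —
is invisible to the classifier. Train-time and inference-time inputs
are normalized identically.

Two backbones stand behind one interface. The desk-scale default
(`toy_cnn`) is a small CNN (5×5 and 3×3 convolutions, average pooling,
a 64-unit dense feature layer) trained with plain SGD, momentum 0, in
minibatches of 32; forward and backward passes are implemented with
im2col + GEMM. `efficientnet_b0` implements the B0 architecture —
compound-scaling filter rounding (divisor 8), MBConv blocks with
squeeze-and-excitation and swish — up to the block6a expansion, whose
global average pool is the 672-dimensional feature layer; the
pseudo-RGB path replicates each of the five channels to three, resizes
to 224×224, maps to [−1, 1], and concatenates five 672-vectors into
3,360 features. Because no pretrained weights ship with the package
(they are an external binary artifact), the B0 instance is randomly
initialized with a fixed seed and serves as a deterministic,
architecture-faithful feature geometry; it is forward-only and not
trainable at desk scale. Batch normalization is initialized to the
identity and folded away.

**Learning-rate note.** The production schedule (SGD, lr 0.005, 30
epochs) assumes an ImageNet-initialized backbone and millions of cells.
Training the small CNN from scratch on hundreds of cells needs a larger
step; desk-scale runs in this package use lr 0.1 explicitly. Both are
plain-SGD settings; only the magnitude differs.

# Profiling and sphering

Features aggregate median → mean → mean (cells to site, sites to well,
replicate wells to treatment); the median absorbs segmentation and
featurization outliers where data are plentiful, the mean smooths where
they are scarce. Well rows containing any NA feature are dropped before
use.

Sphering is fitted **only on negative-control well profiles**: with the
centered control matrix X (n wells × d features), Σ = XᵀX/n = UΔUᵀ and
Q = U(Δ + λ)^(−1/2)Uᵀ; every well is corrected as t′ = Q(t − μ). Two
deliberate choices:

* **Centering.** The literal second-moment formula omits mean
  subtraction; the default subtracts the control mean μ (the standard
  covariance, and the behavior of the typical-variation-normalization
  lineage), with `center = FALSE` available for the literal reading.
* **λ semantics.** λ is *added to every eigenvalue* before the inverse
  square root — not an eigenvalue floor. Corrected control covariance
  therefore has eigenvalues δᵢ/(δᵢ + λ), each in (0, 1), monotone in λ;
  λ → ∞ degenerates to uniform shrinkage λ^(−1/2)I. λ = 0 demands more
  controls than dimensions and errors otherwise. Defaults: 1e−3 for
  retrieval, 1e−2 inside the effect-score procedure.

One transform is fitted per dataset from all pooled controls; per-plate
variants are out of scope.

# Treatment effect and effect bands

Per plate: the median control profile; Euclidean distances of every
well to it; mean and standard deviation of the *control* distances
(population form, n denominator — the controls are the reference
distribution itself, not a sample of a larger one); Z-scores for
treated wells; a treatment's score is the mean Z over its replicate
wells. Plates with fewer than two control wells are skipped; a zero
control spread is an error, not a silent division. Band selection sorts
ascending (ties broken by treatment id) and takes k = round(0.2·N) from
the bottom, middle (indices ⌊(N−k)/2⌋ onward) and top.

# Retrieval evaluation

Queries are treatments whose annotation class has at least two members;
the library is every other annotated treatment, ranked by cosine
similarity (stable sort by (−similarity, id)); positives share at least
one annotation. Average precision interpolates
p_inter(r) = max_{r′≥r} p(r′) on the recall grid {j/K}; for a single
query K is its own number of positives, for mAP K is the maximum over
queries — the single biggest metric-definition choice in the package,
made so that averaging happens on one shared grid.

Folds of enrichment cuts each ranked list at k = max(1, ⌈0.01·L⌉) and
computes the cross-product odds ratio (a·d)/(b·c) of the
above/below-cut × positive/negative table, adding 0.5 to every cell
when any cell is zero (Haldane). The ranking-independent row-sum
reading of the odds ratio that a literal transcription would give is
retained behind `literal = TRUE` for reference, with one-sided Fisher
p-values recorded per query either way. The 1% threshold is applied
per query list, not globally.

# The synthetic testbed

`generate_experiment()` renders a full screen: plates × wells × sites
of 5-channel 16-bit fields. Cells are parametric blobs — a Gaussian
nucleus disc in channel 1, Gaussian annular cytoplasm rings elsewhere —
with per-cell lognormal intensity jitter and additive/multiplicative
sensor noise. This is deliberately not photorealistic: downstream
stages need statistically controllable structure, not texture realism.

**Phenotype model.** Each MoA class owns a unit direction in the
2×5-dimensional space of per-channel log-intensity and log-radius
shifts; treatments perturb their class direction slightly and scale it
by a non-negative effect size (channel c intensity × exp(effect·dᵢ),
radius × exp(0.4·effect·dᵣ)) — monotone in the effect, shared within a
MoA, which is exactly what MoA retrieval needs to be able to succeed.

**Confounder model** (two hierarchical levels, as in the screens it
imitates):

* *plate level*: per-channel multiplicative gains, a linear
  illumination gradient with random orientation, a defocus-blur base
  and a density drift (acquisition-day effects);
* *well-position level, nested within plate*: additive per-channel
  background offsets, focus jitter and density jitter.

Defocus enters as a widening of blob widths in quadrature with
amplitude renormalization; density scales the per-site Poisson cell
count. The structural components (focus, density) exist because the
photometric ones (gain, offset) are — correctly — cancelled by
per-channel contrast normalization and would otherwise leave the
pretext task with nothing technical to overfit to; real screens have
both kinds. The plate map fixes each treatment to the same well
positions across plates unless `randomize_layout = TRUE`. Every field
of view derives its RNG stream by hashing (plate, well, site) from the
master seed, so rendering is order-independent and bit-reproducible.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: segmentation error (nucleus centers are
exact), texture/granularity phenotypes, heterogeneous cell
subpopulations within a treatment, annotation noise, plate-edge
spatial autocorrelation, and cross-batch reagent drift. Results on
synthetic truth demonstrate that the machinery behaves as designed,
not that any particular real screen will reach the same numbers.

# Study conditions and problem sizes

Chosen once, as the package's desk-scale study design:

* default experiment: 3 plates × 30 wells (20 treatments at one well
  per plate + 10 control wells, mirroring high-replicate controls) ×
  3 sites, 160×160 px images, 64 px crops, ~12 cells per site, graded
  effect sizes 0.2–2.0 over 5 MoA classes, confounders
  (plate 0.3, well 0.15);
* split-gap conditions: 8 uniform strong treatments (effect 2.0),
  strong confounders (plate 0.4, well 0.2), 96 px images, 32 px crops,
  30 training epochs;
* the permutation null for folds of enrichment uses libraries of 400
  with 120 positives and a 20% cut, where the exact hypergeometric
  expectation of the Haldane-corrected odds ratio is 1.029 — close
  enough to 1 that a 10,000-shuffle mean is a meaningful calibration
  check.

Production-scale settings (1080p images, 128 px crops, hundreds of
treatments) are configuration changes, not code changes.

# Numerical conventions

* Percentiles: linear-interpolation empirical percentiles (R type 7).
* Quantization: round-half-to-even; constant images map to 0.
* Illumination surface: stored at round(0.25·H) × round(0.25·W);
  median filter window = ¼ of the downscaled dimension, Gaussian blur
  σ = window/4; rescaled so the 1st-percentile value is 1, floored
  strictly above zero.
* Crops: 0-based coordinates, x = column; half-open windows.
* Eigenvalues are clipped at zero before regularization; Q is
  symmetrized against floating-point drift.
* Ties: treatment ids break all ranking and band-selection ties.

# Known limitations

The trainable backbone is intentionally small; it demonstrates the
training dynamics (balanced epochs, augmentation, OLS, split
phenomenology) rather than state-of-the-art accuracy. The B0 path
provides exact feature geometry but random-weight features until the
user supplies compatible pretrained parameters. MIL attention pooling
is limited to bag construction (the classifier head brought no
improvement in the reference workflow and is excluded from the default
pipeline). Harmony-style clustering correction, gradient-reversal
domain adaptation, and CellProfiler feature computation are out of
scope; the package consumes such feature tables rather than producing
them.
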