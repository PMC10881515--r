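# morphopipe

Image-based morphological profiling of Cell Painting perturbation
experiments in R: from raw 5-channel microscopy images to batch-corrected
treatment profiles and retrieval-based biological evaluation.

## The problem

High-throughput Cell Painting screens image hundreds of thousands of
wells, each treated with a chemical compound or a gene-overexpression
construct, across five fluorescence channels. The scientific goal is a
*profile* per treatment — a feature vector summarizing the morphological
outcome — good enough that treatments sharing a mechanism of action
(MoA) sit close together in feature space. Two obstacles stand in the
way:

* **Weak labels.** The only label available at scale is the treatment
  applied to a well; it has no single-cell resolution and no guarantee
  of a visible phenotype. A CNN trained to classify single cells into
  treatments (the *pretext task*) nevertheless learns a useful
  morphology representation.
* **Confounders.** Plates, wells and acquisition days inject technical
  variation (illumination, focus, cell density) that correlates with
  treatment because plate maps are not fully randomized. A model — or a
  naive profile — will happily exploit it.

`morphopipe` implements the full workflow around those two ideas:

1. **Preprocessing** — per plate-channel illumination correction
   (surface fitted at 25% scale), percentile stretch (0.05/99.95),
   16→8-bit quantization (exactly 2× smaller buffers), lossless PNG.
2. **Single-cell corpus** — 128×128 (configurable) crops centered on
   nucleus locations without resizing or masking; leave-cells-out
   (~60%/40% per well) and leave-plates-out splits; balanced epochs at
   the median class size; augmentation (random crop-and-resize, flips,
   90° rotations, per-channel brightness/contrast with renormalization);
   multiple-instance bags of 16 cells (4–12 treated members).
3. **Weakly supervised training** — treatment classification with
   categorical cross-entropy, label smoothing 0.1, optional online label
   smoothing `L = αL_hard + (1−α)L_soft` (α = 0.03), plain SGD,
   minibatches of 32. A compact trainable CNN ships for CPU-scale work;
   an EfficientNet-B0 implementation provides the architecture-faithful
   feature geometry (block6a expansion = 672 channels; the pseudo-RGB
   protocol concatenates 5 × 672 = 3,360 features).
4. **Profiling** — median (cells→site), mean (sites→well), mean
   (wells→treatment) aggregation; **sphering (ZCA whitening) batch
   correction** fitted on negative-control wells only:

       Σ = XᵀX/n = UΔUᵀ,   Q = U(Δ + λ)^(−1/2)Uᵀ,   t′ = Q(t − μ)

   directions of large control variance (batch effects) are shrunk,
   directions of small variance (candidate phenotypes) amplified, with
   regularization λ (default 1e−3).
5. **Treatment effect** — per plate, Z-score the Euclidean distance of
   each treated well to the median control profile against the control
   distance distribution; a treatment's effect score is the mean Z over
   its replicate wells. Ranking treatments and taking 20% bands (weak /
   median / strong) reproduces the published band sizes (41/199/310 for
   205/995/1,550 treatments).
6. **Evaluation** — leave-one-treatment-out retrieval by cosine
   similarity against an annotated library: interpolated mean average
   precision (p_inter(r) = max_{r′≥r} p(r′) on the shared recall grid)
   and folds of enrichment (mean cross-product odds ratio of the 2×2
   table at the top 1% of each ranked list, Haldane-corrected, with
   one-sided Fisher p-values for audit).

A **synthetic experiment generator** makes all of this testable without
any download: parametric blob cells whose per-channel intensity/size
shift along MoA directions with controllable effect sizes, under
hierarchical technical confounders (plate-level gains, illumination
gradients, defocus and density drift; well-level background, focus and
density jitter), with matching metadata, nucleus locations and MoA
ground truth.

## Worked example

```r
library(morphopipe)
report <- pipeline_demo(seed = 1)
#> cells: 1100
#> mAP raw: 0.490  mAP sphered: 0.632
#> plate silhouette raw: 0.170  sphered: 0.109
```

The demo generates a 3-plate, 12-treatment synthetic screen (1,100
cells), builds well-level profiles from per-channel intensity features,
and evaluates MoA retrieval. The numbers tell the package's core story:
sphering raises mean average precision from 0.49 to 0.63 because it
suppresses the control-variance (batch) directions, and the plate
silhouette of well profiles drops from 0.17 to 0.11 — wells cluster
less by plate after correction.

Every stage is also exposed directly, e.g.:

```r
cfg    <- experiment_config(n_plates = 3, n_treatments = 20, seed = 17)
bundle <- generate_experiment(cfg)
cells  <- build_cell_index(bundle, min_cells = 0)
crops  <- load_crops(bundle, cells, crop_size = cfg$crop_size)
wells  <- aggregate_profiles(extract_baseline_features(crops), cells)
sph    <- fit_sphering(wells[wells$Metadata_Control, ], lambda = 1e-2)
scores <- effect_scores(apply_sphering(sph, wells))
strong <- select_effect_band(scores, "strong", frac = 0.2)
```

A thin command-line wrapper lives at
`inst/scripts/profile-pipeline.R` (`--demo`, or `--config run.yaml`).

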