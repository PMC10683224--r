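---
title: "The RGD fusion classifier: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The RGD fusion classifier: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Malignant lung nodules on CT tend to be more heterogeneous in texture and
more irregular in shape (spiculated margins) than benign ones. `rgdfusion`
implements a fusion classifier that scores a nodule sub-volume by combining
three complementary views of it:

1. **Hand-crafted texture radiomics** (`FR`): a volume local-binary-pattern
   histogram, a 3D histogram of oriented gradients, and gray-level
   co-occurrence statistics. These are monotone-intensity-invariant (LBP),
   orientation-summarizing (HOG) and second-order (GLCM) texture summaries
   of the kind radiologist-informed radiomics pipelines use.
2. **Learned convolutional features** (`F_i`): five small networks with
   deliberately different inductive biases — a plain convolutional stack, a
   deep 3×3 stack, residual skips, attention-masked residuals, and parallel
   multi-size filter banks — each trained end-to-end with the focal loss and
   ending in a learned projection to a common feature width so that the five
   feature vectors are dimension-aligned.
3. **Graph-fused features** (`FG`): the five feature vectors form the nodes
   of a *model graph*; the edge weight between two models is their
   *divergence*, one minus the fraction of training samples on which their
   hard predictions agree. A two-layer graph convolution with the
   symmetrically normalized self-loop propagation matrix
   `D^{-1/2}(A + I)D^{-1/2}` mixes information across models; the
   concatenated node outputs form `FG`.

One linear *fusion head* per backbone classifies `[F_i, FR, FG]`; the five
head probabilities are averaged with weights proportional to each head's
held-out accuracy. The intuition for the divergence adjacency is that a
model benefits most from exchanging information with models that behave
*differently* from it; the ablation variants (`a0` no edges, `a1` complete
graph, `as` similarity weights, `a1s` divergence weights) let this choice be
tested directly via `rgd_ablation()`.

### Assumptions

* Binary labels (malignant = positive) derived from mean radiologist
  ratings on a 1–5 scale: mean ≤ 2.75 benign, mean ≥ 3.125 malignant,
  anything between is *uncertain* and excluded. Both boundary values are
  decided in favor of the rule that names them first (2.75 → benign,
  3.125 → malignant); the source rules overlap at 2.75 and the package
  resolves the ambiguity this way consistently.
* One label per nodule volume; patients never straddle a train/test split
  (enforced at runtime with a hard failure).
* Inputs are intensity volumes; Hounsfield-unit data is windowed to
  [−1000, 400] HU (a standard lung window) before min–max scaling, data
  already in [0, 1] passes through unchanged. A constant crop normalizes to
  all zeros rather than dividing by zero.

## Preprocessing

`preprocess_volume()` resamples the through-plane axis to 1 mm (linear
interpolation), takes a zero-padded 56×56×8 crop around the nodule center,
upsamples in-plane to 128×128 with Keys cubic-convolution interpolation, and
normalizes intensities. In-plane pixel spacing is *not* resampled before the
crop (the crop is defined in voxels); radiomics is computed on the final
128×128×8 grid that the networks consume — both choices are configurable in
principle but fixed here as the package default, since the alternative
(native-resolution radiomics) changes only the descriptor scale, not the
pipeline.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `lbp_params(L, P, R)` | 1, 4, 1 | slice interval, neighbors per slice, radius (pixels). The histogram has `2^(3P+2)` = 16384 bins; no uniform-pattern reduction is applied, since `P = 4` keeps the raw pattern space tractable. `P = 4, R = 1` neighbors fall on exact grid offsets; other settings use bilinear interpolation. |
| `hog_params(cell_shape, inplane_bins, elevation_bins)` | 32×32×4, 8, 4 | cells tile 128×128×8 into 4×4×2 = 32 cells; 8 unsigned azimuth bins over `[0, π)`, 4 elevation bins over `[−π/2, π/2]`; one global L2 block normalization. The geometry is a compact default chosen once — the source method fixes none of it. |
| `glcm_params(gray_levels, z_direction_distances, inplane_distances)` | 32, (1,2,3,4), (1,2,4,8) | equal-width quantization over `[0, 1]`; all 52 (direction, distance) pairs are kept (9 through-plane directions × 4 distances + 4 in-plane × 4), with symmetric accumulation so opposite directions merge — consistent with using 13 of the 26 neighborhood directions. |
| `focal_params(alpha, gamma)` | 0.25, 2 | class-balance weight and focusing exponent. |
| `optimizer_config(lr, weight_decay, max_epochs, batch_size)` | 1e-4, 1e-4, 100, 32 | the full-scale training schedule (Adam). Tiny-scale runs override to lr 3e-3 and 20 epochs (see below). |
| `backbone_spec(feature_dim)` | 32 tiny / 256 full | width of the learned projection shared by all five families, hence the GCN node width. |
| `gcn_params()` | d → d → max(8, d/2) | two-layer widths; mirrors a 256 → 256 → 128 stack at full width. Hidden widths are not prescribed by the source method. |
| `rgd_config(val_fraction)` | 0.1 | fraction of training *patients* held out to measure the per-head accuracies that set the ensemble weights. |

## Training and numerical choices

* **Focal loss** uses the natural logarithm and clamps probabilities to
  `[1e-7, 1 − 1e-7]` for stability.
* **GCN weights are trained jointly with the heads** under the summed focal
  loss, with backbone trunks frozen. `FG` is shared by all five heads, which
  forces shared GCN weights; no separate GCN objective exists.
* **The graph topology is computed once per training fold** from the trained
  backbones' training-set predictions and reused for every sample; node
  features vary per sample. The divergence definition averages over the
  training set, so nothing per-sample is defined for `A`. The `a1s`/`as`
  diagonal is zero before the self-loop is added (divergence of a model with
  itself is zero).
* **Ensemble weights use held-out validation accuracy**, not training
  accuracy: a 10% patient-disjoint slice of each training fold. Training
  accuracies of the fused heads are typically all ≈ 1 and would degenerate
  to uniform weights.
* **AUC** follows the strict pairwise estimator (ties count 0); the
  Mann–Whitney half-credit convention is available as `tie_mode = "half"`.
  Fold aggregation is the unweighted mean across folds with the population
  standard deviation.
* **Determinism**: one global seed fans out to per-fold, per-model streams
  through an integer mixing function (`derive_seed()`), every stochastic
  step (initialization, minibatch order, fold assignment, validation split)
  draws from a derived stream, and `.Random.seed` is saved and restored
  around internal draws.
* Degenerate inputs: constant volumes yield an all-zero HOG descriptor, the
  all-ones-pattern LBP histogram and trivial GLCM matrices; a GLCM distance
  exceeding the volume extent yields an all-zero feature block with a
  warning; an all-zero adjacency normalizes to the identity propagation.

## The phantom generator

`generate_cohort(phantom_spec(...))` synthesizes 56×56×8 crops of two
classes: *benign-like* anisotropic Gaussian-blurred ellipsoids (smooth,
homogeneous) and *malignant-like* ellipsoids with radial spicules and
band-limited intra-nodular texture (default amplitude 0.3 of the intensity
range, 8 spicules), over a dim background with additive Gaussian noise
(default sd 0.02). One nodule per synthetic patient keeps patient-disjoint
splitting trivially satisfiable. Defaults were chosen once to mimic the
shape/heterogeneity cues the method targets at a separability where a single
GLCM-contrast threshold already exceeds 0.9 accuracy — the phantoms carry a
strong, clean version of the signal.

What the phantoms do **not** emulate: CT acquisition physics (beam
hardening, reconstruction kernels, slice-thickness variation), anatomy
(vessels, pleural attachment), inter-reader label noise, class imbalance,
or the hard boundary cases of real nodules. Passing tests on phantoms
therefore demonstrate that the pipeline is implemented correctly and that
fusion does not lose the signal its inputs carry — they say nothing about
clinical performance, and the published LIDC-IDRI benchmark numbers are not
reproducible at this scale.

## Problem sizes (desk scale)

The packaged defaults are sized so that the complete stack runs on one CPU
core in minutes: the `tiny` backbones pool the 128×128 plane to 16×16 at the
stem, use 2.7k–15k parameters per family, feature width 32, and train for 12
epochs at learning rate 3e-3; fusion heads and GCN take 120 full-batch Adam
steps at 0.01. With 100 phantoms per class, a full 5-fold cross-validation
(five backbones retrained per fold) finishes in a few minutes, and the
accuracy-weighted ensemble reaches 100% test accuracy while the best
individual backbone stays below it. `scale = "full"` instantiates wider and deeper
variants of the same families with the original optimizer schedule (lr 1e-4,
weight decay 1e-4, ≤ 100 epochs), but these are not exercised by the test
suite.

## Known limitations

* The backbones treat the 8 slices as input channels after the stem (planar
  convolutions); a full 3D-convolutional adaptation of each named family is
  out of scope, and the original architectures' exact 3D-ification is not
  specified anywhere authoritative.
* DICOM series ingestion is not provided (no DICOM reader is available to
  the package); NIfTI volumes and the raw-array + CSV manifest dialect are
  the supported inputs, and malignancy ratings are ingested from CSV.
* The published per-fold reference table shipped in `inst/extdata` is used
  for arithmetic consistency checks only; its fold 5 prints a precision that
  is inconsistent with its printed F1 (the F1 implies precision 92.31%, the
  printed mean implies 82.31%), and several folds recompute to within only
  ~1e-4 of the printed F1 because the printed inputs carry four significant
  digits. The package's own metrics are exact on integer counts.
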