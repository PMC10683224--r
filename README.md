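# rgdfusion

Benign–malignant lung nodule classification on chest CT by the **RGD fusion
algorithm**: **R**adiomics texture descriptors and **G**raph-convolutional
feature fusion embedded into an ensemble of **D**eep convolutional feature
extractors. The package is aimed at researchers studying multi-model feature
fusion for nodule malignancy scoring who want a complete, reproducible,
desk-scale implementation of the pipeline — including a synthetic nodule
phantom generator, so every stage can be trained, tested and ablated without
downloading a CT archive.

## The method

Each nodule is a preprocessed `128 x 128 x 8` voxel sub-volume with
intensities in `[0, 1]` (1 mm slice spacing, lung window, min–max
normalized). The classifier combines three feature families:

* **Radiomics vector `FR`** — the concatenation of
  * a *volume LBP* histogram: per voxel, a `(3P + 2)`-bit pattern
    `sum_q v_q 2^q` built from thresholded differences `B(g - g_c)`
    (`B(x) = 1` iff `x >= 0`) against the center pixels of the slices `L`
    above/below and the `P` circular neighbors at radius `R` in the three
    slices (defaults `L = 1, P = 4, R = 1`, so 16384 bins);
  * a *3D HOG* descriptor from central-difference gradients, binned by
    in-plane azimuth `theta(x,y) = atan(Gy / Gx)` and elevation
    `theta(z,xy) = atan(Gz / sqrt(Gx^2 + Gy^2))`, magnitude-weighted per
    cell and globally L2-normalized;
  * *3D GLCM* statistics (energy, entropy, contrast, homogeneity) over the
    13 unique directions of the 26-neighborhood, distances 1, 2, 3, 4 for
    through-plane directions and 1, 2, 4, 8 in-plane — 52 matrices, 208
    features.
* **Backbone features `F_i`** — five convolutional families (AlexNet-, VGG-,
  ResNet-, attention-ResNet- and GoogLeNet-style), each trained with the
  focal loss and projected to a common feature width.
* **Fused features `FG`** — a two-layer GCN
  `H^(l+1) = relu(D^(-1/2) (A + I) D^(-1/2) H^(l) W^(l))` over the 5-node
  *model graph*, whose divergence adjacency is
  `A_ij = 1 - similarity(Net_i, Net_j)` with `similarity` the fraction of
  training samples on which two models emit the same hard prediction.
  `FG` concatenates the five node outputs of the last layer. Ablation
  variants `a0` (no edges), `a1` (all-ones), `as` (similarity) and `a1s`
  (divergence, default) are provided.

One **fusion head** per backbone classifies `[F_i, FR, FG]` under the focal
loss `L = -alpha (1 - y')^gamma log(y')` for positives (and the mirrored
term for negatives; `alpha = 0.25`, `gamma = 2`); the final probability is
the accuracy-weighted average `P = sum_i W_i P_i` with
`W_i = Acc_i / sum_j Acc_j`. Evaluation uses accuracy, sensitivity,
specificity, precision, F1 and the pairwise-ranking AUC under
patient-disjoint 10-fold (configurable) cross-validation.

All numerics — including the batched im2col convolutions, the composite
residual / inception / attention blocks, backpropagation and Adam — are
implemented in base R over BLAS and validated against finite-difference
gradient checks and brute-force descriptor oracles in the test suite.

## Worked example

```r
library(rgdfusion)

cohort <- generate_cohort(phantom_spec(n_per_class = 25, seed = 0))
cv <- rgd_cv(cohort, config = rgd_config(), k = 5, seed = 1)
print(cv)
#> <rgd_cv> 5 folds, 50 samples (29.2 s)
#>   mean: acc 1.0000  sens 1.0000  spec 1.0000  prec 1.0000  F1 1.0000  AUC 1.0000
round(colMeans(cv$trunk_accuracy), 2)
#>     alexnet       vgg13    resnet34 attention56   googlenet
#>        0.56        0.52        0.50        0.50        0.50
```

The fused ensemble separates the two phantom classes perfectly while the
individual tiny backbones — trained for only a few epochs on 40 volumes per
fold — remain near chance: the radiomics and graph-fused feature blocks
carry the texture signal that distinguishes the smooth homogeneous
(benign-like) from the spiculated heterogeneous (malignant-like) phantoms.

Single fits and ablations follow the classic modelling idiom:

```r
fit <- rgd_fit(cohort, config = rgd_config(), seed = 1)
round(coef(fit), 3)              # accuracy-proportional ensemble weights
#>     alexnet       vgg13    resnet34 attention56   googlenet
#>         0.2         0.2         0.2         0.2         0.2
round(predict(fit, cohort$volumes[1:4]), 3)   # four benign training nodules
#> [1] 0 0 0 0
rgd_ablation(cohort, arms = c("cnn_1", "cnn_1+g", "rgd"),
             variants = c("a0", "a1s"), k = 2, seed = 6)
```

A thin command-line front end with `phantom`, `radiomics`, `cv` and
`ablate` subcommands is installed at `inst/cli/rgd.R`.

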