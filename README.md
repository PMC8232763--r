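# c2fseg — coarse-to-fine mandible segmentation for artifact-affected CT/CBCT

Segmenting the mandible from cone-beam CT is a prerequisite for 3D
virtual surgical planning, and it is hard precisely where it matters:
dental braces, fillings and implants throw bright/dark streaks across
the axial plane, erasing the true bone boundary, while low dose buries
the condyles in noise. `c2fseg` implements a two-stage coarse-to-fine
neural segmentation framework for this problem:

1. **Coarse stage** — a patch-based 3D SegUnet (encoder–decoder with
   U-Net skip concatenation *and* SegNet-style max-pooling index
   transfer) produces a rough whole-volume probability map
   `Ŷ₁ = UnCrop(F₁(Crop(X), θ₁))` by sliding-window inference with
   voxelwise mean fusion.
2. **Fine stage** — a recurrent 2D SegUnet walks the axial slices in
   order; step *t* maps the stack `(x_t, ŷ¹_t, ŷ²_{t−1})` — image slice,
   coarse slice, previous fine prediction — to `ŷ²_t`, so anatomical
   continuity across slices constrains each slice's decision. The full
   cascade is `Ŷ = F₂(F₁(X, θ₁), X, θ₂)`.

Both stages train separately on the compound objective
`L = ω₁·L_BCE + ω₂·L_Dice` (defaults ω₁ = ω₂ = 0.5) with Adam; the fine
stage uses truncated backpropagation through time. The package ships the
analytic loss gradient, the evaluation metrics of the field (Dice,
average symmetric surface distance, 95% Hausdorff distance, all in mm on
anisotropic grids), NIfTI IO, and a seedable synthetic phantom generator
(mandible-like arch + metallic voxels + streak artifacts) so the entire
pipeline trains and validates on one CPU with no clinical data. The
network engine — direct C++ convolutions, max pooling with recorded
argmax indices, batch norm, manual backprop, Adam, BPTT — is
self-contained.

Intended users: researchers in medical image analysis who want a fully
inspectable, dependency-light reference implementation of recurrent
coarse-to-fine segmentation, and method developers who need its
components (sliding-window tiling/fusion, compound loss with analytic
gradient, surface-distance metrics) as tested building blocks.

## Worked example

Generate an artifact-polluted phantom, inspect it, and score an
imperfect segmentation:

```r
library(c2fseg)

cfg <- PhantomConfig(shape = c(32, 64, 64), seed = 7)
ph <- generatePhantom(cfg)
ph$image
#> ImageVolume: 32 x 64 x 64 voxels (slice x row x col), spacing 1 x 0.5 x 0.5 mm
#>   intensity range: [-1479.19, 3415.33]

mean(volData(ph$label))          # foreground fraction
#> 0.069

pred <- ph$label
pred@data[12, , ] <- 0L          # damage one slice
evaluateCase(pred, ph$label)
#> MetricsReport: Dice 0.9635 | ASD 0.1324 mm | 95HD 1.4142 mm | HD 1.8028 mm
```

The intensity range shows the phantom's point: metal voxels sit at ~3000,
above the [−1000, 2000] normalization ceiling, and streaks push values
far outside the clean two-material range. Dropping one of 32 slices
costs ~3.7 Dice points, and the 95HD (1.41 mm) stays below the maximum
HD (1.80 mm) because the percentile discounts the worst boundary points.

Training and prediction at desk scale:

```r
man <- makeDataset(8, PhantomConfig(seed = 1), "data/phantoms",
                   split = rep(c("train", "test"), c(6, 2)))
coarse <- trainCoarse(man, NetworkConfig(1, 4, 2, 3),
                      TrainConfig(learningRate = 1e-3, epochs = 10,
                                  patchSize = c(16, 32, 32), seed = 101))
fine <- trainFine(man, coarse$model, NetworkConfig(3, 4, 2, 2),
                  TrainConfig(learningRate = 1e-3, epochs = 5,
                              patchSize = c(16, 32, 32), seed = 202))
cascade <- CascadeModel(coarse$model, fine$model,
                        patchSize = c(16, 32, 32), overlap = c(8, 16, 16))
mask <- predictCascade(readVolume(man$image[7]), cascade, postprocess = TRUE)
```

A command-line driver wrapping these functions is installed at
`system.file("cli", "c2fseg.R", package = "c2fseg")` with subcommands
`simulate`, `train-coarse`, `train-fine`, `predict`, `evaluate`.

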