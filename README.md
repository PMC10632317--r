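# xmpipe

Chest x-ray preprocessing, hardware-mimicking augmentation, and robustness
evaluation for binary (normal / abnormal) radiograph classification.

Radiograph classifiers trained on one x-ray machine often degrade on
another: CR plates, DR flat panels and mobile generators differ in contrast
(generator voltage), sharpness (grids, scatter) and noise (dose, detector
electronics). `xmpipe` provides:

* **Ingest** of raw stored pixel values from single-frame grayscale DICOM
  (rescale applied; display window/level deliberately ignored;
  MONOCHROME1 inverted on read) and 8/16-bit grayscale PNG, normalized to a
  matrix on [0, 1].
* **Lung-field localization** — a deterministic, contrast-invariant
  classical segmenter (percentile stretch + median-anchored power
  normalization, Otsu threshold, morphology, component selection) with a
  guaranteed fallback, plus bounding-box cropping.
* **Preprocessing**: histogram equalization (HE), contrast-limited adaptive
  histogram equalization (CLAHE), unsharp masking (UM), and an iterative
  **histogram modification** that clips outlier tails to a stable fixed
  point and then anchors the lower stretch bound at the minimum intensity
  inside the lung field, so the darkest lung pixel maps exactly to 0.
* **Augmentation**: gamma contrast (x^γ), a signed sharpness coefficient
  (s < 0 blurs, s > 0 sharpens), additive Gaussian noise, and conventional
  rotation/flip — all exact identities at (γ, s, σ) = (1, 0, 0), all
  seeded and bit-reproducible.
* **Phantom generator**: synthetic chest phantoms with ground-truth lung
  masks, nodule / consolidation lesions, and CR/DR/mobile machine profiles,
  so the whole pipeline is testable without clinical data.
* **Evaluation**: ROC AUC (Mann–Whitney, ties = ½), DeLong variance / CI /
  paired test, Fisher p-value combination, majority-class under-sampling,
  seed-shared repeated 80/20 splits, a deterministic reference classifier
  (ridge logistic on a 16×16 feature grid), and single-axis γ/s/σ
  perturbation sweeps of any scorer.

The statistic at the core of the evaluation is the pairwise AUC
θ = P(S⁺ > S⁻) + ½ P(S⁺ = S⁻), with DeLong's structural-component variance
for confidence intervals and paired comparisons, and Fisher's
X = −2 Σ ln pᵢ ~ χ²(2k) for combining p-values across repeated splits.

## Worked example

```r
library(xmpipe)

train <- generate_dataset(n = 100, abnormal_frac = 0.5, seed = 7,
                          size = 128, lesion_contrast = 0.25)
test  <- generate_dataset(n = 80,  abnormal_frac = 0.5, seed = 99,
                          size = 128, lesion_contrast = 0.25)

clf <- train_reference_classifier(train$images, train$labels,
                                  preprocess = "xm",
                                  augment = augment_params(), seed = 1)

scores <- score_images(clf, test$images)
delong_ci(test$labels, scores)
#> AUC 0.8381 (95% CI 0.7462-0.9300), n_pos=40, n_neg=40

perturbation_sweep(clf, test$images, test$labels,
                   axis = "noise", grid = c(0, 0.05, 0.1),
                   n_repeats = 5, seed = 2)
#> <sweep_result> axis noise, 3 grid points, 5 repeats
#>   grid auc_mean  ci_lo  ci_hi
#> 1 0.00   0.8381 0.8381 0.8381
#> 2 0.05   0.7685 0.7147 0.8223
#> 3 0.10   0.5705 0.5181 0.6229

fisher_combine(c(0.04, 0.01, 0.12))$p_value
#> [1] 0.00289867
```

The sweep rows read: at noise σ = 0 the model scores its clean AUC exactly
(zero-width CI, deterministic axis); adding acquisition-side noise before
the model's own preprocessing degrades AUC to 0.77 at σ = 0.05 and 0.57 at
σ = 0.1, with normal CIs over 5 fresh noise seeds.

## Command line

```sh
Rscript inst/cli/xmpipe phantom --out data --n 50 --profile CR --seed 1
Rscript inst/cli/xmpipe train --manifest data/manifest.csv --method xm --out model.json
Rscript inst/cli/xmpipe eval --manifest data/manifest.csv --model model.json
Rscript inst/cli/xmpipe sweep --manifest data/manifest.csv --model model.json \
    --axis gamma --grid 0.2,0.5,1,2,5 --out sweep.csv
Rscript inst/cli/xmpipe demo --out demo_out --seed 7 --n 200
```

`demo` generates a phantom dataset, trains the robust arm (histogram
modification + γ/s/σ augmentation) and a conventional arm (HE +
rotation/flip) on a shared split, runs all three perturbation sweeps for
both, and writes the comparison CSVs. Identical seeds give byte-identical
outputs.

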