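# glandpath

Gland segmentation and hierarchical classification for H&E colon
histopathology, in R.

A healthy colonic gland is a ring: a white central lumen, wrapped in pale
epithelial cytoplasm, bounded by a ring of purple basal nuclei, set in pink
stroma. Malignancy dismantles this architecture, and the degree of
dismantling defines tumour grade. `glandpath` operationalises that
observation for pathologists' image cohorts:

1. **Tissue clustering** — K-means (k = 3) on RGB partitions pixels into
   WHITE (lumen/cytoplasm), PINK (stroma) and PURPLE (nuclei), named by
   stain logic from the centroids, followed by disk erosion cleanup.
2. **Gland segmentation** — moment-based ellipse fitting of candidate
   components; Ward-linkage 2-cut discrimination of true glandular objects
   from stromal false positives; lumen detection; iterative dilation of the
   lumen until the nucleus ring is reached; radial-ray selection of
   boundary nuclei with outlier-nucleus removal; final dilation over the
   boundary nuclei to the complete gland region.
3. **Radiomic features** — 11 Haralick features (entropy, energy,
   correlation, inverse difference moment, inertia, sum average/entropy/
   variance, difference average/variance/entropy) of 8×8 co-occurrence
   (SGLD) matrices at offset 1 and angles {0°, 45°, 90°, 135°}; per-gland
   morphometrics (component distances, areas, size ratios, shape) for the
   5 largest + 5 smallest glands; the same texture features on random
   patch subsets.
4. **Two-level SVM ensemble** — per-family RBF SVMs produce calibrated
   probability scores (the most confident patch weak classifier is
   selected); a meta level stacks the scores into linear/RBF/sigmoid SVMs
   combined by majority vote. Grid-searched, cross-validated, leakage-free.
5. **Evaluation** — Dice/Jaccard/F-score segmentation scoring against
   ground-truth masks, accuracy/sensitivity/specificity/MCC/ROC-AUC
   classification reports, Wilcoxon–Bonferroni feature comparisons.

Because public gland-annotated cohorts are not always at hand, the package
ships a **synthetic histology phantom** (`generate_phantom()`): H&E-like
images with exact per-gland, per-component ground truth and a single
`deformation` knob (0 = ideal crypts, rising through grade presets) that
controls elongation, boundary perturbation, loss of nuclear polarity,
stromal invasion pockets and texture disorder. Every stage of the pipeline
is tested end-to-end against this ground truth.

## Worked example

```r
library(glandpath)

# a phantom image with 3 ideal glands, and one with poorly-differentiated
# architecture
normal <- generate_phantom(grade_config("normal", seed = 42))
poor   <- generate_phantom(grade_config("poor",   seed = 42))

seg <- segment_image(normal$image, segmentation_params(seed = 1))
length(seg$glands)
#> [1] 3

sc <- gland_overlap_scores(seg, normal$gland_label_mask)
round(sc$per_gland$dice, 3)
#> [1] 0.973 1.000 1.000

# texture disorder separates the grades
image_features(normal$image)[["entropy"]]
#> [1] 0.8371217
image_features(poor$image)[["entropy"]]
#> [1] 1.817406
```

Each of the three ideal glands is recovered with Dice ≥ 0.97 against
the generator's ground truth, and the whole-image co-occurrence entropy
roughly doubles from ideal to poorly-differentiated architecture — the
texture signal the image-level classifier feeds on.

A full detection experiment on a 60-image synthetic cohort:

```r
cohort <- generate_cohort(list(normal = grade_config("normal"),
                               poor   = grade_config("poor")),
                          n_per_class = 30, seed = 20260101)
bundles <- lapply(seq_along(cohort), function(i)
  extract_bundle(cohort[[i]]$image, label = cohort[[i]]$class_label, seed = i))
cv <- cross_validate(bundles, cv_scheme(10, seed = 5), positive = "poor")
cv$report
#> classification report (n = 60, classes: normal, poor)
#>   accuracy    1.0000
#>   sensitivity 1.0000
#>   specificity 1.0000
#>   mcc         1.0000
#>   auc          normal=1.0000 poor=1.0000
```

On this strongly separated synthetic cohort the stacked ensemble classifies
every held-out image correctly; permuting the labels drops it to chance,
which is the package's own negative control.

A thin command-line front end lives at `inst/cli/glandpath.R`
(subcommands `phantom`, `segment`, `crossval`).

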