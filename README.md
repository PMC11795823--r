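# deformark

Data-driven discovery of soft-tissue imaging biomarkers from 2D
deformation fields.

Given a cohort of single-slice grayscale images (one mid-sagittal slice
per subject), per-subject class labels (control vs disease) and seven
anatomical landmarks per control subject, `deformark`:

1. selects a **reference subject** by PCA of the landmark configurations
   (the medoid in the ≥ 95%-variance component subspace);
2. registers every subject to it — rigid landmark alignment centered on
   landmark 1, then **Thirion demons** non-rigid registration — yielding a
   dense per-pixel displacement field `d(x)` per subject;
3. screens every pixel with a **searchlight**: the 9×9 locale of
   deformation magnitudes (81 features) feeds a linear SVM evaluated by
   stratified 8-fold cross-validation on an 80/20-split training set,
   producing a per-pixel AUC map
   (`AUC = P(score_disease > score_control)`, the Mann–Whitney statistic);
4. thresholds the map at AUC > 0.62, then **refines** each connected
   region by dilation-to-plateau and per-pixel boundary sweeps;
5. exhaustively searches all 2^n − 1 **region combinations** for the best
   jointly-trained classifier, refits the winner and evaluates it once on
   the reserved test subjects (test AUC, ROC, Youden operating point);
6. characterizes the **morphology** of each winning region: class mean
   displacement and prominent class direction at an exemplar pixel,
   angular separation between classes, and pooled PCA explained-variance
   ratios.

Because cohorts of this kind are typically clinical and not
redistributable, the package includes a first-class synthetic-cohort
generator (`default_phantom()`, `render_cohort()`) that implants known
class-specific displacement effects at known loci, so the entire pipeline
is testable end-to-end with no external data.

## Worked example

```r
library(deformark)

run <- run_pipeline(run_config(
    out   = "demo_run",
    synth = list(phantom = default_phantom(),
                 cohort  = two_locus_cohort(seed = 1234L)),
    split_seed = 1235L, fold_seed = 1236L,
    experiment = "two-locus demo"))
print(run)
#> <pipeline_run 'two-locus demo': reference C000, 6 regions, winner {1,2,3,4},
#>  train AUC 0.986, test AUC 1.000>

print(run$auc_map)
#> <auc_map 128 x 128 (k = 9): mean 0.551, max 1.000>
print(run$morphology)
#> <morphology_summary: 4 regions, first PC 39.2% of variance>
#>   region 1 @ (88, 50): separation 170.1 deg
#>   region 2 @ (37, 76): separation 55.9 deg
#>   region 3 @ (56, 114): separation 43.9 deg
#>   region 4 @ (36, 6): separation 11.4 deg
```

Reading the output: the two largest refined regions sit on the two
implanted effect loci (ground truth at (92, 50) and (36, 76)) and their
exemplar pixels land within a few pixels of the locus centers; the
combined classifier separates the 12 reserved test subjects with test AUC
1.00 under these study conditions. The printed class separations are
measured through the registration path, which observes the
gradient-aligned component of each displacement (see the methods
vignette); validating the same discovered regions against the cohort's
retained ground-truth fields recovers the implanted 135° and 90°
separations to within 5°, as the test suite asserts. Regions 3 and 4 are
chance formations the training-time subset search retained — the reserved
test set is what guards against over-reading them. Artifacts (fields, AUC
map + heatmap PNG, region masks, ROC, morphology vectors, manifest with
checksums) are written under `demo_run/`.

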