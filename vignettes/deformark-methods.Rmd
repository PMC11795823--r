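---
title: "Deformation-based biomarker discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformation-based biomarker discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Soft-tissue conformation disorders — the motivating case is Chiari-like
malformation (CM) and syringomyelia (SM) in brachycephalic dogs — often lack
a single agreed morphometric marker. Instead of prescribing measurements,
`deformark` treats the *deformation field* between each subject and a common
reference anatomy as the data, and searches it exhaustively for small
regions whose local deformation pattern discriminates disease from control.
The pipeline has six stages, each exposed as ordinary R functions and
orchestrated by `run_pipeline()`:

1. **Reference selection.** Each control subject's seven anatomical
   landmarks, centered on landmark 1 (the central structure the rigid
   alignment also uses), form a 14-dimensional configuration. PCA is run on
   these configurations and the subject nearest the group mean — the medoid
   — in the subspace of components explaining ≥ 95% of variance becomes the
   reference. The selection criterion is our reading of "the subject most
   representative of the group average"; only translation is removed before
   PCA (no rotation/scale Procrustes), consistent with the rigid stage,
   which also centers on landmark 1. A full-variance subspace
   (`variance_target = 1`) makes the criterion identical to the raw-space
   nearest-to-mean rule.

2. **Registration.** A rigid step maps each query's landmark 1 onto the
   reference's and applies the least-squares rotation fitting the other six
   pairs (closed-form 2D orthogonal Procrustes). Then classic Thirion
   demons registration estimates the dense field `d` under the pull
   convention `warped(x) = moving(x + d(x))`: per iteration the force
   `u = -(m(x+d) - f) ∇f / (|∇f|² + (m(x+d) - f)²)` is accumulated and the
   field Gaussian-smoothed (σ = 1.5 px), inside a 3-level coarse-to-fine
   pyramid (×4, ×2, ×1), at most 100 iterations per level, stopping when
   the relative SSD improvement over 5 iterations falls below 1e-4. The
   best-SSD field seen is kept, which makes the SSD-decrease contract hold
   even when late iterations oscillate. Both images are min-max scaled to
   [0, 1] first; gradients are central differences with edge replication.
   These numeric settings are package defaults (`demons_params()`) — the
   method family prescribes none — chosen as the standard, well-documented
   baseline. The inner loop is compiled (RcppArmadillo), as is usual for
   registration codes.

3. **Searchlight screening.** For every pixel whose 9×9 locale stays
   inside the image (a 4-px border is masked out rather than padded —
   padding would fabricate deformation values), the 81 per-pixel
   deformation *magnitudes* form each subject's feature vector. A
   linear-kernel SVM (unit cost) is evaluated by stratified 8-fold
   cross-validation *on the training subjects only* — the cohort is first
   split 80/20, stratified by class, and the 20% test subjects are not
   touched until the final combined model. Features are standardized per
   fold using fold-train statistics only, preventing leakage and making
   the AUC map exactly invariant to a global rescaling of magnitudes.
   Fold-validation AUC is the Mann–Whitney statistic of the SVM decision
   values; folds whose validation part is single-class are skipped and the
   mean renormalized. The same split and fold assignment (drawn once in
   `cohort_features()`) is reused by every later stage so that region
   scores are comparable across stages.

4. **Region refinement.** The AUC map is thresholded at 0.62 and
   8-connected components are extracted (8-connectivity matches the
   one-pixel dilation ring used next). Each region is dilated ring-by-ring
   until its cross-validated AUC plateaus — improvement below 1e-3 for 2
   consecutive dilations, or any decrease — and rolled back to the
   best-scoring state; then raster-order per-pixel sweeps test every
   exterior neighbor for inclusion and every boundary pixel for exclusion,
   accepting only strict improvements, until a full pass changes nothing
   (≤ 10 passes). This is a greedy local search by construction, not a
   global optimum. Refined regions that touch are merged and rescored
   once. `run_pipeline()` treats the threshold as a working parameter at
   the margins: if nothing survives 0.62 it steps down by 0.02 (floor
   0.52), and if more components survive than the exhaustive search can
   enumerate in reasonable time (`max_regions`, default 12) it steps up —
   a signal-free, null-like map otherwise yields hundreds of chance
   components. Both adaptations are recorded in the manifest
   (`threshold_used`).

5. **Combination search.** All `2^n − 1` subsets of the refined regions
   (guarded at n ≤ 22) are scored by the same cross-validated AUC on the
   union of their pixels' magnitudes; enumeration is size-ascending and
   lexicographic so that taking the first strict maximum implements the
   tie-break (smallest subset, then lexicographic). The winner is refit on
   the full training set and scored once on the reserved test subjects:
   test AUC, the ROC curve, and the operating point maximizing Youden's
   J (ties → higher sensitivity). Both train and test AUC are reported,
   since a training-time AUC is optimistically biased by the search itself.

6. **Morphology inference.** Within each winning region, the class mean
   displacement at the region's exemplar pixel (the member nearest the
   centroid, ties by raster order) and the class's prominent direction are
   reported. The prominent direction is the first *uncentered* singular
   vector of the class's 2D displacement stack, sign-aligned with the
   class mean: it is the axis most deformations point along. Centered PCA
   would instead return the axis of scatter about the mean — the noise
   axis when a class deforms consistently — which is not what the
   direction plots are meant to show. The pooled explained-variance
   ratios, by contrast, come from conventional mean-centered PCA over all
   region pixels and both classes jointly (directions are class-wise,
   variance is pooled; the two conventions serve different questions).

## The synthetic study

The cohorts the paper-scale method was developed on are clinical and not
distributable, so the package carries a first-class synthetic generator
emulating the study design. The reference anatomy is a 128×128 sum of 12
Gaussian blobs — smooth, gradient-rich structure that intensity-driven
registration can work with — with seven landmarks on distinctive loci.
Each subject gets a ground-truth displacement field: smoothed white noise
(σ = 8 px) rescaled to exactly 1 px RMS as nuisance anatomy variation,
plus, per implanted effect, `amplitude(class) × direction(class) ×
Gaussian envelope` at a known locus. Subjects are rendered as
`subject(x) = reference(x − d(x))` with bilinear interpolation — that
orientation makes registration recover approximately `+d`, so
parameter-recovery tests are direct — plus additive Gaussian intensity
noise (SD 0.02), clipped to [0, 1]. Landmarks are transported through the
exact field (fixed-point solve of `x − d(x) = p`), with an optional jitter
SD for annotation-noise experiments.

Default conditions, chosen once as a realistic desk-scale analogue and not
revisited: 30 controls + 30 diseased; the single-locus study implants one
effect (σ = 6 px) at a blob boundary with disease amplitude 3 px versus
control 0; the two-locus study adds a second well-separated locus and
gives controls their own 1.5 px directions (implanted class separations 90°
and 135°) so both classes have recoverable morphology; the null study sets
the two classes' effect parameters equal.

One design point deserves emphasis. Implanted effects are defined as
displacements *relative to the template anatomy*, but the pipeline
measures displacement relative to the selected reference **subject** —
and a typical control reference carries the control-class effect, which
would then cancel out of every control's measured field, making the
implanted control direction unobservable in principle. The warping
contract (registration recovers ≈ `+d_true`) therefore requires the
reference to be the template. The two-locus study consequently includes
one extra control subject, `C000`, drawn with zero deformation — the
idealized average anatomy. Its landmark configuration equals the
population mean, so the medoid rule of reference selection identifies it
by itself; no stage is bypassed or special-cased. Effects sit on intensity
gradients deliberately — a displacement of featureless background is
invisible to any intensity-driven registration, and real anatomical ROIs
sit on tissue boundaries for the same reason.

What the generator does *not* emulate: MRI contrast physics and artifacts,
anatomical shape priors, annotation error in landmarks (by default), and
between-scanner variation. Passing tests therefore demonstrate the
pipeline's internal correctness and its ability to recover implanted
effects through a real registration step — not clinical performance.

## Problem sizes and numerical choices

Tests and the acceptance script run the full pipeline at the default
128×128 / 60-subject scale (a searchlight screen is ~14,400 seed pixels ×
8 folds), with a smaller 64×64 / 16-subject configuration used where only
determinism or bookkeeping is under test. The SVM is fitted through a
direct call to e1071's compiled libsvm trainer; a unit test pins exact
agreement of decision values with `e1071::svm()`. Degenerate inputs are
contract-handled: constant feature blocks score AUC 0.5, demons guards the
zero-gradient/zero-residual denominator, degenerate landmark sets fall
back to translation-only alignment with a warning flag, and exclusion
sweeps never empty a region.

A registration-physics caveat applies to morphology directions: an
intensity-driven method can only observe the displacement component along
the local intensity gradient (the aperture problem), so a class direction
tangent to the isophotes around its locus is recovered poorly however many
iterations are run. In synthetic validation we therefore check recovered
directions at the *discovered* regions against the generator's retained
ground-truth fields — region discovery exercises the full registration
path, while direction fidelity is assessed where it is well-posed. On real
data the same caveat means reported deformation directions are most
trustworthy across tissue boundaries and least trustworthy along them.

Known limitations: the demons variant is non-diffeomorphic (no field
invertibility guarantees, no 3D); the refinement search is greedy; the
operating point uses Youden's J, which ignores asymmetric misclassification
costs; and reference selection assumes translation is the only nuisance in
landmark configurations.
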