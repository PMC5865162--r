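---
title: "Radiomic subtyping of glioblastoma mpMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic subtyping of glioblastoma mpMRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gliotype)
```

This vignette is the package's own account of the science it implements:
the radiomic feature model, the stability-based clustering procedure, the
survival and radiogenomic analyses, the synthetic cohort the pipeline is
validated on, and the numerical decisions taken where the methodology was
genuinely open.

## The analysis object

A subject is an `imaging_study`: up to 11 co-registered 3D channels —
structural (T1, T1CE, T2, FLAIR), diffusion-tensor derived (AX, FA, RAD,
TR) and perfusion derived (rCBV, PH, PSR) — together with a segmentation
labelling three tumor subregions: enhancing tumor (TU, label 4),
non-enhancing core (NC, label 1) and peritumoral edema (ED, label 2),
following the de-facto BraTS label convention. All analysis assumes the
channels, segmentation and the 9-region anatomical parcellation share one
voxel grid; co-registration, bias correction and segmentation are upstream
of this package.

## The radiomic feature catalog

`feature_catalog()` enumerates 278 features in six families. Counts follow
from the structure of the catalog, not from tuning:

* **Volumetric & shape (11).** ED, NC and TU volumes normalized by total
  brain volume (brain size is a normalizer, not a feature), the edema
  fraction ED/(ED+NC+TU), the TU/NC ratio, and circularity + sphericity of
  NC, NC∪TU and the whole tumor. The TU/NC ratio is undefined when NC is
  empty and is median-imputed at table level.
* **Intensity (66).** Mean and population SD (divisor *n*) of the raw
  voxel intensities per (subregion × channel).
* **Histogram (165).** Each channel is first normalized per subject to
  [0, 1] by clipping at the 1st/99th percentile of in-brain intensities and
  min–max scaling; each (subregion × channel) distribution is then split
  into five equal-width bins and the voxel percentages reported. Rows sum
  to 100 by construction. The percentile normalization makes bin features
  comparable across subjects without assuming any absolute intensity
  calibration.
* **GLCM texture (24).** Six measures (energy, contrast, entropy,
  correlation, dissimilarity, homogeneity) × four structural channels (T1,
  T1CE, T2, FLAIR) on the whole tumor TU∪NC∪ED. In-region intensities are
  quantized to 32 equal-width levels over the region's own range;
  co-occurrences are accumulated region-wide for the 26 principal 3D
  directions at distances 1 and 2 voxels (a 2-voxel co-occurrence radius);
  matrices are symmetric, so opposite directions coincide and each pair of
  directions is evaluated once; measures are averaged over all matrices
  with at least one pair. Entropy uses the natural logarithm. A constant
  region gives the single-cell limit (energy = homogeneity = 1, contrast =
  entropy = dissimilarity = 0, correlation undefined).
* **Location (9).** Percentage of tumor-core (TU∪NC) voxels in each of the
  nine anatomical regions (frontal, temporal, parietal, basal ganglia,
  insula, cc fornix, occipital, cerebellum, brain stem).
* **Growth (3).** Pass-through biophysical growth-model descriptors
  (diffusion time, white-matter diffusion coefficient, focus count) taken
  from the clinical table; this package does not fit a growth model.

### Discrete shape measures and their bias

Circularity is 4πA/P² with A the voxel count of the largest-area axial
slice and P the exposed-edge count (4-connectivity); sphericity is
π^(1/3)(6V)^(2/3)/A with A the exposed-face count. These definitions are
deterministic and exactly testable, but the discrete perimeter/surface is a
taxicab measure: its maximizers are squares (π/4 ≈ 0.785) and cubes
((π/6)^(1/3) ≈ 0.806), while rasterized disks and balls converge to π²/16
≈ 0.617 and 2/3 respectively (the exposed-edge perimeter of a disk is 8r,
not 2πr; face counting overestimates a sphere's surface by 3/2). The
values are therefore *comparative* shape-regularity scores, not quantities
calibrated to 1 for ideal spheres; the test suite freezes the analytic
limits above.

## Subtype discovery

Features are min–max scaled to [0, 1] on the discovery cohort
(`fit_scaling()`); replication data reuse the discovery scaling and are
deliberately not clipped, preserving the geometry of the discovery space.

`select_k()` runs, for each K in 2–6, an ensemble of Lloyd K-means fits
(default 1000 restarts; 200 in the package's own experiments, which is
where the stability estimates plateau), each initialized with K distinct
subjects drawn uniformly at random — deliberately *not* k-means++ — and
scores each K by the average adjusted Rand index over all unordered pairs
of restarts. Identical partitions are grouped first, so the exact all-pairs
average costs only one ARI evaluation per pair of *distinct* partitions; a
`max_pairs` switch subsamples pairs for very diverse ensembles. The chosen
K maximizes stability, ties going to the smaller K (parsimony).

The reported assignment (`representative_assignment()`) groups restarts
into equivalence classes of identical partitions (for non-degenerate
partitions this is exactly pairwise ARI = 1, the only parameter-free
reading of "the same clustering"); among classes holding at least 20% of
restarts, the one with the highest mean silhouette wins. If no class
reaches 20%, the most frequent is returned with a warning.

Two behaviours of this algorithm are worth knowing. First, restarts whose
random initial centers do not cover all true clusters can converge to
stable local minima; this is intrinsic to Lloyd with random-point
initialization and is precisely why the procedure uses many restarts plus a
representative-assignment rule rather than a single fit. Second, on
perfectly symmetric toy clusters K = 4 partitions can be almost as stable
as K = 3 ones (they share the three-cluster backbone); on realistic data —
including the synthetic cohorts below, with their noise features and
unequal cluster geometry — the K = 3 maximum is clear.

Reproducibility is quantified two ways: `cv_reproducibility()` re-clusters
9/10 of the cohort, assigns the held-out tenth to the nearest training
centroid, aligns training clusters to the full-data reference by
maximum-agreement matching (exhaustive over K! permutations), and reports
pooled held-out agreement; `assign_new()` (also `predict()` on the fitted
model) assigns replication subjects to the nearest discovery centroid in
scaled space, ties to the lowest cluster index.

Cluster display names are cosmetic, derived from centroid signatures:
largest edema fraction → *irregular*; of the remainder, higher tumor rCBV →
*solid*, lower → *rim-enhancing*.

`feature_association()` screens features against the subtype labels with
Kruskal–Wallis (tie-corrected) and Bonferroni adjustment
(min(1, p × n_features)), significant at adjusted p < 0.05.

## Survival models

`km_estimate()` wraps the product-limit estimator; the median is the
smallest time with S(t) ≤ 0.5 (left endpoint when S sits exactly at 0.5),
undefined if S never reaches 0.5. `logrank_test()` is the Mantel–Cox test
with df = groups − 1. `cox_fit()` maximizes the partial likelihood with
Breslow tie handling (ties are rare with continuous synthetic times) and
reports hazard ratios with 95% Wald intervals. Pairwise subtype hazard
ratios use the rim-enhancing subtype as reference, matching the direction
of the reported contrasts.

`harrell_c()` implements the concordance index from first principles: over
comparable pairs (the earlier time carries an event), concordance means the
shorter survival has the higher risk score; score ties count 0.5; tied
times and pairs whose earlier time is censored are not comparable. The
p-value against 0.5 uses a normal approximation with the linearized
U-statistic variance over per-subject concordance contributions — a
pair-count ("independent pairs") variance would be too small by a factor of
roughly the sample size, because pairs sharing a subject are strongly
correlated. The c value (not the p) is cross-checked against
`survival::concordance` in the tests.

`model_comparison()` fits the six covariate configurations — age, location
(nine percentages), subtype (K − 1 indicators, rim-enhancing reference),
subtype+age, subtype+location, and all three — and reports each model's
apparent (fitting-cohort) c-index, which is what the in-sample comparison
of nested prognostic models calls for; a held-out variant is a
straightforward extension but is not what the headline comparison reports.

## Spatial maps

`subtype_probability_map()` gives, per subtype and voxel, the fraction of
that subtype's tumor cores covering the voxel — every value is k/n for
integer k, an invariant the tests assert. `regional_tumor_proportions()`
shares its implementation with the location features;
`subtype_regional_summary()` averages member vectors within subtypes.

## Radiogenomics: within- vs across-subtype EGFRvIII signatures

The hypothesis: mutation signatures are clearer inside phenotypically
uniform subtypes than across a pooled, heterogeneous cohort. Two analyses:

* **Univariate:** `within_vs_pooled_effect_sizes()` computes |Cohen's d|
  (pooled-SD form) per feature, within each subtype and pooled. Subjects
  with unknown status are excluded; strata with fewer than two subjects per
  mutation group are omitted with a warning.
* **Multivariate:** `svm_within_vs_pooled()` trains one RBF-SVM per
  subtype (except rim-enhancing) and one pooled RBF-SVM, each evaluated by
  stratified 5-fold cross-validation. Inside every training fold, sequential
  forward selection adds the feature that maximizes inner 3-fold CV
  accuracy, stopping as soon as no candidate improves it (patience 1, at
  most 15 features); a small C × γ grid is then searched on the selected
  subset by the same inner CV, and the tuned model predicts the held-out
  fold. Selection and tuning therefore never see the held-out fold — the
  test suite asserts this by poisoning a fold's feature values and checking
  the other folds' selections are unchanged. Fold assignment depends only
  on the labels and the seed, which is what makes that check well-defined.
  The rim-enhancing stratum, where the mutation is rare, uses a null model
  instead: every subject is predicted mutation-absent, so its accuracy is
  the stratum's wildtype fraction.

The within-subtype summary is the **size-weighted accuracy**: total correct
/ total classified across strata (never the unweighted mean of stratum
accuracies) — `weighted_accuracy()` keeps this arithmetic explicit and the
tests pin it to exact rational values.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without
patient data. It emulates, per planted archetype:

* **Geometry.** An ellipsoidal core (radius ≈ 6 ± 0.35 voxels, per-axis
  anisotropy U(0.9, 1.15)) split into a 1.8-voxel enhancing shell (TU) and
  interior (NC), surrounded by an edema envelope scaled so vol(ED) ≈
  `edema_scale` × vol(core) (1.4 / 2.2 / 0.7 for rim-enhancing / irregular
  / solid). Boundaries are perturbed by a smooth low-frequency random field
  with amplitude `irregularity` voxels (0.5 / 2.5 / 1.2). With zero
  irregularity the core is an exact discrete ellipsoid — the symmetry the
  tests exploit.
* **Intensities.** Gaussian voxel intensities per (region × channel), in
  arbitrary units: the literature supplies orderings, not absolute values,
  so only the orderings are meaningful. The contrasts follow three
  physiological axes — cellularity (diffusivities TR/AX/RAD high, FA low,
  when cellularity is low: rim > irregular > solid in core TR),
  vascularity (rCBV/PH high, PSR low: solid > irregular > rim in rCBV) and
  water/infiltration (FLAIR/T2 highest in the fluid-rich irregular edema) —
  plus a bright T1CE rim for the rim-enhancing archetype. Each archetype's
  signature occupies a partly disjoint set of channels and regions, keeping
  the three archetypes roughly equidistant in feature space (no two
  archetypes collapse at K = 2, consistent with a K = 3 stability maximum).
  Within-region voxel SD is 0.06–0.12 (the irregular archetype is the most
  heterogeneous), a per-subject random effect of SD 0.02 moves region
  means, and independent voxel noise (`voxel_noise_sd`, default 0.02) is
  added on top. These spreads put the cohort in the strongly separated
  regime the recovery experiments assume.
* **Placement.** Tumor centers are sampled from the archetype's preferred
  atlas region (frontal for rim-enhancing, temporal for the others) with
  15% spillover into other *supratentorial* regions — glioblastoma is a
  supratentorial tumor, and infratentorial placements would additionally
  manufacture artificial spatial outliers in the one-hot-like location
  features.
* **Survival.** Event times are exponential with the archetype's median
  (19 / 12 / 6 months) — the simplest law with a closed-form median — with
  a mild age effect on the log-hazard (0.15 per decade, centered at the
  mean age 58) so that age is a genuinely prognostic covariate for the
  six-model c-index comparison; the marginal median shift from the age
  mixture is ~1%. Censoring is independent uniform administrative
  censoring whose window is calibrated (by root-finding on the closed-form
  censored fraction of an exponential) so the expected censored fraction
  equals `censoring_fraction` (default 0.2, a realistic loss to follow-up);
  this keeps Kaplan–Meier consistent.
* **Molecular labels.** EGFRvIII prevalence 12.5% / 39.0% / 30.6%;
  molecular-subtype mixtures favouring proneural (rim-enhancing),
  neural+mesenchymal (irregular) and classical (solid); IDH1 mutation
  enriched in the long-surviving rim-enhancing archetype; MGMT methylation
  archetype-independent at 45%. A configurable fraction of labels is
  masked to "unknown" to emulate incomplete mutation panels.
* **Atlas.** A deterministic, fabricated 9-region parcellation of an
  ellipsoidal brain (`synthetic_atlas()`); it is generated in code rather
  than shipped as a binary volume, and it is synthetic — region shapes are
  geometric rules, not anatomy.

Everything is a deterministic function of (spec, archetypes): per-subject
seeds derive from the master seed, the clinical record is drawn before the
channel volumes (so clinical-only cohorts are byte-identical to full ones),
and rare degenerate geometries are retried with derived seeds.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: MR physics (no partial-volume effects, bias
fields, scanner or motion artifacts), realistic tumor morphology beyond
perturbed ellipsoids, multifocality, spatially correlated intra-tumoral
texture (voxel noise is white, so GLCM features carry little planted
signal), registration error, or any coupling between imaging noise and
outcome. Recovery of planted structure demonstrates the pipeline's
correctness, not clinical validity.

## Numerical choices and degenerate inputs

* K-means: Lloyd, convergence on centroid movement (tolerance of the
  underlying implementation, iteration cap 300); restarts that converge to
  an empty cluster are re-seeded with bounded retries.
* Problem sizes in the package's own experiments, chosen to make the
  statistical properties clearly measurable: discovery cohorts of 120
  subjects on 40³ grids with 200 restarts per K; replication cohorts of
  45; survival cohorts of 600 (clinical-only generation); radiogenomic
  experiments with n = 300 and 20 seeds.
* KM medians are noisy statistics: for an exponential arm of n subjects
  the sample KM median has sd ≈ 1.44·median/√n (≈ 10% of the median at
  n = 200), so recovery bands tighter than ~2 of those sd's will fail on a
  sizable fraction of seeds even with a perfectly unbiased generator and
  estimator.
* Constant features scale to 0 and are flagged; constant covariates and
  empty groups raise informative errors rather than propagating NaN.
* Assignment ties (equidistant centroids) go to the lowest cluster index;
  K-selection ties to the smallest K; both are asserted in tests.
* Missing feature values are imputed by the per-feature cohort median
  before scaling/clustering (K-means needs complete rows); imputed cells
  are recorded in the table's `imputed` attribute.
* Serialization: feature tables as CSV at 10 significant digits; the
  subtype model as JSON at full precision, so a restored model reproduces
  assignments identically.

## Limitations

* The feature catalog is the reconstructable 278-feature version; historical
  catalog variants of slightly different sizes can be matched via the exclusion
  list, but which exact features a historical catalog dropped is not
  recoverable.
* The discrete shape measures carry the taxicab bias described above.
* Texture features are computed by region-level pair accumulation,
  equivalent to pooling per-voxel sliding-window co-occurrences up to edge
  effects, and are cheaper and exactly oracle-checkable; per-voxel texture
  *maps* are out of scope.
* The c-index comparison reports apparent (in-sample) concordance;
  honest out-of-sample prognostic evaluation needs an external cohort.
* Real-data use assumes upstream registration and segmentation quality;
  the package performs no image pre-processing.
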