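# gliotype

Radiomic subtype discovery for glioblastoma multi-parametric MRI (mpMRI).

Glioblastoma is strikingly heterogeneous across patients, and that
heterogeneity is visible in imaging: cell density in diffusion measures,
neovascularization in perfusion measures, infiltration in FLAIR/T2 signal,
and tumor shape and location. `gliotype` implements an end-to-end,
data-driven pipeline that turns co-registered mpMRI of segmented tumors into
quantitative imaging subtypes and characterizes what those subtypes mean
clinically and molecularly:

1. **Radiomic feature extraction** — a fixed 278-feature catalog per subject
   over the three segmented subregions (enhancing tumor TU, non-enhancing
   core NC, peritumoral edema ED) and 11 channels (T1, T1CE, T2, FLAIR, AX,
   FA, RAD, TR, rCBV, PH, PSR): volumetric & shape (11), intensity mean/SD
   (66), five-bin histogram percentages (165), GLCM texture (24: energy,
   contrast, entropy, correlation, dissimilarity, homogeneity averaged over
   the 26 principal 3D directions at distances 1–2 on 32 gray levels),
   atlas-region location (9) and biophysical growth pass-through features (3).
2. **Stability-selected clustering** — features scaled to [0, 1]; K-means
   (Lloyd, random-subject initialization) repeated many times per candidate
   K; K chosen by the maximum average pairwise adjusted Rand index (ARI)
   across restarts; the reported assignment is the partition with the
   highest silhouette among those recurring in ≥ 20% of restarts.
3. **Replication & reproducibility** — 10-fold held-out assignment
   agreement, and nearest-centroid assignment of new cohorts under the
   discovery scaling.
4. **Survival analysis** — Kaplan–Meier curves and medians per subtype,
   log-rank, pairwise Cox hazard ratios, and Harrell c-index comparison of
   six Cox covariate configurations (age | location | subtype | pairwise and
   joint combinations).
5. **Spatial maps** — voxelwise lesion frequency maps per subtype and
   9-region tumor proportions.
6. **Radiogenomics** — within-subtype vs pooled RBF-SVM classification of
   EGFRvIII mutation status with nested cross-validated sequential forward
   feature selection, a mutation-absent null model for the low-prevalence
   rim-enhancing subtype, and size-weighted accuracy aggregation
   (total correct / total n).

Because clinical mpMRI cohorts cannot be redistributed, the package ships a
**synthetic cohort generator**: three planted imaging archetypes
(`rim_enhancing`, `irregular`, `solid`) with archetype-specific intensity
contrasts, edema size, boundary irregularity, survival medians (19 / 12 / 6
months), EGFRvIII prevalences (12.5% / 39.0% / 30.6%), molecular-subtype
mixtures and preferred anatomical locations. Every stage of the pipeline is
tested against this generator and against brute-force oracles.

## Worked example

```r
library(gliotype)

# simulate a 60-subject cohort of 40^3 mpMRI studies
spec   <- cohort_spec(n_subjects = 60, volume_shape = c(40, 40, 40),
                      random_seed = 42)
cohort <- generate_cohort(spec)

# extract the 278-feature radiomic table and discover subtypes
features <- extract_feature_table(cohort)
model    <- discover_subtypes(features, k_range = 2:6, n_runs = 200,
                              seed = 42)
print(model)
```

```
Imaging subtype model: K = 3 (60 subjects, 278 features)
stability (average pairwise ARI) by K:
 K average_ari
 2   0.6250253
 3   0.7183420
 4   0.7014860
 5   0.5932455
 6   0.5647113
representative assignment: silhouette 0.530, frequency 61.5%
cluster sizes:
rim_enhancing     irregular         solid 
           26            13            21 
```

K = 3 maximizes restart-to-restart stability (average pairwise ARI 0.72);
the winning assignment recurred in 61.5% of the 200 restarts, and the
clusters are named from their centroid signatures (largest edema fraction →
irregular; of the rest, higher tumor rCBV → solid). Here the assignment
matches the generator's planted archetypes exactly
(`adjusted_rand_index(model$labels, cohort$clinical$truth_archetype)` is 1).

Survival separation of the subtypes, on a larger clinical-only cohort
(`generate_cohort(..., channels = FALSE)` skips the image volumes):

```r
sco <- generate_cohort(cohort_spec(600, volume_shape = c(40, 40, 40),
                                   random_seed = 42), channels = FALSE)
rec <- sco$clinical
rec$time <- rec$survival_months
rec$subtype <- rec$truth_archetype
sv <- subtype_survival(rec)
round(sv$medians, 1)
sv$pairwise_hr
```

```
    irregular rim_enhancing         solid 
         12.4          19.0           5.7 
      reference    comparison   hr ci_lower ci_upper       p
1     irregular rim_enhancing 0.67     0.53     0.84 5.3e-04
2     irregular         solid 2.02     1.60     2.55 3.8e-09
3 rim_enhancing         solid 3.12     2.42     4.03 1.5e-18
```

The Kaplan–Meier medians recover the planted 19 / 12 / 6 months and the
hazard ordering (solid worst, rim-enhancing best). New subjects are assigned
with `predict(model, new_features)`; `run_pipeline()` orchestrates all
stages and writes every artifact (CSV/JSON/NIfTI) to a directory, and
`inst/cli/gliotype.R` exposes the same stages as a command line.

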