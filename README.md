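# rvshape

Particle-based statistical shape analysis of the right ventricle (RV) in
tricuspid regurgitation (TR), for researchers studying how TR remodels RV
geometry from cardiac MRI segmentations — and for anyone who needs a fully
testable statistical-shape-modelling pipeline with known ground truth.

TR is retrograde flow through an incompetent tricuspid valve; the RV
responds with a characteristic constellation of shape changes (free-wall
bulging, basal widening, apical blunting) that volumetric indices summarize
poorly. `rvshape` analyses this point-wise. Its core objects and methods:

- **Correspondence particles**: M ordered landmarks (default 512) placed on
  every subject's endocardial surface so index *j* is the anatomically
  analogous location cohort-wide, optimized on signed distance transforms by
  gradient descent on
  `α·logdet(cov(z₁…z_K) + εI) + (1−α)·Σ_k Σ_i log Σ_{j≠i} exp(−|p_i−p_j|²/2σ_i²)`
  (ensemble compactness vs per-shape uniform sampling), with a 1→2→…→M
  particle-splitting schedule.
- **PCA shape space** over the flattened K×3M correspondence matrix, with
  per-subject loading vectors s_i and the mode count explaining 99% of
  variance.
- **TR classification** from loadings: stratified 80/20 split,
  Borderline-SMOTE balancing of the minority groups, lasso stability
  selection (dominance probability = fraction of 1000 resampled
  intercept-free L1 fits in which a mode's weight is non-zero), top-4 modes
  into a CV-tuned logistic model, metrics from the confusion matrix
  (`accuracy = (TN+TP)/(TN+TP+FN+FP)`, `precision = TP/(TP+FP)`,
  `recall = TP/(TP+FN)`, `F1 = 2PR/(P+R)`), ROC/AUC.
- **Linear discrimination of variation (LDV)**: each shape projected onto
  the difference of two group mean shapes, affinely normalized so the group
  means map to −1 (TR) and +1 (non-TR); Gaussian densities fitted per group.
- **Per-point Hotelling T² significance maps**:
  `T² = (n₁n₂/(n₁+n₂)) (x̄₁−x̄₂)ᵀ S⁻¹ (x̄₁−x̄₂)` per correspondence point,
  p-values via the F(3, n₁+n₂−4) transform, Benjamini–Hochberg FDR at 0.05.
- **A synthetic RV cohort generator** (star-shaped radial surfaces with
  group deformations, smooth spherical-harmonic shape noise and rigid pose
  jitter, voxelized to binary masks) that makes every stage testable against
  exact ground truth. See the methods vignette
  (`vignettes/rv-shape-analysis.Rmd`) for the model and all design choices.

## Worked example

Generate the default 54-subject synthetic cohort (6 healthy / 27 comorbid
controls / 21 TR), build the shape space from ground-truth correspondence,
classify TR, and map group differences:

```r
library(rvshape)

coh <- generate_cohort(cohort_spec(seed = 1), voxelize_masks = FALSE)
#> <rv_cohort> 54 subjects (control=27, healthy=6, tr=21), surfaces only

particles <- attach_ground_truth(coh, M = 128)
pca <- fit_pca(shape_matrix(particles, coh$manifest))
glance(pca)
#> # A tibble: 1 × 5
#>   n_shapes n_coords n_modes total_variance n_modes_99
#>      <int>    <int>   <int>          <dbl>      <int>
#> 1       54      384      53           559.         33

loadings <- pca_loadings(pca, n_modes = num_modes_for_variance(pca, 0.99))
cls <- classify_pipeline(loadings, n_repeats = 200, seed = 1)
cls$modes
#> [1] 1 3 4 2
cls$report
#> <rv_report> n=11  TN=7 FP=0 FN=0 TP=4
#>   accuracy 1.000  precision 1.000  recall 1.000  F1 1.000  AUC 1.000

sig <- hotelling_map(particles, coh$manifest, "control", "tr")
sum(sig$significant)
#> [1] 87
```

33 modes carry 99% of the shape variance; lasso stability selection picks
the four dominant modes (mode 1 is the TR free-wall/base/apex pattern), and
the held-out test set of 11 subjects is classified perfectly — the synthetic
effect size (5 mm bulge over 1 mm shape noise) is deliberately strong. 87 of
128 correspondence points differ significantly between controls and TR
after FDR correction, concentrated on the free-wall patch.

The LDV shape score for the CHF subgroup, with group means pinned at ±1:

```r
chf <- coh$manifest$subgroup == "chf"
sub <- new_particle_system(particles$points[chf, , ], coh$manifest$subject_id[chf])
ldv <- ldv_scores(shape_matrix(sub, coh$manifest[chf, ]), "tr", "control")
ldv
#> <rv_ldv> tr -> -1, control -> +1; 21 subjects scored
#> # A tibble: 2 × 4
#>   group    mean    sd     n
#>   <chr>   <dbl> <dbl> <int>
#> 1 control     1 0.268    12
#> 2 tr         -1 0.242     9
overlap_fraction(ldv)
#> [1] 0
```

Each result type has `tidy()`/`glance()` accessors and an `autoplot()`
method (scree, dominance bars, ROC, score densities, significance maps).
`run_pipeline(pipeline_config(...), outdir)` orchestrates everything from
one config (YAML-serializable) and writes all artifacts with a run
manifest; `exec/rvshape` is a thin command-line wrapper
(`rvshape run --config config.yaml --out results/`). Setting
`use_ground_truth_correspondence = FALSE` runs the full
`preprocess_masks()` → `optimize_particles()` path instead of the
generator's exact correspondence.

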