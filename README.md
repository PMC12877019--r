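# miftiles

Tile-based spatial analysis of multiplex immunofluorescence (mIF) for
predicting response to anti-PD-1 immune checkpoint blockade (ICB).

## The problem

Pre-treatment tumor biopsies imaged with an 8-marker mIF panel yield, after
segmentation and thresholding, a table of cells per slide: a centroid in
microns and a binary positivity call for each marker (for the lymphoid
panel: iNOS, CD20, PD-L1, LAG-3, CD8, nNOS, SOX10, CD3). The question is
whether the *composition* and *spatial organisation* of the tumor
microenvironment in these tables predicts which melanoma patients will
respond to anti-PD-1 therapy. `miftiles` implements that analysis end to
end for researchers working with per-cell mIF (or similar spatial
single-cell) exports:

1. **Ingestion** — per-slide CSV/Parquet cell tables are normalised to
   micron coordinates (`read_cell_table()`, pixel inputs scaled by the
   image resolution, default 0.4992 µm/px).
2. **Tiling** — each slide is partitioned into 1 mm × 1 mm tiles by cell
   centroid; tiles with fewer than 100 cells are dropped
   (`build_tiles()`). Tiles are the unit of every downstream feature.
3. **Cell states** — the catalog of cell states is the top-20 exact marker
   combinations pooled over all slides, plus singleton states for the
   remaining markers, plus the all-negative "Stromal" state
   (`enumerate_states()`). Membership is by superset: a CD3+CD8+ cell
   counts in the CD3, CD8 and CD8+CD3 states alike.
4. **Features per tile** —
   * compositional: cell-state proportions (`state_proportions()`) and
     subpopulation marker proportions P(Y+ | X+)
     (`subpop_proportions()`);
   * proximity scores: cross-state pair counts under 20/30/60/90 µm,
     normalised by the summed state proportions (`proximity_score()`);
   * Ripley statistics: cross-type K with isotropic rectangle edge
     correction,
     `L = sqrt(K/pi)`, `delta_L(r) = L(r) − r` at 20/30/60/90 µm, and the
     cluster score `∫₀¹⁰⁰ delta_L dr` (`ripley_cross_K()`,
     `ripley_tile_features()`). Under complete spatial randomness
     `L(r) = r`, so positive `delta_L` means clustering and negative means
     separation;
   * recurrent cellular neighborhoods (RCNs): every cell's 60 µm
     neighborhood composition profile, clustered by elbow-selected k-means;
     per-tile RCN proportions (`neighborhood_profiles()`, `fit_rcn()`,
     `rcn_tile_proportions()`).
5. **Univariate screening** — Wilcoxon rank-sum per feature with
   Benjamini–Hochberg FDR (`wilcoxon_screen()`), within-group feature
   correlations (`group_correlations()`), and a linear mixed model with
   slide as random intercept for slide-aware inference
   (`mixed_effects_screen()`).
6. **Classification** — leave-one-patient-out cross-validation of a
   gradient-boosted tree classifier over repeated iterations
   (`logo_cv()`), with three feature modes: *Compositional*, *Combined*
   (+ RCN + `delta_L` at 20 µm) and *Immune-High* (combined, restricted to
   tiles with ≥ 2% CD8+ cells); pooled metrics, patient-level
   majority-vote calls (`patient_vote()`), TreeSHAP feature importance
   (`importance_summary()`), and a CD8 threshold sweep
   (`threshold_sweep()`).
7. **Synthetic cohorts** — a generator with known ground truth
   (`synthetic_config()`, `generate_cohort()`): Poisson stroma, Thomas
   tumor nests, Poisson immune infiltrates, and — on responder slides —
   planted TIL-like niches (CD8/PD-L1/LAG-3/SOX10/iNOS co-positive disks)
   plus an elevated iNOS rate among CD8+ T cells, with `null`/`weak`/
   `strong` effect presets. Every stage of the pipeline is validated
   against this generator.

## Worked example

```r
library(miftiles)

cfg <- synthetic_config("strong", n_responders = 2, n_nonresponders = 4,
                        extent = c(2000, 2000), seed = 7)
cohort <- generate_cohort(cfg)

pipe <- compute_tile_features(cohort$tables, rcn_k = "auto",
                              ripley = FALSE, seed = 7)
head(pipe$catalog$states[, c("label", "rank", "count")], 5)
#>        label rank count
#> 1      SOX10    1  1904
#> 2        CD3    2  1213
#> 3    CD8+CD3    3   470
#> 4       CD20    4   337
#> 5 iNOS+SOX10    5   334

cfg_m <- model_config("compositional", n_iterations = 5, seed = 7)
a <- assemble_features(pipe$features, cfg_m)
cv <- logo_cv(a$X, a$y, a$groups, cfg_m, tile_id = a$tile_id)
cv
#> <cv_result> 5 iteration(s), 6 folds
#>             metric      mean         sd
#>           accuracy 0.9166667 0.00000000
#>            roc_auc 0.8875000 0.12664928
#>              auprc 0.9141414 0.07764895
#>          precision 1.0000000 0.00000000
#>             recall 0.7500000 0.00000000
#>        specificity 1.0000000 0.00000000
#>  balanced_accuracy 0.8750000 0.00000000
#>                 f1 0.8571429 0.00000000

ari <- niche_recovery_ari(pipe$rcn_model, cohort$ground_truth)
sprintf("niche recovery ARI: %.3f (RCN%d of k = %d)",
        ari$ari, ari$rcn, pipe$rcn_model$k)
#> "niche recovery ARI: 0.872 (RCN5 of k = 5)"
```

The catalog lists marker-combination states ranked by pooled prevalence
(SOX10+ melanoma cells most common, then CD3+ T cells, CD8+CD3+ cytotoxic
T cells, ...). The CV summary pools each iteration's held-out tile
predictions across all patient folds before computing the eight metrics;
here the planted responder effect is recovered with pooled ROC AUC ≈ 0.89
from compositional features alone on this small demonstration cohort. The
adjusted Rand index of 0.87 says one recovered RCN coincides closely with
the planted TIL-like niches.

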