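---
title: "Methods: tile features, spatial statistics and grouped cross-validation in miftiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tile features, spatial statistics and grouped cross-validation in miftiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`miftiles` turns per-cell multiplex immunofluorescence (mIF) exports into
per-tile feature tables and patient-level response predictions. This
vignette records the model choices, the parameters that matter, and the
numerical conventions, in enough detail that a reader can audit or change
any of them.

## Input model and units

The atomic datum is a cell: a centroid (from the bounding-box midpoint
`((x_min + x_max)/2, (y_min + y_max)/2)`) and an 8-vector of binary marker
calls. All internal coordinates are microns; pixel inputs are converted
once at read time using the image resolution (default 0.4992 µm/px, the
resolution of the PhenoImager HT exports this schema comes from). Every
spatial threshold in the pipeline (tile size 1 mm, neighborhood radius
60 µm, proximity radii 20/30/60/90 µm, Ripley grid 0–100 µm) is metric, so
the micron canonicalisation happens exactly once. Cells with a missing
marker call are dropped at ingestion, never imputed: a positivity call is
the measurement itself, and an imputed call would silently manufacture
cell states.

## Tiling

Slides are partitioned into 1 mm × 1 mm tiles by cell centroid. Two
conventions are deliberate:

* the grid is anchored at the minimum cell centroid of the slide — a
  deterministic, data-driven origin that avoids empty margins (the
  alternative, the image origin, is not recoverable from a per-cell
  export);
* intervals are half-open `[x0, x1)`, so boundary cells belong to exactly
  one tile.

Tiles with fewer than 100 cells are retained in the tiling output but
flagged and excluded from all feature computation; 100 cells is the
minimum for proportion features at this tile size to be meaningfully
estimated.

## Cell states: exact counting, superset membership

The catalog is built from the top 20 *exact* positivity patterns pooled
over all slides, then singleton states for markers lacking one, then the
all-negative Stromal state. Membership, by contrast, is *superset*: a cell
belongs to every state whose marker set it covers. This resolves the
apparent tension between ranking "occurring combinations" and counting
cells "inclusive of those expressing more markers": frequency ranking uses
patterns, quantification uses supersets. Ties in pattern counts are broken
lexicographically on the sorted marker label and then by smaller set size,
under byte-order (`radix`) comparison, so the catalog is deterministic
across platforms and locales. States rarer than a configurable prevalence
can be pruned (`min_prevalence`), but the default keeps everything so
synthetic catalogs are fully controlled.

## Spatial features

**Proximity scores** count cross-state cell pairs at distance strictly
less than the radius (the strict inequality is frozen; at 4 radii it is
numerically immaterial but must be fixed for reproducibility), then divide
by the sum of the two states' tile proportions. A cell belonging to both
states contributes to both sides of the bipartite count, but never as a
self-pair; same-state scores count unordered distinct pairs. Undefined
scores (a state absent from the tile) are missing, never zero — a tile
with no SOX10+ cells carries no evidence about SOX10 proximity, and
downstream tree models treat missingness natively.

**Ripley's cross-K** is estimated as

$$\hat K_{AB}(r) = \frac{|W|}{n_A n_B}\sum_{i \in A}\sum_{j \in B,\, j \neq i}
w_{ij}\,\mathbf 1(d_{ij} \le r),$$

with `W` the tile rectangle and `w` the isotropic edge correction: the
reciprocal of the fraction of the circle of radius `d_ij` centred on a
point that lies inside `W`, computed analytically (half-plane arcs with
corner inclusion–exclusion) and verified in the test suite against a
numeric arc integration. The weight is symmetrised — the mean of the two
endpoint corrections — which makes `K(A,B) = K(B,A)` exactly; this is the
package's frozen convention. The indicator uses `≤` (the standard
estimator convention; note proximity scores use `<`). `L = sqrt(K/pi)`,
`delta_L(r) = L(r) − r`, and the cluster score integrates `delta_L` by
trapezoid on a fixed 1 µm grid from 0 to 100 µm. The tile rectangle is the
correction window because features are per-tile; cells appear in each
state's point set they belong to, a direct consequence of superset
membership. Inside fractions below 1e−3 (only possible for radii
comparable to the tile size at a corner) are capped and flagged.
Coincident cell centroids (distance 0 between distinct cells) are excluded
from the weighted sum, preserving `K(0) = 0`.

Because each iteration of the estimator on a 500-cell tile touches ~250k
pairs, the per-tile implementation precomputes one pair list (distance ≤
100 µm, symmetrised weight) and reuses it for every state pair via binned
cumulative sums on the 1 µm grid; this makes the per-pair indicator
`d ≤ r` exact on integer radii.

## Recurrent cellular neighborhoods

Every cell in a retained tile seeds a neighborhood: all tile cells within
60 µm (`≤` at the boundary), *including the seed* — inclusion guarantees
non-empty neighborhoods and well-defined proportions, and the choice is
frozen since either reading is defensible. Neighborhoods are tile-bounded;
cells near a tile edge have truncated neighborhoods, accepted for the same
reason tiles are the unit of analysis. The profile is the state-proportion
vector of the neighborhood.

k-means over profiles uses the elbow rule operationalised for a strictly
decreasing objective: the selected k is the smallest candidate whose
relative WCSS decrease to k+1 falls below `tau = 0.10`. Cluster labels are
relabelled by descending size (RCN1 largest). Two reproducibility
mechanisms are built in: profiles are fitted in a canonical (lexicographic)
row order, making results invariant to input row order; and fitting can
subsample (seeded) above `max_fit_points`, then assigns every profile to
its nearest centre. An empty cluster after assignment is an error rather
than silently reduced k.

## Univariate screening

The Wilcoxon rank-sum screen treats tiles as independent observations —
knowingly optimistic, since tiles within a slide are correlated; it is the
descriptive complement to the mixed model, not a substitute. P-values are
BH-adjusted within the tested feature family. A constant feature yields
p = 1. The mixed-effects screen fits
`value ~ response + (1 | slide)` by maximum likelihood (REML off, as
required for a likelihood-ratio test of a fixed effect) against the
intercept-only mixed model. Proportion-valued features are
log10-transformed after adding half the smallest non-zero value of that
feature — a standard pseudo-count that keeps zero proportions finite
without dominating the scale. Features observed in fewer than 10 slides
are skipped; singular fits are flagged and yield missing p-values. The
type-I error of this screen under a slide-level null is checked by
simulation in the test suite.

## Classification under leave-one-patient-out CV

Tiles inherit their slide's response label; for each of the repeated
iterations (iteration i reseeds everything with `base_seed + i`) and each
slide, a classifier trains on all other slides' tiles and predicts the
held-out slide. Predictions are pooled across folds before metrics are
computed (accuracy, rank-based ROC AUC, average-precision AUPRC,
precision, recall, specificity, balanced accuracy, F1; responder
positive), then summarised as mean ± sd across iterations. Patient calls
are tile-majority votes with an exact tie resolved to non-responder — the
cohort majority class and the conservative clinical call.

The default classifier is an xgboost ensemble of depth-1 stumps (100
rounds, eta 0.1, per-fold class-balancing via `scale_pos_weight`). The
depth choice is a considered one. With 12 patients, trees deep enough to
form feature conjunctions memorise slide-specific feature fingerprints;
under leave-one-patient-out evaluation a held-out slide matches none of
them, and because the minority class contributes fewer training slides,
its held-out tiles drift toward the majority region. On no-signal data
this *anti-learning* pushes the pooled AUC systematically below 0.5 — a
structural property of pooling predictions across grouped folds with few
groups per class, not a bug, and worth knowing about before interpreting
small-cohort CV results. Stumps restrict the model to marginal feature
effects, which recovers planted signal essentially perfectly in the
synthetic cohorts while keeping the no-signal pooled AUC near (slightly
below) chance; a residual downward offset remains and is inherent to the
design. The classifier interface is pluggable (`fit` / `predict_prob` /
`contrib`), so deeper trees or another library can be swapped in for
larger cohorts; feature importance uses TreeSHAP contributions (mean
absolute attribution over all held-out predictions) and asserts Shapley
additivity in the tests.

The Immune-High mode restricts tiles to CD8+ proportion ≥ the threshold
(default 2%); `≥` is the frozen reading of the boundary. Slides left with
zero qualifying tiles become patient-level no-calls. `threshold_sweep()`
re-runs the CV over a cutoff grid; cutoff 0 reduces exactly to the
Combined model.

## The synthetic cohort: what it does and does not emulate

The generator reproduces the statistical skeleton the pipeline relies on:

* background stroma as homogeneous Poisson (250 cells/mm²);
* tumor nests as a Thomas process (3 parents/mm², mean 40 offspring,
  σ = 50 µm) — the simplest stationary cluster process with analytic
  intensity;
* immune infiltrates as Poisson (T cells 60, cytotoxic T 30, B cells
  20 cells/mm²);
* marker co-expression via latent cell types with independent Bernoulli
  marker draws per type — co-expression is induced *only* through the
  latent types, keeping ground truth interpretable;
* responder effects: planted TIL-like niches (100 µm disks at
  3000 cells/mm² of a CD8/PD-L1/LAG-3/SOX10/iNOS co-positive latent type)
  and an elevated iNOS rate among CD8+ cytotoxic T cells. Presets: `null`
  (no difference), `weak` (2 niches, +0.15), `strong` (4 niches, +0.30).

Slides are 3 mm × 3 mm (9 tiles, ~4.3k cells; 12 slides ≈ 52k cells), a
deliberate desk-scale choice: large enough that every feature family has
estimable values on >100 tiles, small enough that the full pipeline —
including the Ripley pair sums — runs in about a minute per cohort. The
cohort shape (4 responders, 8 non-responders) mirrors the clinical setting
the method targets.

`preset_cd8_confined()` is a designed scenario, not a realism claim: the
only responder effect is the niches and the background CD8+ proportion
sits below 2%, so the responder signal lives exclusively in CD8-rich
tiles. It exists to demonstrate, with ground truth, the mechanism by which
immune-high filtering helps: discarding uninformative tiles concentrates
the training and test sets on the region of tissue where the classes
actually differ.

What the generator does **not** emulate: segmentation and thresholding
errors, marker intensity distributions (calls are drawn, not thresholded),
spatial marker gradients within a type, cell-size variation (bounding
boxes are degenerate points), panel-to-panel registration, or biopsy
heterogeneity. Passing the synthetic checks therefore validates the
computational pipeline — estimators, clustering, CV plumbing — not the
biological claim that these features predict ICB response in patients.

## Numerical conventions and edge cases

* Proportions with an empty denominator are `NA`, never 0.
* `wilcox.test` is used with its exact small-sample p-value when
  available; all-tied comparisons return p = 1.
* BH adjustment is `p.adjust(method = "BH")` behind a validated surface.
* k-means ties in nearest-centre assignment resolve to the first centre;
  kept deterministic by the canonical row order.
* All seeds are explicit function arguments; cohort generation derives
  per-slide seeds from the cohort seed, and CV iteration i uses
  `base_seed + i`.

## Known limitations

* The pooled-AUC anti-learning offset discussed above means no-signal
  pooled AUC centres near 0.40–0.47 rather than 0.50 at these cohort
  dimensions; evaluations of weak effects at this scale should compare
  against a permutation/no-signal baseline rather than against 0.5.
* Ripley features for state pairs that are absent from many tiles produce
  missingness patterns that correlate with composition; tree models
  exploit this benignly, but linear downstream models would need explicit
  missingness handling.
* Neighborhoods and edge corrections are tile-bounded; spatial structure
  spanning tile borders is attenuated.
* The mixed-effects screen fits one feature at a time; it controls
  slide-level pseudo-replication, not multiplicity beyond BH or
  between-feature correlation.
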