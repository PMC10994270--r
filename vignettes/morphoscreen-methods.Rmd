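---
title: "Methods: phenotypic reversion scoring in Cell Painting screens"
author: "morphoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotypic reversion scoring in Cell Painting screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

High-content phenotypic drug screens compare the morphology of gene-edited
mutant cells against isogenic wild-type controls and ask which compounds move
the mutant morphological profile back towards the wild-type one. The concrete
setting this package models is a Cell Painting screen of neural progenitor
cells carrying a homozygous knock-out of an Alzheimer's-risk sorting-receptor
gene: nine 384-well plates (three knock-out sub-clones x three compound
concentrations, 100/300/1000 nM), 330 annotated anti-cancer compounds at one
well per compound per plate, 24 wild-type vehicle (positive control) and 16
knock-out vehicle (negative control) wells per plate plus a handful of
untreated knock-out wells, and four image fields per well from which
CellProfiler-style software extracts on the order of a thousand correlated
morphological features per image.

`morphoscreen` implements the complete downstream analysis — feature QC,
dimension reduction, separation testing, classifier-based reversion scoring,
hit calling and gene-set enrichment — together with a first-class synthetic
screen generator with known ground truth, so that every stage of the pipeline
is testable without any external data.

## The synthetic screen generator

`simulate_screen()` draws image-level feature vectors in standardised units
from a hierarchical Gaussian model:

* wild-type vehicle wells have mean **0**;
* knock-out wells are shifted by `genotype_effect` (delta, default 1.0) on an
  affected-feature mask `g` covering `affected_fraction` (default 20%) of the
  `n_features` (default 1100) features;
* a compound `c` with reversion strength `rho_c` in [0, 1] moves the treated
  knock-out mean to `(1 - rho_c_eff) * delta * g`, plus an off-target
  displacement `eta_c * u_c` along a random unit direction `u_c` that is
  drawn once per compound and held fixed across its wells and doses (a
  reproducible drug effect rather than noise);
* by default `rho_c_eff = rho_c * dose / 1000 nM`, a monotone dose-response
  whose full effect is reached at the top concentration; a dose-independent
  mode is available;
* noise has four components: a plate x feature offset (sd `sigma_plate`,
  default 0.1), a well x feature offset (sd `sigma_well`, 0.1), and
  field-level noise of unit sd (default) split between `n_latent` (20)
  latent block factors (within-block correlation `block_r = 0.3`) and
  independent residuals. Feature names follow `Compartment_Class_Index`
  across six stained compartments and nine feature classes (colocalisation,
  adjacency, size, shape, area, texture, radial distribution, granularity,
  intensity), so class-level reporting is possible.

Ten planted reverters receive `rho >= 0.8`; the remaining compounds draw
`rho` uniformly below 0.15. The ground truth (every `rho_c`, `eta_c`, the
mask, the true-hit labels at `rho* = 0.8`, and all seeds) is emitted next to
the table and serialises losslessly to JSON.

Default magnitudes were chosen once as a realistic desk-scale analogue of a
strong, replicable genotype phenotype: the per-feature effect (delta = 1 image-level
sd) is modest, but across ~220 affected features the aggregate separation is
large, which is exactly the regime the real screen reports (its control
classes separate almost perfectly). Untreated knock-out wells default to 6
per plate — the design shows them but never counts them, so a small plausible
number was fixed. What the generator deliberately does **not** model:
spatial plate artefacts (edge effects), optical artefacts, segmentation
errors, non-Gaussian feature distributions, cytotoxic dose-response shapes
(toxicity is available only as whole-well dropout), or any
pharmacokinetics. Passing tests on this generator therefore demonstrate the
statistical machinery, not robustness to those real-data pathologies.

## Feature QC

The stage order is fixed: aggregate, normalise, drop degenerate, drop
redundant, ANOVA filter; the pipeline is idempotent on its own output.

1. **Aggregation** (`aggregate_to_well()`): well-level median of the four
   image fields (mean available); missing fields are ignored.
2. **Normalisation** (`normalize_to_controls()`): per plate and feature,
   robust z-scores `(x - median) / (1.4826 * MAD)` anchored on the
   **knock-out vehicle** wells. The anchor choice is deliberate: the real
   pipeline's normalisation lives inside proprietary software, and anchoring
   to the mutant baseline makes "reversion towards wild-type" a signed,
   interpretable displacement; a wild-type-anchored mode is provided.
   Features whose anchor MAD vanishes on any plate are flagged degenerate and
   centred but not scaled.
3. **Degenerate variables** (`drop_degenerate()`): zero-variance columns,
   then a left-to-right scan removing any column linearly dependent on the
   retained ones within `rank_tol = 1e-8` (a Cholesky sweep of the Gram
   matrix of unit-scaled columns) — the variables that would make the
   correlation matrix singular.
4. **Redundant variables** (`drop_redundant()`): among pairs with
   `|r| >= 0.95`, the member with the larger mean absolute correlation to all
   remaining features is dropped (ties: lexicographically later name), until
   no pair exceeds the threshold. The source screen reports 756 retained
   features but not the rule that produced them, so this module reports its
   own counts rather than targeting that number.
5. **ANOVA filter** (`anova_filter()`): per-feature one-way ANOVA across the
   control classes at **well** level (image-level testing would
   pseudo-replicate fields within wells), BH-adjusted, significant at
   `q < 0.05`. The F statistics are computed by vectorised row-wise matrix
   algebra and verified against `stats::aov` in the tests.

## Dimension reduction

`reduce_profiles()` performs correlation-matrix PCA (so `sum(lambda) = p`),
selects `k` components (Kaiser `lambda > 1` strict, scree elbow at the
maximum second difference, or fixed `k`; the pipeline default is the fixed
`k = 50` used by the source screen), then treats the retained
`sqrt(lambda)`-scaled loadings as a factor solution: **direct oblimin**
rotation (gamma = 0, i.e. quartimin) by the gradient-projection algorithm,
and **ten Berge** correlation-preserving factor scores. The source analysis
applies "PCA" and "factor analysis" without stating their relationship; the
extract-then-rotate flow implemented here is the standard interpretation for
this software lineage, and an unrotated mode is kept (in which the scores
reduce to unit-variance PCA scores).

Numerical choices:

* rotation converges when the projected gradient norm falls below `1e-10`
  **or** the criterion decrease stays below `1e-10` for three consecutive
  iterations (high-`k` rotation manifolds are nearly flat and the gradient
  rule alone can spin), capped at 1000 iterations with the criterion trace
  reported on non-convergence; multi-start (identity plus seeded random
  orthogonal starts) is available and is the default for standalone use,
  while the pipeline uses the single identity start standard at screen scale;
* ten Berge scores are `Z R^{-1/2} C Phi^{1/2}` with
  `C = R^{-1/2} L (L' R^{-1} L)^{-1/2}`, `L = Lambda Phi^{1/2}`; their
  correlation matrix equals `Phi` by construction (asserted to 1e-8 in the
  tests). A rank-deficient feature correlation matrix is refused with a
  pointer to `drop_degenerate()`;
* the PCA sign convention fixes each component's largest-|loading| entry
  positive, so results are reproducible across platforms;
* the reduction is fit on all wells jointly (controls plus treated), as the
  source screen reduces the whole dataset; labels never enter the fit, and
  projection of new records (`predict()`) reuses the training centring and
  scaling so there is no leakage.

## Separation testing

`separation_score()` quantifies two-group separation as
`D = mean(between-class dissimilarity) / mean(within-class dissimilarity)`,
with Euclidean or Bray-Curtis (`sum|u - v| / sum(u + v)`) dissimilarity.
Component scores are signed, while Bray-Curtis requires non-negative
profiles, so each component is min-max rescaled to [0, 1] across the compared
profiles first — consistent with the min-max scaling the source screen uses
for its clustered heatmaps. The screen prints a "Bray-Curtis distance
score = 1.27" without defining the statistic; since plain Bray-Curtis cannot
exceed 1, its internal definition must differ, and the between/within ratio
used here (which can exceed 1 and equals ~1 under no separation) matches the
qualitative claim without targeting the printed value.

`permutation_test()` permutes labels uniformly (default 999 permutations)
and reports the add-one p-value `(1 + #{D_perm >= D_obs}) / (n_perm + 1)`;
the p depends on D only through its rank, so any monotone transform of the
statistic leaves it unchanged. `cluster_view()` provides the min-max-scaled
Ward clustering used for heatmap ordering.

## Classification and reversion scoring

The classifier is anchored on the vehicle controls only: a three-layer
(single hidden layer) neural network on the `k` component scores of the
control **images**, with hidden-layer `size` and weight `decay` chosen by
two-fold cross-validated accuracy over a small grid (ties prefer the smaller
size, then the larger decay), an 80/20 train/test split stratified by class
and **by well** (a well's four fields never straddle the split), and
inverse-class-frequency case weights for the 24:16 control imbalance (the
source is silent on imbalance handling). Random-forest and SVM comparators
run through the identical train/evaluate/score interface.

Evaluation on the held-out control images reports the confusion matrix with
the wild-type (focus) class positive, sensitivity `TP/(TP+FN)`, specificity
`TN/(TN+FP)`, detection rate `TP/total`, and each class's mean focus-class
probability — the analogue of the screen's ">99.68% / >99.64%" control
likelihoods. Compound-treated images are scored by the model's wild-type
probability; the **well score `s`** is the median of its fields' image-level
probabilities (classification happens at image level, reporting at well
level, mirroring the source's convention; an image-level view is retained in
the outputs).

## Hit calling

A compound is a hit when **every** sub-clone exceeds `tau = 0.505` strictly
at one or more concentrations. The replication wording of the source
("replicated in n = 3 sub-clones at one or more of the concentrations
tested") is ambiguous about whether the concentration must be the same
across sub-clones; the default `any_conc` mode allows different effective
doses per sub-clone (the plausible reading given per-sub-clone sensitivity
differences), and a `same_conc` mode implements the stricter reading —
its hit set is provably a subset. Missing wells (e.g. toxic dropouts) count
as non-exceeding, the conservative choice for hit calling. Hits sharing a
parent drug (salt forms) collapse to unique drugs keeping the best score,
and drugs are grouped by mechanism class with an "unannotated" bucket.

## Gene-set enrichment

`hypergeometric_enrichment()` implements one-sided over-representation: for
a query of `n` genes against a background of `N` expressed genes, a set with
`K` background members and `x` observed overlaps has upper-tail p
`P(X >= x)` (hypergeometric), expected overlap `E = nK/N`, enrichment
strength `log10(x/E)` (the effect-size convention of the STRING-style
tools; defined only for `x > 0`), and BH q across all tested sets. The
background is the **expressed-gene list**, not the whole annotation
universe — the background correction the source states it applies. Gene
symbols are uppercased throughout; query genes outside the background are
dropped with a warning; sets without background members are skipped. The
package ships small synthetic GMT / expressed-list / drug-target fixtures
(named `synthetic_*` in `inst/extdata`) so no live database is touched; on
the default synthetic screen the planted reverters are mechanism-agnostic,
so no set is expected to enrich — the stage demonstrates the machinery, not
a biological claim.

## Orchestration and reproducibility

`pipeline_config()` holds every stage parameter (unknown keys are rejected;
YAML round-trip supported) and one root seed from which each stage's seed is
derived deterministically — a single integer reproduces an entire screen,
and identical config + seed gives identical hit lists. `run_pipeline()`
executes simulate → qc → reduce → separate → train → score → call-hits →
enrich, writes all stage outputs under one run directory, embeds the exact
config in the report, aborts with the failing stage's name, and collects
stage warnings into the report. The numbered scripts under `analysis/`
present the same flow as a stepwise narrative over plain-text intermediates.

## Problem sizes used in the tests

The test suite validates the statistical machinery at sizes a laptop handles
comfortably, chosen as the package's own verification scale: five full
default-scale screens (9 plates x 376 wells x 4 fields x 1100 features) for
end-to-end reverter recovery; 400 replicates of a one-plate, 40-feature
screen for permutation-test calibration (199 permutations each) and 100 for
power; 100 replicates of m = 1000 features x 40 wells per group for FDR
control of the ANOVA+BH filter; exhaustive hypergeometric enumeration for
all backgrounds up to N = 30; and 1000 random pairs for the dissimilarity
oracles.

## Known limitations

* The generator's Gaussian, spatially-uniform plates cannot surface
  plate-edge or illumination artefacts; a real screen needs spatial QC
  before this pipeline.
* The between/within separation ratio is not the source screen's (undefined)
  "distance score"; absolute values are not comparable, only the qualitative
  behaviour.
* Oblimin rotation at k = 50 stops at the iteration cap on near-flat
  criterion manifolds; the returned solution is a practical optimum (the
  criterion decrease per iteration is below 1e-5 of its value), consistent
  with the behaviour of reference rotation software at this scale.
* Enrichment fixtures are synthetic; swap in real GMT/expressed files via
  the `enrichment` config block for any real analysis.
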