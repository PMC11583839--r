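---
title: "Mining LC-MS metabolomics feature tables with metabnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining LC-MS metabolomics feature tables with metabnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabnet)
```

## The problem

An untargeted LC–MS metabolomics experiment produces a feature table: peak
areas for thousands of m/z–retention-time features over tens to hundreds of
injections, interleaved with pooled quality-control (QC) samples and often
spread over several batches. Before any biology can be read off such a table
it must be cleaned (noise features and failed injections removed, missing
values imputed, instrument drift and batch shifts corrected), the features
must be annotated against a spectral library with an honest statement of
confidence, and the cleaned matrix must be condensed into interpretable
structure — differentially accumulated metabolites for simple designs, or
co-accumulation modules when the design has too many groups to enumerate
contrasts (mutant panels, populations, time–tissue grids).

metabnet implements that full path as composable R functions around a single
container, `metabo_dataset`, which carries the intensity matrix, sample and
feature metadata, MS2 spectra and an append-only operation log, and can be
checkpointed to disk and restored so long analyses resume from the last
finished stage.

## Cleaning model

**Missingness.** A zero peak area means "not detected", so zeros are read as
missing, never as intensity. A feature is treated as background noise and
removed when it is missing in more than 20% of QC injections (the pooled QC
contains every analyte, so absence there is a detection failure), or when
its missing rate exceeds 20% in *every* study group. The every-group rule is
deliberate: in heterogeneous designs a metabolite fully observed in one
tissue or genotype and absent elsewhere is biology, not noise. Thresholds
are strict inequalities — a rate exactly at 20% is retained. Samples are
triaged by their own missing rate: below 50% kept, above 80% flagged for
removal, the closed interval in between put up for explicit review;
`triage_outliers()` never drops a sample itself.

**Imputation.** K-nearest-neighbour over features: distances are Euclidean
on log2(x+1) profiles over the samples two features share, normalized by the
number of shared samples; a missing entry is the mean of the k = 10 nearest
features' values in that sample. Observed values are never altered.

**Drift and batches.** Within each batch, a support-vector regression
(radial kernel, cost 1, epsilon 0.1) of each feature's QC intensities
against injection order models the drift curve; all samples are corrected by
`raw * median(QC)/predicted(order)`. Predictions below `1e-6 * median(QC)`
fall back to the median so a pathological fit cannot explode a value. The
covariate is injection order alone — simple, observable, and sufficient for
the monotone-to-smooth drift the QC design can identify. At least 5 QC
injections per batch are required; below that the function refuses unless
the median-fold-change fallback is explicitly requested. Residual
between-batch level shifts are then removed by scaling each feature in each
batch so its QC median equals the global QC median
(`integrate_batches()`, a no-op on single-batch data).

## Annotation model

Candidates are generated by MS1 mass over a fixed adduct table ([M+H]+,
[M+Na]+, [M+NH4]+, [M−H2O+H]+, [M−H]−, [M+HCOO]−), polarity-matched, within
a 25 ppm default tolerance. Confidence follows the Metabolomics Standards
Initiative: level 1 requires m/z, retention time (library RT present,
|ΔRT| ≤ 30 s) and an MS2 match; level 2 requires m/z plus MS2; level 3 is
m/z alone. MS2 similarity is the cosine of square-root-intensity vectors
after greedy one-to-one fragment pairing within 0.02 Da — the standard
mirror-plot score; a match counts as evidence at 0.5 or above. The composite
score is a weighted mean of the evidence scores (m/z 0.25, RT 0.25, MS2 0.5,
renormalized over the evidence present); `deduplicate_annotations()` keeps
each feature's best record with deterministic tie-breaks (better level,
smaller |ppm|, lexicographic compound id) and by default preserves all
features sharing one annotation, since near-isomers legitimately co-occur.
In-source fragments are not detected or removed; they remain a known source
of redundant annotations.

## Differential statistics

`dam_analysis()` computes, per feature: a Welch t-test (chosen over
Student's: metabolite variances are rarely equal between groups) or a
Wilcoxon rank-sum test on log2(x+1) intensities; Benjamini–Hochberg FDR
across features; the log2 ratio of raw group means (tests on the log scale,
fold changes on the measurement scale); and a PLS-DA variable importance
(VIP) from a NIPALS fit of the group indicator on the unit-variance-scaled
log2 data of the two compared groups only — restricting to the compared
groups keeps the VIP aligned with the contrast the p-value tests. VIPs obey
the mean-square-one normalization, which the tests exploit as an
implementation check against an independent PLS-DA implementation. A
zero-variance feature is reported with p = 1 and a flag rather than an
error. OPLS-DA is deliberately out of scope: for a two-class VIP criterion
it adds rotation without changing selections, at the cost of determinism.

Enrichment over chemical-taxonomy or pathway terms is the upper-tail
hypergeometric test with BH adjustment; the reported `ratio = k/n` (overlap
over term size) is the conventional dot-size statistic. The default universe
is the annotated metabolites of the dataset, not the whole library — terms
should be judged against what was measurable.

## Iterative module detection

The core mining tool for many-group designs is an iteratively pruned
weighted correlation network:

1. **Soft threshold.** Adjacency `|cor|^beta` (unsigned by default; the
   signed variant is available). beta is the smallest power whose
   connectivity distribution reaches a signed scale-free fit R² of 0.8 over
   a 10-bin log-log regression, selected once in round 1 and held fixed —
   re-selecting on a shrinking feature set is unstable.
2. **Topological overlap.** `TOM_ij = (Σ_u a_iu a_uj + a_ij) /
   (min(k_i,k_j) + 1 − a_ij)`, so two features are similar when directly
   connected *and* sharing neighbours.
3. **Modules.** Average-linkage clustering on `1 − TOM` with a static cut at
   0.995 of the maximum merge height; clusters below 10 members are grey
   (unassigned). The static cut is deterministic, has one interpretable
   parameter, and recovers planted modules in the package's simulations;
   the dynamic-hybrid cut is a possible future extension. Each module is
   summarized by its eigenmetabolite — the first left singular vector of
   the per-feature z-scored submatrix, sign-oriented to correlate
   positively with its members — and modules whose eigenmetabolites
   correlate above 0.75 are merged.
4. **Pruning.** Module membership kME is the correlation of a feature with
   its module's eigenmetabolite. Features that are grey or have own-module
   kME below 0.5 are dropped and the network is rebuilt, until a round
   drops nothing (or 10 rounds, flagged as non-converged). The kME cutoff
   0.5 is a pruning parameter and is distinct from the hub definition,
   which is the strict kME > 0.8.

The result carries assignments, the kME matrix, eigenmetabolites, per-round
counts and the within-module TOM edge list; `export_network()` writes
Cytoscape/Gephi-ready node and edge tables. Pearson correlation is used
throughout; biweight midcorrelation is out of scope.

## Pseudotargeted matching

`select_mrm()` picks one precursor→product transition per feature: the most
intense MS2 fragment at least 3 Da below the precursor (excluding the
unfragmented precursor; ties to the larger m/z). `match_feature_sets()`
classifies cross-run feature pairs as *precise* (precursor < 100 ppm) or
*rough* (100–1,000 ppm), both gated by product < 20 ppm (when both sides
carry products) and RT < 30 s; an A-feature is matched when one or more
partners qualify. Ppm denominators use set A as reference, stated in the
output. `cross_platform_consensus()` performs greedy mutual-nearest one-to-
one pairing (30 ppm / 30 s gates) on the combined normalized distance —
deterministic and O(n log n), which is the right trade-off for
near-identical feature sets; optimal bipartite matching would add cost
without changing near-duplicate pairings.

## What the simulations emulate — and what they do not

`simulate_dataset()` generates log-normal baselines; planted modules as
shared latent factors (within-module correlation ≈ the target, checked by
Monte Carlo); pooled-QC injections every 10 positions carrying the mean
profile plus 0.05 log2 technical noise; per-batch multiplicative drift
linear in injection order; per-feature batch level shifts; and missingness
that is part MCAR, part logistic in −log intensity — the low-abundance
dropout that the QC-rate filters presuppose. `simulate_library()` closes
the annotation loop with records whose evidence exactly matches a planted
MSI level, plus decoys at least 50 ppm from every feature.

Three presets fix the study conditions used by the tests and the acceptance
script: `fbox-like` (2,583 features, 206 subject samples in 20 groups and
3 batches, 12 planted modules of 114, mixed MCAR/MNAR missingness) emulates
a large mutant-panel design; `drift-3batch` (300 features, 90 samples,
strong drift and batch shifts, complete matrix) is the cleaning test bed;
`planted-modules` (5 × 40 members plus 100 noise features, 100 samples) is
the module-recovery test bed. Null calibration uses 10 independent
2,000-feature, 10-vs-10 null tables (20,000 tests).

What passing these simulations does **not** show: real LC–MS drift is not
exactly linear, real module structure is not block-latent, fragment spectra
are not uniform draws, and RT shifts can be locally nonlinear. The
simulations validate the *logic* of each stage (thresholds, invariants,
recoverability), not instrument physics.

## Numerical choices and degenerate inputs

- RT is always stored in seconds; imports auto-detect minutes (max ≤ 120)
  with an explicit override, and the decision is logged.
- Tests run on log2(x + 1); the raw scale is preserved in the matrix.
- Tiny floating-point inversions in average-linkage merge heights are
  monotonized before the tree cut.
- Annotation ties, hub ordering, consensus pairing and module labelling are
  all deterministic (documented tie-breaks); two runs with one config give
  byte-identical tables.
- Degenerate cases are contracts, not crashes: empty annotation sets export
  header-only tables; all-grey clustering returns an empty module set with
  a warning; constant features get p = 1 and are excluded from correlation
  networks with a warning.

## Known limitations

No raw-signal (mzML/mzXML) processing — the pipeline starts at the peak
table. No blank subtraction, no LOESS/quantile normalization alternatives,
no in-source-fragment removal, no OPLS-DA, no module–trait heatmaps. The
checkpoint format is versioned and intentionally refuses files it does not
recognize.
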