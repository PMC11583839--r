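# metabnet

Scriptable mining of untargeted LC–MS plant metabolomics feature tables:
QC-anchored cleaning, MSI-levelled spectral-library annotation, differential
and enrichment statistics, pseudotargeted MRM selection and cross-run
matching, and iterative weighted-correlation-network module detection with
hub-metabolite screening.

It is written for metabolomics researchers who have a peak-picking table
(features × samples with m/z and RT), a sample sheet with class
(Subject/QC/Blank), group, batch and injection order, and optionally MGF
MS2 spectra and a spectral library — and who need to get from that table to
clean intensities, confident annotations and interpretable metabolite
modules without a GUI.

## The methods at the core

- **Noise filtering**: a feature is removed when missing in > 20% of pooled
  QC injections, or in > 20% of samples in *every* study group; samples are
  triaged at 50%/80% missing-rate boundaries.
- **Drift correction**: per feature and batch, a support-vector regression
  of QC intensity on injection order; samples corrected by
  `raw · median(QC)/predicted(order)`, then per-feature batch scaling to a
  common QC median.
- **Annotation**: MSI level 1 = m/z + RT + MS2 match, level 2 = m/z + MS2,
  level 3 = m/z only; MS2 similarity is the sqrt-intensity cosine with
  greedy one-to-one fragment pairing.
- **Differential analysis**: Welch/Wilcoxon tests on log2 intensities with
  BH FDR, raw-scale fold changes, and NIPALS PLS-DA VIP
  (mean VIP² = 1); hypergeometric enrichment with the k/n overlap ratio.
- **Iterative WGCNA**: adjacency `|cor|^β` with β from the scale-free fit,
  topological overlap `TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j)+1−a_ij)`,
  average-linkage clustering, SVD eigenmetabolites, and kME-based pruning
  iterated until every remaining feature sits coherently in a module; hub
  metabolites have kME > 0.8.
- **Feature matching**: precise (< 100 ppm precursor) vs rough
  (100–1,000 ppm) classification with < 20 ppm product and < 30 s RT gates;
  greedy mutual-nearest cross-platform consensus at 30 ppm / 30 s.

A full account of the models, defaults and design choices is in the methods
vignette, `vignettes/metabolomics-mining.Rmd`.

## Worked example

```r
library(metabnet)

sim <- simulate_preset("planted-modules", seed = 1)   # 5 planted modules
ds  <- sim$dataset
ds
#> <metabo_dataset> 300 features x 110 samples (QC: 10, Subject: 100)
#>   missing: 0.0%   MS2 spectra for 0 features
#>   log: simulate

ds  <- filter_noise(ds)                    # QC/group missing-rate rule
x   <- t(log2(ds$expression + 1))
mod <- iterative_wgcna(x)                  # prune-and-recluster to coherence
mod
#> <metabo_modules> 200 features in 5 modules after 2 round(s)
#>   sizes: M1=40 M2=40 M3=40 M4=40 M5=40

glance(mod)
#> # A tibble: 1 x 7
#>   n_modules n_assigned n_hubs n_rounds n_input power converged
#> 1         5        200    200        2     300    19 TRUE

head(hub_metabolites(mod), 3)
#> # A tibble: 3 x 3
#>   module feature_id   kme
#> 1 M1     F0017      0.966
#> 2 M1     F0030      0.965
#> 3 M1     F0031      0.965
```

All 200 planted module members are recovered into 5 modules and all 100
uncorrelated noise features are dropped during iteration; `hub_metabolites()`
ranks each module's most central features by module membership (kME), the
correlation with the module's eigenmetabolite. `export_network(mod, "M1")`
writes Cytoscape-ready edge/node tables, and `autoplot(mod)` draws the
eigenmetabolite profiles.

For real data the entry point is
`read_peak_table("peaks.csv", "samples.csv")`, then the same chain —
`filter_noise() |> impute_knn() |> normalize_svr_qc() |> integrate_batches()`
— followed by `annotate_features()` against a library from
`read_library()`, `dam_analysis()`/`enrich_terms()` for group designs, and
`iterative_wgcna()` for panel designs. `run_pipeline()` chains all stages
from a declarative config with per-stage checkpoints and resume. A thin
command-line front-end lives at `inst/cli/metabnet.R`.

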