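# hippoapms

Scoring and modular analysis of affinity-purification mass-spectrometry
(AP-MS) interaction proteomics, as used to map the human Hippo-pathway
interactome. The package is for proteomics analysts who have protein-level
purification tables (spectral counts and precursor-ion intensities per run)
and need to separate high-confidence interacting proteins (HCIPs) from the
nonspecific background, organize the resulting network into modules, and
compare complex composition across conditions.

## What it computes

**Abundance.** Normalized spectral abundance factors per run:
`NSAF[r,j] = (SpC[r,j]/L_j) / Σ_k (SpC[r,k]/L_k)`.

**Control filter.** A mock-control profile per protein (mean of its top-10
NSAF values across all control runs, zero-padded); a candidate bait–prey
pair passes when the enrichment `E = x̄ / max(profile, floor)` exceeds 10
strictly, where `x̄` is the mean NSAF over the bait's replicates.

**WD^N filter.** A CompPASS-style score
`WD[i,j] = sqrt( x̄[i,j] · ((k/f_j)·ω_j)^n[i,j] )` combining abundance,
cross-bait frequency `f_j` (of `k` baits), replicate reproducibility
`n[i,j]`, and a CV weight `ω_j` floored at 1. Scores are normalized to the
95% quantile of a simulated data matrix (per-prey permutation of entries
across bait columns, 100 seeded rounds); interactions with `WD^N ≥ 1` pass.

**Modules and rescue.** Bait-relative abundance profiles, uncentered-Pearson
distances `d = 1 − Σxy/√(Σx²Σy²)`, average-linkage clustering cut into three
major modules; sub-threshold candidates that pass the control filter are
rescued when their profile has positive similarity to an existing HCIP of
the same bait. Networks export as edge table, SIF and GraphML, with recall
against reference PPI sets.

**Quantification.** Label-free TOP3 (mean of the three most intense
precursor ions) normalized to the bait, log2 fold changes with a shared
pseudo-value, and per-prey t-tests with `*`/`**` significance bands; plus
time-course summaries.

**Synthetic data.** A seeded generator with planted modular truth networks
(Poisson counts, Zipf contaminant background, lognormal intensities,
multiplicative condition effects) so the whole pipeline is testable with no
external data.

## Worked example

The numbered scripts under `analysis/` run the full study on synthetic
data. `Rscript analysis/01_simulate.R` generates the dataset (12 baits, 3
planted modules, 300 true preys, 150 contaminants, 20 mock controls);
`Rscript analysis/02_score_hcip.R` then prints:

```
WD threshold (95% of simulated scores): 1.6800
Final network: 579 interactions (524 rescued) over 312 proteins
Against planted truth: precision 1.000, recall 0.998 (579/580)
```

i.e. the enrichment + WD^N + rescue cascade recovers 579 of the 580 planted
interactions with no false positives at the default thresholds.
`analysis/03_cluster_modules.R` clusters the network and reports an
adjusted Rand index of 1.000 against the three planted modules, and
`analysis/04_quantify.R` recovers a planted 4-fold interaction increase:

```
Planted 4x effect on PREY093: log2 fold change 1.97 (expected 2), p = 3.3e-05 **
```

Equivalently, in R:

```r
library(hippoapms)
sim <- simulate_apms(generator_config(rng_seed = 1L))
res <- score_hcip(sim$dataset, pipeline_config(rng_seed = 1L))
hcip_performance(res$network, sim$truth)
```

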