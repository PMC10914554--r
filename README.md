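# meiobar

Taxonomy-free analysis of benthic meiofaunal communities from 18S-V4
amplicon metabarcoding, for ecologists who need species-level community
structure where morphological identification is impractical (deep-sea
sediments, monitoring time series, under-described faunas).

## What it computes

The pipeline treats **3%-dissimilarity clusters of amplicon sequence
variants (ASV-3)** as species-proxies and anchors read counts to physically
counted specimens:

1. **Read QC** — BWA-style 3' quality truncation (Phred cutoff 25),
   anchored IUPAC primer removal, length (≥ 180 bp) and N-run (> 3) filters,
   exhaustive ungapped pair merging with quality-aware consensus.
2. **Species-proxy library** — pairwise p-distances from global alignments
   (gap/N columns excluded), group-average (UPGMA) agglomeration with a
   deterministic tie rule, dendrogram cut strictly below 3%.
3. **Profiles** — merged reads mapped to the meiofaunal reference at ≤ 3%
   mismatch, ≤ 1% gaps, ≤ 3 bp per gap; per-slice read counts per cluster.
4. **Abundance** — reads normalized to counted specimens,
   `est(c) = reads(c)/Σreads × counts`, then the **counts/ASV-3 index**
   rule: the smallest global threshold τ* is found such that zeroing every
   cell below τ* makes `counts / #nonzero clusters > 1` in every
   informative slice, removing background DNA (uncounted soft-bodied taxa,
   gut contents, adsorbed DNA).
5. **Diversity** — Hill numbers q = 0 (richness, Chao1 asymptote) and q = 1
   (exponential Shannon, singleton-corrected estimator), hypergeometric
   rarefaction / Chao-style extrapolation, detection-adjusted bootstrap
   intervals, on replicate-combined, per-cm-normalized profiles.
6. **Community structure** — square-root transform, Bray-Curtis similarity,
   group-average dendrograms, pairwise PERMANOVA permutation tests, BIOENV
   best-subset search over abiotic variables with a max-over-permutations
   significance threshold, shared-ASV-3 percentage matrices.
7. **Abiotics** — grain-size fractionation (clay < 4 µm, silt 4-63 µm,
   sand > 63 µm; silt/clay ratio), abiotic-table validation and horizon
   midpoints.

A seeded **synthetic-data generator** (`simulate_study()`) produces
complete studies — reference barcodes with planted cluster structure,
depth/horizon-structured Poisson communities, paired reads with a
configurable background fraction, abiotic tables — so every stage is
testable without sequencing data. See `vignette("methods")` for the models,
defaults and their rationale.

## Worked example

```r
library(meiobar)

cfg <- sim_config(n_sites = 3, depths_m = c(54, 394, 1134),
                  n_cores_per_site = 2, n_species = 12,
                  reads_per_slice = 300, seed = 101)
sim <- simulate_study(cfg)
res <- run_pipeline(sim, n_perm = 99, boot_B = 200, seed = 1)

head(res$funnel, 3)
#>    slice n_raw_pairs n_filtered_pairs n_merged n_mapped n_mapped_meiofauna
#> 1 HS54A0         300              300      300      300                287
#> 2 HS54A1         300              300      300      300                284
#> 3 HS54A3         300              300      300      300                286
```

All 300 pairs survive QC and merge (errors here are rare substitutions);
287 of the first slice's reads map to meiofaunal species-proxies — the rest
hit non-meiofaunal references or fail the 3% threshold. The background
zeroing then finds τ* = 0.93 estimated specimens, leaving every slice's
counts/ASV-3 index above 1 (range 1.5-20.2 in this run):

```r
res$zeroing$tau                      # 0.933
range(na.omit(res$zeroing$index))    # 1.50 20.23

head(res$diversity[res$diversity$q == 0, ], 3)
#>   site horizon_top_cm q observed estimated        se ci_lo  ci_hi
#> 1 HS54              0 0       14        14 0.2113459    13 14.000
#> 3 HS54              1 0       12        12 0.7952345    11 14.000
#> 5 HS54              3 0       11        13 2.2597305     9 17.025
```

Observed and estimated richness nearly coincide in the well-sampled surface
slices — the asymptote has been reached — while deeper slices carry wider
intervals. The abiotic best-subset search recovers the spatial gradients
that actually structure the simulated community:

```r
res$community$bioenv
#> best subset: oxygen + depth_m + horizon_cm, rho = 0.688 (threshold 0.241)
```

Depth and horizon are the planted drivers; at this small study size a noise
variable (here oxygen) occasionally joins the best subset, which is exactly
the overfitting behaviour BIOENV's permutation threshold is there to keep
honest — the subset's rho (0.69) clears the threshold, single noise
variables do not. At the full default study size (`sim_config()`,
6 sites × 3 cores) the best subset is {depth, horizon} in ≥ 90% of seeded
replicates (asserted in the test suite).

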