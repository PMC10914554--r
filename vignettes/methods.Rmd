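---
title: "Species-proxy metabarcoding of benthic meiofauna: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-proxy metabarcoding of benthic meiofauna: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiobar)
```

## The analysis in one paragraph

meiobar analyses benthic meiofaunal communities from 18S-V4 amplicon reads
without morphological species identification. Exact amplicon sequence
variants (ASVs) are clustered at 3% group-average dissimilarity; each
cluster ("ASV-3") is treated as a species-proxy. Merged reads from each
sediment slice are mapped back to the meiofaunal part of this reference
library, the per-cluster read counts are converted into estimated specimen
counts by normalizing against the number of sorted, counted hard-bodied
individuals in the same slice, and an iterative zeroing rule removes the
estimated-count mass attributable to background DNA (soft-bodied taxa that
disintegrate before counting, gut contents, adsorbed DNA). The cleaned
matrix feeds Hill-number diversity estimation and resemblance-based
community statistics (Bray-Curtis, group-average dendrograms, pairwise
permutation tests, BIOENV).

## Why a specimen-count normalization

Read counts are a poor proxy for abundance: PCR efficiency and rDNA copy
number differ among species. The pipeline therefore treats read counts only
as *within-slice relative* signals and rescales each slice profile so that
it sums to the number of individuals actually counted in that slice,

$$\widehat{c}_{ks} \;=\; \frac{r_{ks}}{\sum_k r_{ks}}\; C_s ,$$

where $r_{ks}$ is the mapped-read count of cluster $k$ in slice $s$ and
$C_s$ the counted specimens. Estimates conserve $C_s$ exactly
(`normalize_matrix()`).

Reads also arrive from organisms that are never counted. The diagnostic is
the **counts/ASV-3 index** $C_s / \mathrm{nnz}_s$ (counted specimens over
the number of clusters with nonzero estimate): if every mapped read came
from a counted individual the index must exceed 1. `background_zero()`
finds the *smallest* global threshold $\tau^\*$, scanned over the multiset
of estimated-count values, such that zeroing every cell below $\tau^\*$
pushes the index above 1 in every informative slice. Design choices, all
checked by tests:

* one global threshold for the whole matrix (a per-slice variant is
  available via `per_slice = TRUE` for sensitivity analysis);
* zeroed mass is not redistributed by default (`renormalize = TRUE`
  rescales survivors to the slice total);
* the inequality is strict (> 1);
* slices whose counted total is 0 or 1 can never satisfy the index and are
  zeroed entirely and flagged;
* when no single threshold can serve all slices at once (one slice needs a
  high cut while another's largest cell sits below it), the slice with the
  smallest maximum cell — the least reliable profile — is zeroed and
  flagged, and the scan repeats. The minimality of $\tau^\*$ is verified
  against a brute-force scan in the test suite.

## Species-proxy clustering

Pairwise p-distances are computed from global Needleman-Wunsch alignments
with match 0, mismatch 1 and gap 1 per position; a small gap-opening
penalty (0.5) breaks ties so that a gapped alignment never replaces an
equal-cost ungapped one, which would otherwise make the p-distance depend
on an arbitrary traceback. Columns containing a gap or an N are excluded
from both numerator and denominator.

Clustering is classical group-average agglomeration (UPGMA: inter-cluster
distance is the pair-count-weighted mean of all cross-pair distances).
Merges at equal height are ordered by the lexicographically smallest member
identifier, so the tree does not depend on input order. The dendrogram is
cut **strictly below** 0.03: a merge at exactly 3% does not join clusters.
The suite checks the implementation against a naive re-agglomeration oracle
and against `hclust(method = "average")`.

Read mapping accepts a hit when the mismatch fraction over aligned columns
is at most 3%, the gapped fraction of the read at most 1%, and no single
gap exceeds 3 bp (all thresholds inclusive). Reads are assigned to the
cluster of the closest admissible ASV; ties go to the cluster already
holding more reads in the slice, then to the smaller cluster id. A shared
k-mer pre-filter (k = 12) skips references that provably cannot reach the
thresholds — a read of length $L$ admissible against a reference retains at
least $(L-k+1) - k \cdot (\lceil 0.03 L \rceil + \lceil 0.01 L \rceil + 1)$
of its positional k-mers — so the filtered and exhaustive paths give
identical assignments (asserted by tests).

## Diversity

Diversity is summarised by Hill numbers of order 0 (richness) and 1
(exponential Shannon). Replicate cores are summed per slice, normalized per
1 cm of horizon thickness and rounded half-to-even to integers, because the
frequency-count estimators need integer abundances; slices where rounding
changes the observed richness are flagged. Asymptotic estimates use the
classical Chao1 lower bound ($S_{obs} + f_1^2/2f_2$, with the
$f_1(f_1-1)/2$ correction when doubletons are absent) and the
singleton-corrected low-bias entropy estimator for $q=1$. Rarefaction is
the exact hypergeometric expectation; extrapolation follows the standard
Chao-style form for richness and, for $q=1$, an entropy blend
$\exp\{w\,H_{obs} + (1-w)\,\hat H_\infty\}$ with $w = n/(n+m^\*)$, which
anchors at the observed value and approaches the asymptotic estimate.
Extrapolation beyond $2n$ is reported but flagged unreliable. Uncertainty
comes from a detection-adjusted bootstrap: observed species get
detection-corrected probabilities, the estimated number of undetected
species share the estimated missing coverage, and $B = 200$ multinomial
resamples give the SE and the percentile 95% interval.

## Community statistics

Profiles are square-root transformed (damping dominants) before Bray-Curtis
similarity $100\,(1 - \sum_k|u_k - v_k| / \sum_k (u_k + v_k))$. The
group-average dendrogram uses the same deterministic UPGMA engine as the
reference library, cut at stated similarity levels (20% and 40% are the
conventional marks). Pairwise differences between profile groups are tested
with a one-way PERMANOVA pseudo-F under unrestricted label permutation,
$p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})$; no asymptotic
small-sample correction is applied — the permutation p-value is the
defensible core, and groups too small for a meaningful permutation null are
reported as such rather than "corrected".

BIOENV searches every non-empty subset of the standardised abiotic
variables (protein, carbohydrate, silt/clay ratio, sand percent, oxygen,
depth, horizon midpoint) for the Euclidean distance structure whose
Spearman rank correlation with the biotic dissimilarities is maximal.
Significance uses the strictest reading of a permutation threshold: slice
identities of the abiotic table are permuted, the *full* best-subset search
is repeated per permutation, and the observed best rho must exceed the
maximum of these. Ties in ranks use average ranks. The search is verified
against `vegan::bioenv` on random studies.

Shared species-proxy percentages between sites default to the Jaccard
convention $|A \cap B|/|A \cup B| \times 100$; because published tables of
this kind rarely state their denominator, a "percentage of the smaller
set" convention is selectable and neither is asserted as canonical.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every pipeline claim is verified. It emulates a deep-sea,
two-gradient survey: 6 sites at 54-1418 m bottom depth, 3 replicate cores
per site, each core sliced 1, 2, 2, 2, 3, 3, 4 cm down to 17 cm.

**Reference barcodes.** Amplicons are 325-445 bp including the degenerate
primer pair. Within/between-species divergence is planted combinatorially,
not stochastically: species carry base-4 codewords on shared blocks of
$\lceil 0.10\,L \rceil$ positions of an ancestral core (any two species
differ across at least one full block), and each ASV receives a private set
of substitution positions outside the blocks. Planted within-species
p-distance is exactly $2\lfloor 0.015 L/2 \rfloor / L < 3\%$ and
between-species distance at least 10%, so the 3% cut must recover the
species partition exactly; configurations that cannot satisfy these bounds
raise an error rather than silently degrading.

**Communities.** Counts are Poisson with expectation
$b_s\,e^{-k_{d,s} d}\,e^{-k_{h,s} h}$: lognormal per-species baselines
(mean 20 at the surface, spread 0.8 on the log scale) and exponential decay
in depth (0.003 per m, roughly the ~60-fold abundance drop over 54-1418 m
that deep-sea surveys report) and in horizon midpoint (0.3 per cm, which
empties the deepest slices of most species, as observed in such cores).
Per-species lognormal niche multipliers (spread 0.8) on both rates make
*composition*, not just total abundance, turn over along depth and horizon
— without them the two spatial gradients would only rescale every species
equally and no resemblance-based method could attribute composition to
them. The Poisson choice and the multinomial read model are artifact
choices; the underlying study reports no generative distribution.

**Reads.** Forward reads are the 5' 250 bp of the amplicon, reverse reads
the reverse complement of the 3' 250 bp (2 x 250 chemistry), guaranteeing
at least 55 bp of overlap at the longest amplicon. A configurable fraction
of each slice's reads (default 8.9%) is drawn from species absent from the
count table — soft-bodied meiofauna and non-meiofaunal taxa — giving the
zeroing rule a planted signal. Substitution errors are applied per base
(default 0.002); qualities are constant high with an optional degrading 3'
tail to exercise trimming. The `"exact"` read-allocation mode makes read
counts exactly proportional to specimen counts; combined with zero error
and zero background (`no_noise()`), the full pipeline must then recover the
planted truth *exactly* — partition, membership and per-slice counts — and
the tests assert precisely that.

**Abiotic tables.** Depth and horizon midpoint are exact; the five
sedimentary variables are generated on a latent standardised scale as
$\rho g + \sqrt{1-\rho^2}\,\varepsilon$ against the community gradient $g$,
with default coupling $\rho = 0$ (pure noise), so the planted BIOENV answer
is {depth, horizon}. Grain-size spectra are three-point distributions
consistent with the generated silt/clay ratio and sand fraction, so the
fractionation module can be validated on them round-trip.

What the generator deliberately does **not** emulate: chimeras, PCR
amplification bias, rDNA copy-number variation, quality-dependent error
rates, and denoising artefacts. Passing tests therefore demonstrate the
correctness of the *computational* pipeline under its stated model, not
robustness to every bias of real amplicon data.

## Read QC details

3' quality truncation uses the running-sum rule (the documented behaviour
of BWA-style `-q` trimming): the retained prefix ends before the suffix
maximising the cumulative sum of (cutoff - quality) from the 3' end, with
cutoff Phred 25. Primer matching is anchored at the 5' end, respects IUPAC
degeneracy on both sides, and tolerates one substitution by default (the
originating tools do not publish their exact allowance; the value is a
documented, overridable choice). The length floor is 180 bp and more than
3 consecutive Ns reject a read; a failure in either mate rejects the pair.
Merging scans every ungapped overlap from the longest possible down to the
minimum (20 bp), accepts the best-scoring overlap whose mismatch fraction
is at most 10%, and resolves overlap disagreements by the higher-quality
base, ties to the forward mate.

## Problem sizes and determinism

The default synthetic study is desk-scale: 25 counted species (plus 3
soft-bodied and 2 non-meiofaunal), 2 ASVs per species, 126 slices, 500 read
pairs per slice — roughly 60,000 read pairs end to end. These sizes were
chosen so that a complete study exercises every code path, including rare
ones (empty deep slices, flagged profiles), while a full pipeline run
remains a couple of minutes of computation. Every stochastic stage takes an
explicit seed: the generator derives per-stage seeds from the
configuration seed by fixed offsets, and permutation tests, BIOENV
thresholds and bootstraps accept their own seeds, so any result in the
package can be reproduced byte-for-byte.

## Known limitations

* Normalization divides by meiofauna-mapped reads; whether the original
  procedure used all mapped reads is not stated in public descriptions, and
  the alternative is a one-line change.
* The counts/ASV-3 zeroing is a semi-arbitrary bias correction by its own
  authors' description; the package implements it exactly but also exposes
  the per-slice and renormalizing variants for sensitivity analysis.
* The p-distance of two sequences is only well defined up to co-optimal
  alignments; the small gap-opening penalty makes the package's convention
  deterministic, but other tools may report slightly different values for
  highly divergent pairs.
* Permutation p-values are exact only up to Monte-Carlo error and are
  floored at `1/(n_perm + 1)`; with very small groups the permutation null
  has few distinct relabellings and p-values cannot be small.
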