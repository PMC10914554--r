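Package: meiobar
Title: Taxonomy-Free Meiofaunal Metabarcoding with ASV Species-Proxies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for 18S-V4 amplicon metabarcoding
    of benthic meiofaunal communities that does not rely on morphological
    taxonomy. Paired amplicon reads are quality-filtered, primer-trimmed and
    merged; amplicon sequence variants (ASVs) are grouped by group-average
    clustering of p-distances into 3 percent dissimilarity clusters (ASV-3)
    used as species-proxies; merged reads are mapped back to the species-proxy
    reference library to build per-slice community profiles; read counts are
    normalized by sorted-specimen counts and cleaned by an iterative
    background-zeroing rule; Hill-number diversity (richness and exponential
    Shannon) is estimated with rarefaction, extrapolation and bootstrap
    uncertainty; and community structure is related to sedimentary covariates
    through Bray-Curtis resemblance, group-average dendrograms, pairwise
    permutation tests and a BIOENV best-subset search. A seeded synthetic-data
    generator reproduces the statistical structure the analysis assumes, so
    every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    vegan,
    ape,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
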