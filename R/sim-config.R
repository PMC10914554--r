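#' Simulation configuration for a synthetic metabarcoding study
#'
#' Defines every tunable of the synthetic-data generator: the spatial design
#' (sites, bottom depths, sub-bottom horizon slicing, replicate cores), the
#' species pool and its barcode structure, the community gradient, and the
#' sequencing model. Defaults describe a desk-scale study with the structure
#' of a two-transect deep-sea survey: abundance decays exponentially with
#' bottom depth and with sub-bottom horizon, a fixed fraction of reads comes
#' from soft-bodied taxa that are never counted, and barcodes within a
#' species-proxy cluster diverge by less than 3% while clusters are separated
#' by more than 3%.
#'
#' @param n_sites number of sampling sites.
#' @param depths_m bottom depth (m) per site; length `n_sites`.
#' @param horizon_scheme slice thicknesses in cm from the sediment surface
#'   downward. The default `c(1, 2, 2, 2, 3, 3, 4)` spans 0-17 cm and
#'   compensates for decreasing abundance in deeper horizons.
#' @param n_cores_per_site replicate cores per site.
#' @param n_species number of counted, hard-bodied meiofaunal species.
#' @param n_background_species soft-bodied meiofaunal species that produce
#'   reads but are never present in the sorted-specimen count table.
#' @param n_other_species non-meiofaunal species (e.g. fungi) present in the
#'   reference library; reads mapping to them are tallied separately.
#' @param n_asvs_per_species barcode variants (ASVs) per species.
#' @param barcode_length_range amplicon length range in bp, primers included.
#' @param within_cluster_divergence target pairwise p-distance among ASVs of
#'   one species; must be < 0.03.
#' @param between_cluster_divergence guaranteed minimum p-distance between
#'   ASVs of different species; must exceed 0.03 by `cluster_margin`.
#' @param cluster_margin required separation of `between_cluster_divergence`
#'   above the 0.03 species-proxy cut.
#' @param abundance_decay_depth exponential decay rate of expected abundance
#'   per metre of bottom depth.
#' @param abundance_decay_horizon exponential decay rate per cm of sub-bottom
#'   horizon (midpoint).
#' @param baseline_mean mean expected count per species, core and slice at
#'   depth 0 and horizon 0; per-species baselines are lognormal around it.
#' @param baseline_sdlog lognormal spread of per-species baselines.
#' @param species_niche_sd lognormal spread of per-species multipliers on
#'   the two decay rates. Zero gives every species the same depth and
#'   horizon response (total abundance changes along the gradients but
#'   composition does not); positive values differentiate species responses,
#'   creating compositional turnover with depth and horizon as real
#'   communities show.
#' @param background_read_fraction expected fraction of reads originating
#'   from species absent from the count table.
#' @param reads_per_slice sequencing depth per slice (read pairs surviving
#'   to the mapped stage, before QC losses).
#' @param seq_error_rate per-base substitution probability in reads.
#' @param read_length length of each mate in bp (2 x 250 chemistry).
#' @param read_allocation `"multinomial"` draws read counts per species from
#'   a multinomial around the expected proportions; `"exact"` makes read
#'   counts exactly proportional to specimen counts (a noise-free setting
#'   used to verify that the pipeline recovers planted truth).
#' @param degrade_quality_tail if `TRUE`, read qualities decay linearly
#'   towards the 3' end so that quality trimming is exercised.
#' @param indels if `TRUE`, ASVs may additionally carry a short (1-3 bp)
#'   indel so that the gap rules of read mapping are exercised.
#' @param abiotic_coupling named numeric in \[-1, 1\]: rank-correlation
#'   coupling of each non-spatial abiotic variable (protein, carbohydrate,
#'   silt_clay_ratio, sand_percent, oxygen) to the community gradient.
#'   Zero (the default) makes them pure noise so that depth and horizon are
#'   the only planted drivers.
#' @param forward_primer,reverse_primer IUPAC primer sequences flanking the
#'   barcode.
#' @param seed integer seed; every generator output is a deterministic
#'   function of the configuration including the seed.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_sites = 6L,
                       depths_m = c(54, 122, 394, 771, 1134, 1418),
                       horizon_scheme = c(1, 2, 2, 2, 3, 3, 4),
                       n_cores_per_site = 3L,
                       n_species = 25L,
                       n_background_species = 3L,
                       n_other_species = 2L,
                       n_asvs_per_species = 2L,
                       barcode_length_range = c(325L, 445L),
                       within_cluster_divergence = 0.015,
                       between_cluster_divergence = 0.10,
                       cluster_margin = 0.05,
                       abundance_decay_depth = 0.003,
                       abundance_decay_horizon = 0.3,
                       baseline_mean = 20,
                       baseline_sdlog = 0.8,
                       species_niche_sd = 0.8,
                       background_read_fraction = 0.089,
                       reads_per_slice = 500L,
                       seq_error_rate = 0.002,
                       read_length = 250L,
                       read_allocation = c("multinomial", "exact"),
                       degrade_quality_tail = FALSE,
                       indels = FALSE,
                       abiotic_coupling = c(protein = 0, carbohydrate = 0,
                                            silt_clay_ratio = 0,
                                            sand_percent = 0, oxygen = 0),
                       forward_primer = "CCGCGGTAATWCCAGCHY",
                       reverse_primer = "TTGGCAAATGCYTTCGCAKTHG",
                       seed = 1L) {
  read_allocation <- match.arg(read_allocation)
  cfg <- list(
    n_sites = as.integer(n_sites), depths_m = as.numeric(depths_m),
    horizon_scheme = as.numeric(horizon_scheme),
    n_cores_per_site = as.integer(n_cores_per_site),
    n_species = as.integer(n_species),
    n_background_species = as.integer(n_background_species),
    n_other_species = as.integer(n_other_species),
    n_asvs_per_species = as.integer(n_asvs_per_species),
    barcode_length_range = as.integer(barcode_length_range),
    within_cluster_divergence = within_cluster_divergence,
    between_cluster_divergence = between_cluster_divergence,
    cluster_margin = cluster_margin,
    abundance_decay_depth = abundance_decay_depth,
    abundance_decay_horizon = abundance_decay_horizon,
    baseline_mean = baseline_mean, baseline_sdlog = baseline_sdlog,
    species_niche_sd = species_niche_sd,
    background_read_fraction = background_read_fraction,
    reads_per_slice = as.integer(reads_per_slice),
    seq_error_rate = seq_error_rate,
    read_length = as.integer(read_length),
    read_allocation = read_allocation,
    degrade_quality_tail = isTRUE(degrade_quality_tail),
    indels = isTRUE(indels),
    abiotic_coupling = abiotic_coupling,
    forward_primer = toupper(forward_primer),
    reverse_primer = toupper(reverse_primer),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$n_sites >= 1 && length(cfg$depths_m) == cfg$n_sites,
              "depths_m must supply one depth per site")
  assert_that(all(cfg$depths_m > 0), "depths must be positive")
  assert_that(all(cfg$horizon_scheme > 0),
              "horizon_scheme entries must be positive slice thicknesses")
  assert_that(cfg$within_cluster_divergence < 0.03,
              "within_cluster_divergence must be < 0.03")
  assert_that(cfg$between_cluster_divergence > 0.03,
              "between_cluster_divergence must be > 0.03")
  assert_that(cfg$between_cluster_divergence >= 0.03 + cfg$cluster_margin,
              "between_cluster_divergence must clear the 3% cut by cluster_margin")
  probs <- c(cfg$background_read_fraction, cfg$seq_error_rate)
  assert_that(all(probs >= 0 & probs <= 1), "probabilities must lie in [0,1]")
  assert_that(cfg$abundance_decay_depth >= 0 && cfg$abundance_decay_horizon >= 0,
              "decay rates must be non-negative")
  assert_that(length(cfg$barcode_length_range) == 2 &&
                diff(cfg$barcode_length_range) >= 0,
              "barcode_length_range must be an increasing pair")
  assert_that(is_iupac(cfg$forward_primer) && is_iupac(cfg$reverse_primer),
              "primers must be IUPAC nucleotide strings")
  invisible(cfg)
}

#' Switch a simulation configuration to its noise-free variant
#'
#' Zeroes sequencing error and the background-read fraction and makes read
#' counts exactly proportional to specimen counts. Under this setting the
#' full pipeline must recover the planted truth exactly: the species-proxy
#' partition equals the planted membership and estimated slice counts equal
#' the true counts.
#'
#' @param cfg a [sim_config()].
#' @return the modified `sim_config`.
#' @export
no_noise <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cfg$seq_error_rate <- 0
  cfg$background_read_fraction <- 0
  cfg$read_allocation <- "exact"
  cfg$degrade_quality_tail <- FALSE
  cfg$indels <- FALSE
  validate_sim_config(cfg)
  cfg
}

# horizon boundaries (cm) implied by the slicing scheme: 0, 1, 3, 5, ...
horizon_bounds <- function(scheme) c(0, cumsum(scheme))

# horizon midpoints in cm
horizon_midpoints <- function(scheme) {
  b <- horizon_bounds(scheme)
  (b[-1] + b[-length(b)]) / 2
}

site_names <- function(cfg) paste0("HS", round(cfg$depths_m))
core_names <- function(cfg) LETTERS[seq_len(cfg$n_cores_per_site)]

# slice label: site + core letter + horizon top in cm (e.g. HS54A0)
slice_label <- function(site, core, top) paste0(site, core, top)

HARD_GROUPS <- c("Nematoda", "Copepoda", "Polychaeta", "Isopoda",
                 "Ostracoda", "Cumacea", "Mollusca")
SOFT_GROUPS <- c("Platyhelminthes", "Gastrotricha", "Gnathostomulida",
                 "Xenacoelomorpha")
OTHER_GROUPS <- c("Fungi", "Alveolata", "Chlorophyta")
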