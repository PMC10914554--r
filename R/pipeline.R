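# End-to-end orchestration: QC -> reference library -> slice profiles ->
# count normalization and background zeroing -> diversity -> community
# statistics, with a read-number funnel report.

# strip the primer pair from reference amplicons (forward primer at the 5'
# end, reverse primer at the 5' end of the reverse complement)
trim_primers_from_reference <- function(seqs, forward_primer, reverse_primer,
                                        max_mismatch = 1L) {
  vapply(seqs, function(s) {
    a <- remove_primer(s, NULL, forward_primer, max_mismatch)
    s2 <- if (a$rejected) s else a$seq
    b <- remove_primer(revcomp(s2), NULL, reverse_primer, max_mismatch)
    if (b$rejected) s2 else revcomp(b$seq)
  }, character(1))
}

#' Run the full metabarcoding pipeline on a synthetic study
#'
#' Executes every stage in order: read QC and pair merging; species-proxy
#' reference-library construction from the study's ASV FASTA (primer
#' trimming, p-distance matrix, 3% group-average cut); read mapping into
#' per-slice profiles; count normalization and background zeroing; Hill
#' diversity on replicate-combined, thickness-normalized profiles; and the
#' community statistics (Bray-Curtis dendrogram, pairwise permutation tests,
#' BIOENV, shared-ASV matrix). All randomised stages take their seeds from
#' `seed`, so a re-run with the same inputs is identical.
#'
#' @param sim a `meiobar_sim` study from [simulate_study()].
#' @param qc a [qc_params()]; primers default to the simulation's.
#' @param mapping a [mapping_params()].
#' @param cut species-proxy dissimilarity cut (default 0.03).
#' @param dendro_cut_similarity similarity level (percent) at which profile
#'   groups are formed for the pairwise tests.
#' @param n_perm permutations for the pairwise tests and BIOENV threshold.
#' @param boot_B bootstrap replicates for diversity uncertainty.
#' @param seed integer seed for permutation and bootstrap stages.
#' @param outdir optional directory: stage outputs are written as TSV /
#'   FASTA / Newick when given.
#' @return list of class `meiobar_result` with elements `library`, `funnel`,
#'   `profiles`, `normalized`, `zeroing`, `diversity`, `community`.
#' @export
run_pipeline <- function(sim,
                         qc = NULL,
                         mapping = mapping_params(),
                         cut = 0.03,
                         dendro_cut_similarity = 40,
                         n_perm = 199L,
                         boot_B = 200L,
                         seed = 1L,
                         outdir = NULL) {
  stopifnot(inherits(sim, "meiobar_sim"))
  if (is.null(qc))
    qc <- qc_params(forward_primer = sim$cfg$forward_primer,
                    reverse_primer = sim$cfg$reverse_primer)

  # --- stage 1: QC + merging -------------------------------------------
  merged <- list()
  qc_stats <- list()
  for (sl in names(sim$reads)) {
    df <- sim$reads[[sl]]
    res <- qc_slice(
      data.frame(id = df$id, seq = df$fwd_seq, qual = df$fwd_qual,
                 stringsAsFactors = FALSE),
      data.frame(id = df$id, seq = df$rev_seq, qual = df$rev_qual,
                 stringsAsFactors = FALSE),
      qc)
    merged[[sl]] <- res$merged$seq
    qc_stats[[sl]] <- res$stats
  }

  # --- stage 2: reference library --------------------------------------
  ref_seqs <- stats::setNames(sim$ref$asvs$sequence, sim$ref$asvs$asv_id)
  trimmed <- trim_primers_from_reference(ref_seqs, sim$cfg$forward_primer,
                                         sim$cfg$reverse_primer)
  taxonomy <- data.frame(asv_id = sim$ref$asvs$asv_id,
                         taxonomy_label = sim$ref$asvs$taxonomy_label,
                         stringsAsFactors = FALSE)
  group_table <- data.frame(
    taxon = c(HARD_GROUPS, SOFT_GROUPS, OTHER_GROUPS),
    functional_group = c(rep("meiofauna",
                             length(HARD_GROUPS) + length(SOFT_GROUPS)),
                         rep("other", length(OTHER_GROUPS))),
    stringsAsFactors = FALSE)
  lib <- build_reference_library(trimmed, taxonomy, group_table, cut = cut,
                                 min_length_bp = 180L)

  # --- stage 3: profiles ------------------------------------------------
  prof <- profile_matrix(merged, lib, mapping)

  # --- stage 4: normalization + zeroing ---------------------------------
  totals <- slice_totals(sim$count_table)
  norm <- normalize_matrix(prof$matrix, totals)
  zero <- background_zero(norm$estimates, norm$totals)

  # --- funnel (five-column layout) --------------------------------------
  funnel <- data.frame(
    slice = names(sim$reads),
    n_raw_pairs = vapply(qc_stats, `[[`, integer(1), "n_raw_pairs"),
    n_filtered_pairs = vapply(qc_stats, `[[`, integer(1), "n_filtered_pairs"),
    n_merged = prof$stats$n_merged[match(names(sim$reads),
                                         prof$stats$slice)],
    n_mapped = prof$stats$n_mapped[match(names(sim$reads),
                                         prof$stats$slice)],
    n_mapped_meiofauna = prof$stats$n_mapped_meiofauna[
      match(names(sim$reads), prof$stats$slice)],
    row.names = NULL, stringsAsFactors = FALSE)

  # --- stage 5: diversity per site x horizon ----------------------------
  bounds <- horizon_bounds(sim$cfg$horizon_scheme)
  sites <- site_names(sim$cfg)
  cores <- core_names(sim$cfg)
  div_rows <- list()
  for (si in sites) for (l in seq_along(sim$cfg$horizon_scheme)) {
    slices <- slice_label(si, cores, bounds[l])
    slices <- slices[slices %in% colnames(zero$zeroed)]
    if (!length(slices)) next
    comb <- combine_replicates(zero$zeroed[, slices, drop = FALSE],
                               thickness_cm = sim$cfg$horizon_scheme[l])
    if (sum(comb$x) == 0) next
    for (q in c(0, 1)) {
      de <- diversity_estimate(comb$x, q, B = boot_B, seed = seed + l)
      div_rows[[length(div_rows) + 1L]] <- data.frame(
        site = si, horizon_top_cm = bounds[l], q = q,
        observed = de$observed, estimated = de$estimated, se = de$se,
        ci_lo = de$ci95[1], ci_hi = de$ci95[2],
        stringsAsFactors = FALSE)
    }
  }
  diversity <- do.call(rbind, div_rows)

  # --- stage 6: community ----------------------------------------------
  bc <- bray_curtis(zero$zeroed)
  tree <- profile_dendrogram(bc$s)
  groups <- cut_dendrogram_at_similarity(tree, dendro_cut_similarity)
  ptest <- tryCatch(
    pairwise_permutation_test(groups, bc$s, n_perm = n_perm, seed = seed),
    error = function(e) NULL)
  # abiotic rows matched to the profile slices via site + horizon
  ids <- colnames(bc$s)
  ab <- sim$abiotic
  key_ab <- paste(ab$site, ab$horizon_top_cm)
  slice_site <- sub("([A-Z]+[0-9]+)[A-Z][0-9]+$", "\\1", ids)
  slice_top <- sub("^[A-Z]+[0-9]+[A-Z]", "", ids)
  rows <- match(paste(slice_site, slice_top), key_ab)
  abiotic_vars <- ab[rows, c("protein", "carbohydrate", "silt_clay_ratio",
                             "sand_percent", "oxygen", "depth_m",
                             "horizon_cm")]
  be <- bioenv(bc$s, abiotic_vars, n_perm = n_perm, seed = seed)
  site_sets <- lapply(stats::setNames(sites, sites), function(si) {
    cols <- grep(paste0("^", si, "[A-Z]"), colnames(zero$zeroed), value = TRUE)
    rownames(zero$zeroed)[rowSums(zero$zeroed[, cols, drop = FALSE]) > 0]
  })
  shared <- shared_asv_matrix(site_sets)

  out <- list(library = lib, funnel = funnel, profiles = prof,
              normalized = norm, zeroing = zero, diversity = diversity,
              community = list(similarity = bc$s, tree = tree,
                               groups = groups, pairwise = ptest,
                               bioenv = be, shared = shared))
  class(out) <- "meiobar_result"
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(outdir, f), sep = "\t", quote = FALSE,
    row.names = is.null(colnames(x)) || !is.data.frame(x))
  wt(res$funnel, "funnel.tsv")
  wt(res$profiles$matrix, "profiles.tsv")
  wt(res$zeroing$zeroed, "abundance_zeroed.tsv")
  wt(data.frame(slice = names(res$zeroing$index),
                index = res$zeroing$index, row.names = NULL),
     "slice_index.tsv")
  if (!is.null(res$diversity)) wt(res$diversity, "diversity.tsv")
  writeLines(upgma_newick(res$community$tree),
             file.path(outdir, "dendrogram.nwk"))
  wt(res$community$bioenv$by_size, "bioenv.tsv")
  wt(res$community$shared$pct, "shared_asv_pct.tsv")
  fa <- stats::setNames(res$library$asvs$sequence,
                        paste(res$library$asvs$asv_id,
                              res$library$asvs$cluster_id,
                              res$library$asvs$taxonomy_label,
                              res$library$asvs$functional_group, sep = "|"))
  write_fasta(fa, file.path(outdir, "reference_library.fasta"))
  invisible(outdir)
}
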