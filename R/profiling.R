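# Read mapping against the species-proxy reference and per-slice profiles.

#' Read-mapping parameters
#'
#' A hit is admissible iff its mismatch fraction (mismatched columns over
#' aligned non-gap columns) is at most `max_mismatch_fraction`, its total
#' gapped fraction (gap columns over read length) at most
#' `max_gap_fraction`, and no individual gap exceeds `max_gap_length_bp`.
#' All thresholds are inclusive.
#'
#' @param max_mismatch_fraction allowed read dissimilarity (default 0.03).
#' @param max_gap_fraction allowed total gap fraction (default 0.01).
#' @param max_gap_length_bp longest allowed individual gap (default 3).
#' @param exhaustive if `TRUE`, align against every reference ASV; if
#'   `FALSE` (default) a shared k-mer pre-filter restricts the candidate set
#'   first. Both paths give identical assignments; the filter only skips
#'   references that cannot be admissible hits.
#' @param kmer k-mer size of the pre-filter.
#' @return an object of class `mapping_params`.
#' @export
mapping_params <- function(max_mismatch_fraction = 0.03,
                           max_gap_fraction = 0.01,
                           max_gap_length_bp = 3L,
                           exhaustive = FALSE,
                           kmer = 12L) {
  assert_that(max_mismatch_fraction >= 0 && max_mismatch_fraction <= 1 &&
                max_gap_fraction >= 0 && max_gap_fraction <= 1,
              "fractions must lie in [0, 1]")
  assert_that(max_gap_length_bp >= 0, "max_gap_length_bp must be >= 0")
  structure(list(max_mismatch_fraction = max_mismatch_fraction,
                 max_gap_fraction = max_gap_fraction,
                 max_gap_length_bp = as.integer(max_gap_length_bp),
                 exhaustive = isTRUE(exhaustive), kmer = as.integer(kmer)),
            class = "mapping_params")
}

# alignment statistics between read and reference (global alignment)
alignment_stats <- function(read, ref) {
  al <- Biostrings::pairwiseAlignment(
    read, ref, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 1, gapExtension = 1)
  a <- chars(as.character(Biostrings::alignedPattern(al)))
  b <- chars(as.character(Biostrings::alignedSubject(al)))
  gap <- a == "-" | b == "-"
  cmp <- !gap
  mism <- sum(a[cmp] != b[cmp])
  # individual gap run lengths across both rows
  runs <- integer(0)
  if (any(gap)) {
    r <- rle(gap)
    runs <- r$lengths[r$values]
  }
  list(mismatches = mism, aligned_cols = sum(cmp),
       gap_cols = sum(gap), max_gap = if (length(runs)) max(runs) else 0L)
}

kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

# positional (non-unique) k-mers of a read
kmer_vec <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

# precompute per-ASV k-mer sets (forward strand; reads are checked on both)
build_kmer_index <- function(seqs, k) lapply(seqs, kmer_set, k = k)

# Sound candidate filter: a read of length L admissible against a reference
# (<= m substitutions, <= g gap columns) retains at least
# (L - k + 1) - k * (m + g) of its positional k-mers verbatim in the
# reference, so any reference sharing fewer cannot be an admissible hit.
kmer_candidates <- function(read, index, params) {
  L <- nchar(read)
  budget <- ceiling(params$max_mismatch_fraction * L) +
    ceiling(params$max_gap_fraction * L) + 1L   # slack for gap columns
  min_shared <- (L - params$kmer + 1L) - params$kmer * budget
  if (min_shared <= 0) return(seq_along(index))
  kv_f <- kmer_vec(read, params$kmer)
  kv_r <- kmer_vec(revcomp(read), params$kmer)
  shared <- vapply(index, function(ks)
    max(sum(kv_f %in% ks), sum(kv_r %in% ks)), numeric(1))
  which(shared >= min_shared)
}

#' Map one merged read against the reference library
#'
#' The read (and its reverse complement) is compared to the reference ASVs;
#' among admissible hits (see [mapping_params()]) the ASV with the smallest
#' distance `(mismatches + gap columns) / aligned columns` wins. The read is
#' assigned to that ASV's cluster; `"other"` if the cluster is
#' non-meiofaunal; `"unmapped"` if no admissible hit exists. Ties between
#' equally distant ASVs in different clusters go to the cluster with more
#' reads so far in the slice (`tally`), then to the lexicographically
#' smallest cluster id.
#'
#' @param read merged read sequence.
#' @param lib a `ref_library`.
#' @param params a [mapping_params()].
#' @param tally optional named numeric of reads already assigned per cluster
#'   in the current slice (used only for tie-breaking).
#' @param index optional precomputed k-mer index (internal use).
#' @return the winning `cluster_id`, `"other"` or `"unmapped"`.
#' @export
map_read <- function(read, lib, params = mapping_params(), tally = NULL,
                     index = NULL) {
  assert_that(nrow(lib$asvs) > 0, "configuration error: empty reference library")
  refs <- stats::setNames(lib$asvs$sequence, lib$asvs$asv_id)
  # exact-match fast path (identical to a reference on either strand)
  hit <- match(read, refs)
  if (is.na(hit)) hit <- match(revcomp(read), refs)
  if (!is.na(hit)) {
    cand_stats <- list(list(idx = hit, dist = 0))
  } else {
    cand <- seq_along(refs)
    if (!params$exhaustive) {
      if (is.null(index)) index <- build_kmer_index(refs, params$kmer)
      cand <- kmer_candidates(read, index, params)
      if (!length(cand)) return("unmapped")
    }
    cand_stats <- list()
    pick <- function(s) (s$mismatches + s$gap_cols) / max(s$aligned_cols, 1L)
    admissible <- function(s) s$aligned_cols > 0 &&
      s$mismatches / s$aligned_cols <= params$max_mismatch_fraction &&
      s$gap_cols / nchar(read) <= params$max_gap_fraction &&
      s$max_gap <= params$max_gap_length_bp
    rc_read <- revcomp(read)
    L <- nchar(read)
    gap_budget <- floor(params$max_gap_fraction * L)
    # one strand against one reference: Hamming fast path when lengths are
    # equal (an ungapped alignment with <= 3% mismatches is optimal, since
    # any gap costs more than the mismatches it could remove), full
    # alignment otherwise
    strand_stats <- function(rd, rf) {
      if (nchar(rd) == nchar(rf)) {
        h <- str_mismatches(rd, rf)
        if (h / nchar(rd) <= params$max_mismatch_fraction)
          return(list(mismatches = h, aligned_cols = nchar(rd),
                      gap_cols = 0L, max_gap = 0L))
      }
      alignment_stats(rd, rf)
    }
    for (i in cand) {
      # a length difference forces at least that many gap columns
      if (abs(L - nchar(refs[[i]])) > gap_budget) next
      st <- strand_stats(read, refs[[i]])
      # try the opposite strand only when the forward strand fails
      if (!admissible(st)) {
        st_rc <- strand_stats(rc_read, refs[[i]])
        if (admissible(st_rc)) st <- st_rc
      }
      if (admissible(st))
        cand_stats <- c(cand_stats, list(list(idx = i, dist = pick(st))))
    }
    if (!length(cand_stats)) return("unmapped")
  }
  dists <- vapply(cand_stats, `[[`, numeric(1), "dist")
  best <- which(dists == min(dists))
  clusters <- lib$asvs$cluster_id[vapply(cand_stats[best], `[[`,
                                         integer(1), "idx")]
  cl <- unique(clusters)
  if (length(cl) > 1L) {
    t0 <- if (is.null(tally)) stats::setNames(numeric(length(cl)), cl) else
      stats::setNames(ifelse(is.na(tally[cl]), 0, tally[cl]), cl)
    cl <- cl[order(-t0, cl)]
  }
  win <- cl[1L]
  fg <- lib$clusters$functional_group[match(win, lib$clusters$cluster_id)]
  if (!identical(fg, "meiofauna")) "other" else win
}

#' Profile one slice: tally mapped reads per species-proxy cluster
#'
#' Maps every merged read of a slice and tallies outcomes. The counts
#' partition the input: `sum(reads_per_cluster) + n_mapped_other +
#' n_unmapped` equals the number of merged reads.
#'
#' @param reads character vector of merged read sequences for one slice.
#' @param lib a `ref_library`.
#' @param params a [mapping_params()].
#' @return list of class `slice_profile`: `reads_per_cluster` (named integer
#'   over meiofaunal clusters with at least the observed clusters present),
#'   `n_mapped_other`, `n_unmapped`, `n_total`.
#' @export
profile_slice <- function(reads, lib, params = mapping_params()) {
  refs <- stats::setNames(lib$asvs$sequence, lib$asvs$asv_id)
  index <- if (!params$exhaustive) build_kmer_index(refs, params$kmer)
  tally <- numeric(0)
  n_other <- 0L; n_unmapped <- 0L
  # map each unique sequence once; identical reads get identical outcomes
  uniq <- table(as.character(reads))
  useqs <- as.character(names(uniq))
  mult <- as.integer(uniq)
  # order by multiplicity so the tie-break tally reflects abundant reads first
  ord <- if (length(useqs)) order(-mult, useqs) else integer(0)
  for (k in ord) {
    res <- map_read(useqs[k], lib, params, tally = tally, index = index)
    if (res == "unmapped") n_unmapped <- n_unmapped + mult[k]
    else if (res == "other") n_other <- n_other + mult[k]
    else tally[res] <- (if (is.na(tally[res])) 0L else tally[res]) + mult[k]
  }
  if (length(tally)) tally <- tally[order(names(tally))]
  tally <- stats::setNames(as.integer(tally), names(tally))
  structure(list(reads_per_cluster = tally, n_mapped_other = n_other,
                 n_unmapped = n_unmapped, n_total = length(reads)),
            class = "slice_profile")
}

#' Profile all slices into a cluster-by-slice read-count matrix
#'
#' @param read_sets named list (slice id -> character vector of merged
#'   reads).
#' @param lib a `ref_library`.
#' @param params a [mapping_params()].
#' @return list with `matrix` (meiofaunal clusters x slices, read counts),
#'   and `stats` (data.frame per slice: n_merged, n_mapped, n_mapped_other,
#'   n_mapped_meiofauna, n_unmapped).
#' @export
profile_matrix <- function(read_sets, lib, params = mapping_params()) {
  profs <- lapply(read_sets, profile_slice, lib = lib, params = params)
  meio <- lib$clusters$cluster_id[lib$clusters$functional_group == "meiofauna"]
  m <- matrix(0L, length(meio), length(profs),
              dimnames = list(sort(meio), names(read_sets)))
  for (s in names(profs)) {
    rc <- profs[[s]]$reads_per_cluster
    m[names(rc), s] <- as.integer(rc)
  }
  stats <- data.frame(
    slice = names(profs),
    n_merged = vapply(profs, function(p) p$n_total, integer(1)),
    n_mapped = vapply(profs, function(p)
      as.integer(sum(p$reads_per_cluster) + p$n_mapped_other), integer(1)),
    n_mapped_meiofauna = vapply(profs, function(p)
      as.integer(sum(p$reads_per_cluster)), integer(1)),
    n_mapped_other = vapply(profs, function(p) p$n_mapped_other, integer(1)),
    n_unmapped = vapply(profs, function(p) p$n_unmapped, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(matrix = m, stats = stats)
}
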