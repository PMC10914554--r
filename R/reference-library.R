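# Species-proxy reference library: pairwise p-distances, group-average
# (UPGMA) agglomeration with a deterministic tie rule, the 3% dissimilarity
# cut into ASV-3 clusters, library merging and functional-group partition.

# p-distance between two aligned strings: mismatches / compared positions,
# where positions containing a gap or N in either sequence are excluded.
aligned_p_distance <- function(a, b) {
  av <- chars(a); bv <- chars(b)
  cmp <- av != "-" & bv != "-" & av != "N" & bv != "N"
  n_cmp <- sum(cmp)
  if (n_cmp == 0L)
    stop("undefined distance: no comparable (non-gap, non-N) positions",
         call. = FALSE)
  sum(av[cmp] != bv[cmp]) / n_cmp
}

p_dist_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1,
                                           baseOnly = FALSE)
}

#' Pairwise p-distance between two sequences
#'
#' Sequences are globally aligned (Needleman-Wunsch; match 0, mismatch 1,
#' gap 1 per position, plus a small gap-opening penalty of 0.5 so that a
#' gapped alignment never ties with an equal-cost ungapped one and the
#' distance is well defined) and the p-distance is the fraction of
#' mismatched positions among aligned positions, excluding columns where
#' either sequence has a gap or an N.
#'
#' @param a,b nucleotide strings.
#' @return p-distance in \[0, 1\].
#' @export
p_distance <- function(a, b) {
  assert_that(nchar(a) > 0 && nchar(b) > 0, "sequences must be non-empty")
  if (a == b) {
    if (!grepl("[ACGT]", a))
      stop("undefined distance: no comparable (non-gap, non-N) positions",
           call. = FALSE)
    return(0)
  }
  al <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = p_dist_submat(),
    gapOpening = 0.5, gapExtension = 1)
  aligned_p_distance(as.character(Biostrings::alignedPattern(al)),
                     as.character(Biostrings::alignedSubject(al)))
}

#' Pairwise p-distance matrix over a set of ASVs
#'
#' Computes [p_distance()] for every pair; the matrix is by construction
#' identical to the brute-force loop over all pairs.
#'
#' @param seqs named character vector of ASV sequences (names are ASV ids).
#' @return symmetric matrix of p-distances with zero diagonal, dimnames =
#'   ASV ids.
#' @export
build_distance_matrix <- function(seqs) {
  n <- length(seqs)
  assert_that(n >= 2, "need at least two ASVs")
  assert_that(!is.null(names(seqs)) && !anyDuplicated(names(seqs)),
              "sequences must carry unique ASV ids as names")
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    dd <- tryCatch(p_distance(seqs[[i]], seqs[[j]]), error = function(e)
      stop("distance undefined for pair (", names(seqs)[i], ", ",
           names(seqs)[j], "): ", conditionMessage(e), call. = FALSE))
    d[i, j] <- d[j, i] <- dd
  }
  d
}

#' Group-average (UPGMA) agglomeration with deterministic tie-breaking
#'
#' Classic UPGMA: the distance between two clusters is the arithmetic mean
#' of all cross-pair distances (pair-count weighted, via the Lance-Williams
#' update). When two candidate merges share the same height, the pair whose
#' lexicographically smallest member id is smallest is merged first (residual
#' ties broken by the partner cluster's smallest id), which makes the tree
#' independent of input order.
#'
#' @param d symmetric distance matrix with dimnames.
#' @return a list of class `upgma_tree` with `merges` (data.frame: height and
#'   the member ids of each merged pair's clusters), `heights`, `labels`, and
#'   an `hclust`-compatible representation in `$hclust`.
#' @export
upgma_tree <- function(d) {
  labs <- rownames(d)
  n <- length(labs)
  assert_that(n >= 1, "empty distance matrix")
  assert_that(isTRUE(all.equal(d, t(d))), "distance matrix must be symmetric")
  # active cluster bookkeeping
  members <- as.list(seq_len(n))            # row indices per cluster
  minlab <- labs                            # smallest member label
  sizes <- rep(1L, n)
  node <- -seq_len(n)                       # hclust coding: negative = leaf
  dd <- d
  diag(dd) <- Inf
  merge <- matrix(0L, max(n - 1L, 0L), 2L)
  height <- numeric(max(n - 1L, 0L))
  active <- rep(TRUE, n)
  idx <- seq_len(n)
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    sub <- dd[act, act, drop = FALSE]
    h <- min(sub)
    # all pairs attaining the minimum
    w <- which(sub == h, arr.ind = TRUE)
    w <- w[w[, 1] < w[, 2], , drop = FALSE]
    cand_i <- act[w[, 1]]; cand_j <- act[w[, 2]]
    lo <- pmin(minlab[cand_i], minlab[cand_j])
    hi <- pmax(minlab[cand_i], minlab[cand_j])
    pick <- order(lo, hi)[1L]
    i <- cand_i[pick]; j <- cand_j[pick]
    merge[step, ] <- c(node[i], node[j])
    height[step] <- h
    # Lance-Williams average update into slot i
    others <- setdiff(act, c(i, j))
    if (length(others)) {
      dd[i, others] <- (sizes[i] * dd[i, others] + sizes[j] * dd[j, others]) /
        (sizes[i] + sizes[j])
      dd[others, i] <- dd[i, others]
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    minlab[i] <- min(minlab[i], minlab[j])
    node[i] <- step
    active[j] <- FALSE
    dd[j, ] <- Inf; dd[, j] <- Inf
  }
  hc <- list(merge = merge, height = height, labels = labs,
             method = "average", order = upgma_order(merge, n),
             call = match.call(), dist.method = "p-distance")
  class(hc) <- "hclust"
  structure(list(heights = height, labels = labs, hclust = hc),
            class = "upgma_tree")
}

# leaf order for plotting: in-order traversal of the merge matrix
upgma_order <- function(merge, n) {
  if (n == 1L) return(1L)
  walk <- function(k) {
    if (k < 0) return(-k)
    c(walk(merge[k, 1]), walk(merge[k, 2]))
  }
  walk(nrow(merge))
}

#' Cut a UPGMA tree strictly below a dissimilarity threshold
#'
#' Clusters are the connected components formed by all merges with height
#' strictly below `cut`: a merge at exactly the threshold does not join
#' clusters.
#'
#' @param tree an [upgma_tree()].
#' @param cut dissimilarity threshold in (0, 1\].
#' @return named integer vector of cluster indices (1-based, numbered by
#'   the order of each cluster's smallest label).
#' @export
cut_upgma <- function(tree, cut = 0.03) {
  assert_that(cut > 0 && cut <= 1, "configuration error: cut must lie in (0, 1]")
  labs <- tree$labels
  n <- length(labs)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  hc <- tree$hclust
  node_rep <- integer(max(n - 1L, 0L))  # representative leaf of each merge
  for (k in seq_len(n - 1L)) {
    a <- hc$merge[k, 1]; b <- hc$merge[k, 2]
    ra <- if (a < 0) -a else node_rep[a]
    rb <- if (b < 0) -b else node_rep[b]
    node_rep[k] <- ra
    if (hc$height[k] < cut) parent[find(rb)] <- find(ra)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  # number clusters by their smallest member label
  smallest <- tapply(labs, roots, min)
  lev <- names(sort(smallest))
  out <- match(as.character(roots), lev)
  names(out) <- labs
  out
}

#' Cluster ASVs into species-proxy (ASV-3) clusters
#'
#' Group-average agglomeration of the p-distance matrix, cut strictly below
#' `cut` (default 3% dissimilarity).
#'
#' @param d distance matrix from [build_distance_matrix()].
#' @param cut dissimilarity threshold.
#' @return named integer vector: ASV id -> cluster index.
#' @export
group_average_cluster <- function(d, cut = 0.03) {
  cut_upgma(upgma_tree(d), cut)
}

#' Build a species-proxy reference library
#'
#' Removes short sequences, deduplicates exact duplicates, computes the
#' p-distance matrix, clusters at the 3% group-average cut and attaches
#' taxonomy labels and functional groups. Cluster representatives are the
#' longest member (ties by id); a cluster's taxonomy label and functional
#' group are taken from its representative.
#'
#' @param seqs named character vector of ASV sequences.
#' @param taxonomy data.frame with columns `asv_id`, `taxonomy_label`
#'   (format `Taxon_serial`, e.g. `Nematoda_12`).
#' @param group_table data.frame with columns `taxon`, `functional_group`
#'   (`"meiofauna"` or `"other"`) mapping the label's taxon part; unmapped
#'   taxa default to `"other"` with a warning.
#' @param cut dissimilarity threshold (default 0.03).
#' @param min_length_bp sequences shorter than this are dropped (default 325,
#'   the short-sequence purge applied to the barcode library).
#' @return an object of class `ref_library`: list with `asvs` (data.frame:
#'   asv_id, sequence, length_bp, taxonomy_label, functional_group,
#'   cluster_id), `clusters` (data.frame: cluster_id, representative_id,
#'   taxonomy_label, functional_group, n_members), `cut`, and `tree`.
#' @export
build_reference_library <- function(seqs, taxonomy, group_table = NULL,
                                    cut = 0.03, min_length_bp = 325L) {
  assert_that(length(seqs) > 0, "empty ASV set")
  short <- nchar(seqs) < min_length_bp
  if (any(short)) {
    message("dropping ", sum(short), " sequence(s) shorter than ",
            min_length_bp, " bp: ", paste(names(seqs)[short], collapse = ", "))
    seqs <- seqs[!short]
  }
  dup <- duplicated(unname(seqs))
  seqs <- seqs[!dup]
  n <- length(seqs)
  assert_that(n > 0, "no sequences survive the length filter")
  if (n >= 2) {
    d <- build_distance_matrix(seqs)
    tree <- upgma_tree(d)
    part <- cut_upgma(tree, cut)
  } else {
    tree <- NULL
    part <- stats::setNames(1L, names(seqs))
  }
  cluster_id <- sprintf("ASV3_%04d", part)
  asvs <- data.frame(asv_id = names(seqs), sequence = unname(seqs),
                     length_bp = nchar(unname(seqs)),
                     stringsAsFactors = FALSE)
  asvs$taxonomy_label <- taxonomy$taxonomy_label[
    match(asvs$asv_id, taxonomy$asv_id)]
  asvs$functional_group <- assign_functional_group(asvs$taxonomy_label,
                                                   group_table)
  asvs$cluster_id <- cluster_id
  clusters <- do.call(rbind, lapply(split(asvs, asvs$cluster_id), function(g) {
    rep_id <- g$asv_id[order(-g$length_bp, g$asv_id)][1L]
    data.frame(cluster_id = g$cluster_id[1L], representative_id = rep_id,
               taxonomy_label = g$taxonomy_label[match(rep_id, g$asv_id)],
               functional_group = g$functional_group[match(rep_id, g$asv_id)],
               n_members = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(clusters) <- NULL
  structure(list(asvs = asvs, clusters = clusters, cut = cut, tree = tree),
            class = "ref_library")
}

# taxon part of a label like "Nematoda_12"
label_taxon <- function(label) sub("_[0-9]+$", "", label)

assign_functional_group <- function(labels, group_table) {
  taxa <- label_taxon(labels)
  if (is.null(group_table)) {
    default_meio <- c(HARD_GROUPS, SOFT_GROUPS, "Annelida", "Arthropoda")
    return(ifelse(taxa %in% default_meio, "meiofauna", "other"))
  }
  fg <- group_table$functional_group[match(taxa, group_table$taxon)]
  unmapped <- is.na(fg)
  if (any(unmapped)) {
    warning("unmapped taxa defaulted to 'other': ",
            paste(unique(taxa[unmapped]), collapse = ", "))
    fg[unmapped] <- "other"
  }
  fg
}

#' Partition a reference library by functional annotation
#'
#' Splits the ASV-3 clusters into the meiofaunal set (used for read mapping)
#' and the rest, and tabulates cluster counts per taxon in the layout of a
#' per-phylum annotation summary.
#'
#' @param lib a [build_reference_library()] object.
#' @return list with `meiofauna` and `other` (cluster data.frames) and
#'   `summary` (data.frame: functional_group, taxon, n_clusters).
#' @export
partition_by_annotation <- function(lib) {
  cl <- lib$clusters
  meio <- cl[cl$functional_group == "meiofauna", , drop = FALSE]
  other <- cl[cl$functional_group != "meiofauna", , drop = FALSE]
  if (nrow(cl)) {
    tab <- stats::aggregate(
      list(n_clusters = cl$cluster_id),
      by = list(functional_group = cl$functional_group,
                taxon = label_taxon(cl$taxonomy_label)),
      FUN = length)
    tab <- tab[order(tab$functional_group, tab$taxon), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(functional_group = character(0), taxon = character(0),
                      n_clusters = integer(0))
  }
  list(meiofauna = meio, other = other, summary = tab)
}

#' Merge an existing reference library with new ASVs
#'
#' Old ASVs are trimmed to the coordinate window of the new barcode (the
#' region amplified by the new primer pair), concatenated with the new ASVs,
#' deduplicated on exact sequence, and the whole pool is re-clustered from
#' scratch at the same cut. Trimmed sequences falling below the length floor
#' are dropped with a logged reason.
#'
#' @param old a `ref_library`.
#' @param new_seqs named character vector of new ASV sequences.
#' @param new_taxonomy taxonomy data.frame for the new ASVs (see
#'   [build_reference_library()]).
#' @param trim_to integer pair (start, end): 1-based coordinate window the
#'   old sequences are trimmed to; `NULL` keeps them whole.
#' @param group_table optional functional-group mapping table.
#' @param min_length_bp length floor applied after trimming.
#' @return a new `ref_library` over the combined pool.
#' @export
merge_libraries <- function(old, new_seqs, new_taxonomy = NULL,
                            trim_to = NULL, group_table = NULL,
                            min_length_bp = 325L) {
  old_seqs <- stats::setNames(old$asvs$sequence, old$asvs$asv_id)
  if (!is.null(trim_to)) {
    old_seqs <- vapply(old_seqs, function(s)
      substr(s, trim_to[1], min(trim_to[2], nchar(s))), character(1))
  }
  tax <- rbind(
    old$asvs[, c("asv_id", "taxonomy_label")],
    if (length(new_seqs))
      data.frame(asv_id = names(new_seqs),
                 taxonomy_label = if (is.null(new_taxonomy))
                   NA_character_ else
                     new_taxonomy$taxonomy_label[
                       match(names(new_seqs), new_taxonomy$asv_id)],
                 stringsAsFactors = FALSE))
  pool <- c(old_seqs, new_seqs)
  # deduplicate on exact sequence, keeping the first (old-library) copy
  pool <- pool[!duplicated(unname(pool))]
  build_reference_library(pool, tax, group_table = group_table, cut = old$cut,
                          min_length_bp = min_length_bp)
}
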