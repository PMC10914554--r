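# Resemblance-based community statistics: square-root transform and
# Bray-Curtis similarity, group-average dendrogram of slice profiles,
# pairwise PERMANOVA permutation tests, the BIOENV abiotic best-subset
# search with a permutation significance threshold, and shared-ASV matrices.

#' Bray-Curtis similarity matrix of slice profiles
#'
#' Abundances are square-root transformed (damping dominant taxa) and the
#' Bray-Curtis similarity `100 * (1 - sum|u - v| / sum(u + v))` computed
#' between every pair of slices. Identical profiles score 100, disjoint
#' profiles 0. Pairs of all-zero profiles have undefined similarity; such
#' slices are excluded with a flag.
#'
#' @param m abundance matrix, clusters x slices (non-negative).
#' @param transform `"sqrt"` (default) or `"none"`.
#' @return list with `s` (similarity matrix in \[0, 100\], slices x slices)
#'   and `excluded` (all-zero slices).
#' @export
bray_curtis <- function(m, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  assert_that(all(m >= 0), "abundances must be non-negative")
  zero <- colSums(m) == 0
  excluded <- colnames(m)[zero]
  m <- m[, !zero, drop = FALSE]
  if (transform == "sqrt") m <- sqrt(m)
  n <- ncol(m)
  s <- matrix(100, n, n, dimnames = list(colnames(m), colnames(m)))
  if (n >= 2) for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    u <- m[, i]; v <- m[, j]
    s[i, j] <- s[j, i] <- 100 * (1 - sum(abs(u - v)) / sum(u + v))
  }
  list(s = s, excluded = excluded)
}

#' Group-average dendrogram of a similarity matrix
#'
#' Converts similarity (0-100) to dissimilarity (100 - s) and applies the
#' same deterministic UPGMA engine used for the reference library. The tree
#' can be cut at stated similarity levels (e.g. 20% and 40%).
#'
#' @param s similarity matrix from [bray_curtis()].
#' @return an `upgma_tree` (heights on the dissimilarity scale 0-100).
#' @export
profile_dendrogram <- function(s) {
  d <- 100 - s
  diag(d) <- 0
  upgma_tree(d)
}

#' Cut a profile dendrogram at a similarity level
#'
#' @param tree output of [profile_dendrogram()].
#' @param similarity similarity percentage (e.g. 40); groups are merges at
#'   dissimilarity strictly below `100 - similarity`.
#' @return named integer vector of group memberships.
#' @export
cut_dendrogram_at_similarity <- function(tree, similarity) {
  cut_upgma_raw(tree, 100 - similarity)
}

# cut_upgma without the (0,1] range restriction (heights on 0-100 scale)
cut_upgma_raw <- function(tree, cut) {
  tr <- tree
  tr$hclust$height <- tr$hclust$height / 100
  tr$heights <- tr$heights / 100
  cut_upgma(tr, cut / 100)
}

# PERMANOVA pseudo-F for a squared-dissimilarity decomposition on groups
permanova_F <- function(d2, groups) {
  n <- length(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  k <- length(unique(groups))
  ((ss_total - ss_within) / (k - 1)) / (ss_within / (n - k))
}

#' Pairwise permutation tests between profile groups
#'
#' For each pair of groups, a one-way PERMANOVA pseudo-F is computed on the
#' dissimilarity matrix and compared with its distribution under
#' unrestricted permutation of group labels:
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`. Groups of size one are
#' skipped with a warning.
#'
#' @param groups named vector of group memberships (names = slice ids).
#' @param s similarity (0-100) or dissimilarity matrix over the same ids;
#'   interpreted as similarity when its diagonal is 100.
#' @param n_perm number of permutations (default 10000, the cap used for
#'   the pairwise tests).
#' @param seed RNG seed.
#' @return data.frame: group1, group2, F_obs, p_value, significant
#'   (p < .05).
#' @export
pairwise_permutation_test <- function(groups, s, n_perm = 10000L,
                                      seed = NULL) {
  ids <- names(groups)
  assert_that(!is.null(ids) && all(ids %in% rownames(s)),
              "groups must be named by slice ids present in the matrix")
  d <- if (all(diag(s) == 100)) 100 - s else s
  d2 <- (d[ids, ids])^2
  glev <- unique(groups)
  assert_that(length(glev) >= 2, "need at least two groups")
  pairs <- utils::combn(as.character(glev), 2, simplify = FALSE)
  rows <- list()
  with_seed(seed, {
    for (pr in pairs) {
      idx <- which(groups %in% pr)
      if (min(table(groups[idx])) < 2) {
        warning("pair (", pr[1], ", ", pr[2], ") skipped: group of size 1")
        next
      }
      sub <- d2[idx, idx]
      g <- as.character(groups[idx])
      F_obs <- permanova_F(sub, g)
      count <- 0L
      for (b in seq_len(n_perm)) {
        if (permanova_F(sub, sample(g)) >= F_obs) count <- count + 1L
      }
      p <- (1 + count) / (1 + n_perm)
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = pr[1], group2 = pr[2], F_obs = F_obs, p_value = p,
        significant = p < 0.05, stringsAsFactors = FALSE)
    }
  })
  if (!length(rows))
    return(data.frame(group1 = character(0), group2 = character(0),
                      F_obs = numeric(0), p_value = numeric(0),
                      significant = logical(0)))
  do.call(rbind, rows)
}

# Spearman rank correlation with average ranks for ties
spearman_rho <- function(a, b) stats::cor(rank(a), rank(b))

# lower-triangle vector of a square matrix
lower_vec <- function(m) m[lower.tri(m)]

# Euclidean distance vector (lower triangle) over a column subset of a
# standardised abiotic matrix
euclid_vec <- function(z, cols) {
  lower_vec(as.matrix(stats::dist(z[, cols, drop = FALSE])))
}

#' BIOENV: best abiotic-variable subset by rank correlation
#'
#' Exhaustively searches all non-empty subsets of the abiotic variables for
#' the subset whose Euclidean inter-sample distances (on standardised
#' columns) maximise the Spearman rank correlation with the biotic
#' dissimilarities. Significance is assessed against a permutation
#' threshold: for each of `n_perm` random permutations of the sample
#' identities of the abiotic table, the full best-subset search is repeated
#' and the maximal achievable rho recorded; the observed best rho is
#' significant iff it exceeds the maximum of these.
#'
#' @param biotic similarity (0-100, diagonal 100) or dissimilarity matrix of
#'   the slice profiles.
#' @param abiotic data.frame of abiotic variables (rows matching the order
#'   of `biotic`'s ids); constant columns are excluded with a warning.
#' @param n_perm permutations for the significance threshold (0 skips it).
#' @param seed RNG seed.
#' @return object of class `bioenv_result`: list with `best_subset`
#'   (character), `rho`, `by_size` (data.frame: size, subset, rho),
#'   `permutation_threshold`, `n_permutations`, `significant`.
#' @export
bioenv <- function(biotic, abiotic, n_perm = 99L, seed = NULL) {
  assert_that(nrow(abiotic) == nrow(biotic) && nrow(biotic) >= 3,
              "need >= 3 matched samples")
  d <- if (all(diag(as.matrix(biotic)) == 100)) 100 - biotic else biotic
  db <- rank(lower_vec(as.matrix(d)))
  z <- as.data.frame(abiotic)
  keep <- vapply(z, function(col) stats::sd(col) > 0, logical(1))
  if (!all(keep))
    warning("constant abiotic column(s) excluded: ",
            paste(names(z)[!keep], collapse = ", "))
  z <- scale(as.matrix(z[, keep, drop = FALSE]))
  vars <- colnames(z)
  assert_that(length(vars) >= 1, "no non-constant abiotic variables")

  search_best <- function(zm) {
    best_rho <- -Inf; best_sub <- NULL
    by_size <- list()
    for (k in seq_along(vars)) {
      subs <- utils::combn(vars, k, simplify = FALSE)
      rhos <- vapply(subs, function(sb)
        stats::cor(db, rank(euclid_vec(zm, sb))), numeric(1))
      i <- which.max(rhos)
      by_size[[k]] <- data.frame(size = k,
                                 subset = paste(subs[[i]], collapse = "+"),
                                 rho = rhos[i], stringsAsFactors = FALSE)
      if (rhos[i] > best_rho) {
        best_rho <- rhos[i]; best_sub <- subs[[i]]
      }
    }
    list(rho = best_rho, subset = best_sub,
         by_size = do.call(rbind, by_size))
  }

  obs <- search_best(z)
  thr <- NA_real_
  if (n_perm > 0) {
    perm_max <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        search_best(z[sample(nrow(z)), , drop = FALSE])$rho
      }, numeric(1))
    })
    thr <- max(perm_max)
  }
  structure(list(best_subset = obs$subset, rho = obs$rho,
                 by_size = obs$by_size,
                 permutation_threshold = thr,
                 n_permutations = as.integer(n_perm),
                 significant = if (is.na(thr)) NA else obs$rho > thr),
            class = "bioenv_result")
}

#' Shared species-proxy percentage matrix between sites
#'
#' For every pair of sites, the percentage of shared ASV-3 clusters. The
#' default convention is the Jaccard form `|A intersect B| / |A union B| *
#' 100`; `"smaller"` divides by the smaller set instead. The diagonal is
#' 100.
#'
#' @param site_sets named list: site -> character vector of cluster ids
#'   present at the site.
#' @param convention `"union"` (default) or `"smaller"`.
#' @return list with `pct` (percentage matrix) and `flagged` (empty sites).
#' @export
shared_asv_matrix <- function(site_sets, convention = c("union", "smaller")) {
  convention <- match.arg(convention)
  assert_that(length(site_sets) > 0, "no site sets supplied")
  sets <- lapply(site_sets, unique)
  empty <- names(sets)[vapply(sets, length, integer(1)) == 0]
  sites <- names(sets)
  n <- length(sites)
  pct <- matrix(100, n, n, dimnames = list(sites, sites))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- sets[[i]]; b <- sets[[j]]
    inter <- length(intersect(a, b))
    denom <- if (convention == "union") length(union(a, b))
    else min(length(a), length(b))
    pct[i, j] <- if (denom == 0) NA_real_ else 100 * inter / denom
  }
  list(pct = pct, flagged = empty)
}

#' Export a UPGMA tree as Newick
#'
#' Branch lengths place each leaf at depth equal to the merge heights
#' (ultrametric), so the Newick string reproduces the dendrogram exactly.
#'
#' @param tree an `upgma_tree`.
#' @return single Newick string (terminated by `;`).
#' @export
upgma_newick <- function(tree) {
  hc <- tree$hclust
  n <- length(hc$labels)
  if (n == 1) return(paste0(hc$labels, ";"))
  node_str <- function(k, parent_h) {
    if (k < 0)
      return(paste0(hc$labels[-k], ":", format(parent_h, digits = 10)))
    h <- hc$height[k]
    paste0("(", node_str(hc$merge[k, 1], h), ",",
           node_str(hc$merge[k, 2], h), "):",
           format((parent_h - h), digits = 10))
  }
  top <- nrow(hc$merge)
  h <- hc$height[top]
  paste0("(", node_str(hc$merge[top, 1], h), ",",
         node_str(hc$merge[top, 2], h), ");")
}
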