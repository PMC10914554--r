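# Shared fixtures and independent oracles used across the suite.

# small, fast study configuration for integration-style tests
tiny_cfg <- function(seed = 7, reads_per_slice = 120, ...) {
  sim_config(n_sites = 2, depths_m = c(54, 394), n_cores_per_site = 2,
             n_species = 5, n_background_species = 2, n_other_species = 1,
             reads_per_slice = reads_per_slice, seed = seed, ...)
}

# brute-force Hamming p-distance for equal-length sequences (oracle)
hamming_p <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  keep <- av != "N" & bv != "N"
  sum(av[keep] != bv[keep]) / sum(keep)
}

# Naive group-average agglomeration oracle: recomputes the mean cross-pair
# distance from the ORIGINAL matrix at every step (no Lance-Williams
# update), merging the closest pair; ties by smallest member label. Returns
# the partition from cutting strictly below `cut`.
naive_upgma_partition <- function(d, cut) {
  labs <- rownames(d)
  groups <- lapply(seq_along(labs), function(i) i)
  repeat {
    k <- length(groups)
    if (k == 1) break
    best <- NULL
    for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
      h <- mean(d[groups[[i]], groups[[j]]])
      m1 <- min(labs[groups[[i]]]); m2 <- min(labs[groups[[j]]])
      key <- c(min(m1, m2), max(m1, m2))
      if (is.null(best) || h < best$h - 1e-12 ||
          (abs(h - best$h) <= 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(h = h, i = i, j = j, key = key)
      }
    }
    if (best$h >= cut) break
    groups[[best$i]] <- c(groups[[best$i]], groups[[best$j]])
    groups[[best$j]] <- NULL
  }
  out <- integer(length(labs))
  mins <- vapply(groups, function(g) min(labs[g]), character(1))
  num <- order(mins)   # number clusters by smallest member label
  for (r in seq_along(num)) out[groups[[num[r]]]] <- r
  stats::setNames(out, labs)
}

# adjusted Rand index between two labellings (independent of any package)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# brute-force background-zeroing oracle: scan all cell values (plus 0)
# ascending, zero cells strictly below tau, accept the first tau making
# every slice's counts/nnz index exceed 1 with nnz > 0
brute_force_tau <- function(est, totals) {
  taus <- sort(unique(c(0, est[est > 0])))
  for (tau in taus) {
    z <- est
    z[z < tau] <- 0
    nnz <- colSums(z > 0)
    if (all(nnz > 0 & totals[colnames(est)] / nnz > 1)) return(tau)
  }
  NA_real_
}

# random normalized abundance matrix with per-slice totals >= 2 (estimates
# sum to the totals, mimicking normalize_matrix output)
random_abundance_matrix <- function(n_clusters, n_slices) {
  totals <- stats::setNames(sample(2:60, n_slices, replace = TRUE),
                            paste0("s", seq_len(n_slices)))
  m <- matrix(0, n_clusters, n_slices,
              dimnames = list(paste0("c", seq_len(n_clusters)),
                              names(totals)))
  for (s in seq_len(n_slices)) {
    k <- sample(seq_len(n_clusters), 1)
    rows <- sample(n_clusters, k)
    w <- stats::runif(k)
    m[rows, s] <- w / sum(w) * totals[s]
  }
  list(est = m, totals = totals)
}
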