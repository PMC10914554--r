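test_that("p-distance matches direct mismatch counting", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)

  # equal-length 400-bp pair with 12 planted substitutions -> 0.03
  set.seed(12)
  a <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  v <- strsplit(a, "")[[1]]
  pos <- sample(400, 12)
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  b <- paste(v, collapse = "")
  expect_equal(p_distance(a, b), 0.03)
  expect_equal(p_distance(a, b), p_distance(b, a))

  # N positions are excluded from the denominator
  expect_equal(p_distance("ACGTN", "ACGAN"), 0.25)
  expect_error(p_distance("", "ACGT"), "non-empty")
  expect_error(p_distance("NNN", "NNN"), "comparable")
})

test_that("distance matrix equals the brute-force pairwise loop", {
  set.seed(4)
  seqs <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("a", 1:6)
  d <- build_distance_matrix(seqs)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 6))
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(d[i, j], p_distance(seqs[[i]], seqs[[j]]))

  # identical sequences give an all-zero matrix
  same <- stats::setNames(rep(seqs[1], 3), paste0("b", 1:3))
  expect_true(all(build_distance_matrix(same) == 0))
})

test_that("group-average clustering reproduces hand agglomeration", {
  d <- matrix(c(0, 0.01, 0.10,
                0.01, 0, 0.10,
                0.10, 0.10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  part <- group_average_cluster(d, cut = 0.03)
  expect_identical(part[["A"]], part[["B"]])
  expect_false(part[["A"]] == part[["C"]])

  # all distances above the cut: singletons
  d2 <- d; d2[d2 > 0] <- 0.5
  expect_identical(unname(group_average_cluster(d2, 0.03)), 1:3)

  # all distances zero: one cluster
  d3 <- d * 0
  expect_identical(unname(group_average_cluster(d3, 0.03)), rep(1L, 3))

  # a merge at exactly the cut height does not join clusters
  d4 <- matrix(c(0, 0.03, 0.03, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_identical(unname(group_average_cluster(d4, 0.03)), 1:2)

  expect_error(group_average_cluster(d, cut = 0), "configuration")
})

test_that("clustering equals naive exhaustive agglomeration for small n", {
  set.seed(20)
  for (rep in 1:150) {
    n <- sample(2:8, 1)
    v <- stats::runif(n * (n - 1) / 2)
    d <- matrix(0, n, n)
    d[lower.tri(d)] <- v
    d <- d + t(d)
    dimnames(d) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
    cut <- stats::runif(1, 0.1, 0.9)
    expect_identical(group_average_cluster(d, cut),
                     naive_upgma_partition(d, cut))
  }
})

test_that("clustering also agrees with hclust average linkage", {
  set.seed(30)
  for (rep in 1:40) {
    n <- sample(4:10, 1)
    v <- stats::runif(n * (n - 1) / 2)
    d <- matrix(0, n, n)
    d[lower.tri(d)] <- v
    d <- d + t(d)
    dimnames(d) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
    tree <- upgma_tree(d)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(sort(tree$heights), sort(hc$height))
    cut <- stats::runif(1, 0.1, 0.9)
    mine <- cut_upgma(tree, cut)
    ref <- stats::cutree(hc, h = cut - 1e-12)
    # same partition up to label numbering
    expect_equal(adjusted_rand_index(mine, ref), 1)
  }
})

test_that("input order does not change the partition", {
  set.seed(40)
  n <- 7
  v <- stats::runif(n * (n - 1) / 2)
  d <- matrix(0, n, n)
  d[lower.tri(d)] <- v
  d <- d + t(d)
  dimnames(d) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  base <- group_average_cluster(d, 0.5)
  for (rep in 1:10) {
    perm <- sample(n)
    dp <- d[perm, perm]
    pp <- group_average_cluster(dp, 0.5)
    expect_identical(pp[names(base)], base)
  }
})

test_that("library building drops short sequences and deduplicates", {
  set.seed(6)
  base <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  seqs <- c(a1 = base, a2 = base,                     # exact duplicates
            a3 = paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                       collapse = ""),
            short = substr(base, 1, 100))
  tax <- data.frame(asv_id = names(seqs),
                    taxonomy_label = c("Nematoda_1", "Nematoda_2",
                                       "Fungi_1", "Nematoda_3"))
  expect_message(lib <- build_reference_library(seqs, tax, cut = 0.03),
                 "dropping 1")
  expect_identical(nrow(lib$asvs), 2L)          # a2 deduplicated, short gone
  expect_identical(sort(lib$asvs$asv_id), c("a1", "a3"))
  expect_identical(nrow(lib$clusters), 2L)
  expect_setequal(lib$asvs$functional_group, c("meiofauna", "other"))
})

test_that("partitioning by annotation splits and tabulates clusters", {
  set.seed(61)
  mk <- function() paste(sample(c("A", "C", "G", "T"), 350, TRUE),
                         collapse = "")
  seqs <- stats::setNames(vapply(1:5, function(i) mk(), character(1)),
                          paste0("x", 1:5))
  tax <- data.frame(asv_id = names(seqs),
                    taxonomy_label = c("Nematoda_1", "Nematoda_2",
                                       "Annelida_1", "Fungi_1", "Weirdia_1"))
  gt <- data.frame(taxon = c("Nematoda", "Annelida", "Fungi"),
                   functional_group = c("meiofauna", "meiofauna", "other"))
  expect_warning(lib <- build_reference_library(seqs, tax, gt), "Weirdia")
  parts <- partition_by_annotation(lib)
  expect_identical(nrow(parts$meiofauna), 3L)
  expect_identical(nrow(parts$other), 2L)
  expect_identical(sum(parts$summary$n_clusters), 5L)
  expect_identical(
    parts$summary$n_clusters[parts$summary$taxon == "Nematoda"], 2L)
  # partition property: disjoint and exhaustive
  expect_length(intersect(parts$meiofauna$cluster_id,
                          parts$other$cluster_id), 0)
})

test_that("merging a library with nothing new is idempotent", {
  set.seed(62)
  mk <- function() paste(sample(c("A", "C", "G", "T"), 350, TRUE),
                         collapse = "")
  seqs <- stats::setNames(vapply(1:4, function(i) mk(), character(1)),
                          paste0("x", 1:4))
  tax <- data.frame(asv_id = names(seqs),
                    taxonomy_label = paste0("Nematoda_", 1:4))
  lib <- build_reference_library(seqs, tax)
  lib2 <- merge_libraries(lib, character(0))
  expect_identical(lib2$asvs$cluster_id, lib$asvs$cluster_id)
})

test_that("merging deduplicates shared sequences and co-clusters trimmed twins", {
  cfg <- tiny_cfg(seed = 43)
  ref <- simulate_reference_sequences(cfg)
  core <- substr(ref$asvs$sequence, ref$asvs$core_start, ref$asvs$core_end)
  names(core) <- ref$asvs$asv_id
  tax <- data.frame(asv_id = ref$asvs$asv_id,
                    taxonomy_label = ref$asvs$taxonomy_label)
  lib <- build_reference_library(core, tax, min_length_bp = 200)

  # new ASVs: one exact copy of an old sequence, one fresh one
  new_seqs <- c(new_dup = unname(core[1]))
  merged <- merge_libraries(lib, new_seqs, min_length_bp = 200)
  expect_identical(nrow(merged$asvs), nrow(lib$asvs))  # deduplicated

  # an old ASV trimmed to the window of a new identical ASV lands in the
  # same cluster after re-clustering
  old_full <- stats::setNames(ref$asvs$sequence, ref$asvs$asv_id)
  tax_old <- tax
  lib_full <- build_reference_library(old_full, tax_old, min_length_bp = 200)
  win <- c(ref$asvs$core_start[1], ref$asvs$core_end[1])
  new2 <- stats::setNames(core[1], "newtwin")
  m2 <- merge_libraries(lib_full, new2,
                        data.frame(asv_id = "newtwin",
                                   taxonomy_label = "Nematoda_99"),
                        trim_to = win, min_length_bp = 200)
  cl <- stats::setNames(m2$asvs$cluster_id, m2$asvs$asv_id)
  if (all(c(ref$asvs$asv_id[1], "newtwin") %in% names(cl))) {
    expect_identical(cl[[ref$asvs$asv_id[1]]], cl[["newtwin"]])
  } else {
    # identical after trimming: deduplicated into a single record
    expect_identical(sum(c(ref$asvs$asv_id[1], "newtwin") %in% names(cl)), 1L)
  }
})

test_that("cluster diameter stays below the cut on planted libraries", {
  cfg <- tiny_cfg(seed = 47)
  ref <- simulate_reference_sequences(cfg)
  core <- substr(ref$asvs$sequence, ref$asvs$core_start, ref$asvs$core_end)
  names(core) <- ref$asvs$asv_id
  d <- build_distance_matrix(core)
  part <- group_average_cluster(d, 0.03)
  # within clusters all pairwise distances < 3%; partition = planted truth
  for (cl in unique(part)) {
    ids <- names(part)[part == cl]
    if (length(ids) > 1) expect_lt(max(d[ids, ids]), 0.03)
  }
  expect_equal(adjusted_rand_index(part, ref$membership[names(part)]), 1)
})
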