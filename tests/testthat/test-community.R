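test_that("Bray-Curtis similarity obeys its bounds and closed form", {
  m <- cbind(s1 = c(3, 2, 0), s2 = c(3, 2, 0), s3 = c(0, 0, 5))
  rownames(m) <- paste0("c", 1:3)
  bc <- bray_curtis(m)
  expect_equal(bc$s["s1", "s2"], 100)   # identical profiles
  expect_equal(bc$s["s1", "s3"], 0)     # disjoint profiles
  expect_true(all(bc$s >= 0 & bc$s <= 100))

  # untransformed u = (1,1,0), v = (0,1,1): similarity 50
  m2 <- cbind(u = c(1, 1, 0), v = c(0, 1, 1))
  rownames(m2) <- paste0("c", 1:3)
  expect_equal(bray_curtis(m2, transform = "none")$s["u", "v"], 50)

  # all-zero profiles are excluded with a flag
  m3 <- cbind(a = c(1, 2), b = c(0, 0))
  rownames(m3) <- c("c1", "c2")
  bc3 <- bray_curtis(m3)
  expect_identical(bc3$excluded, "b")
  expect_false("b" %in% colnames(bc3$s))
})

test_that("Bray-Curtis agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(10)
  m <- matrix(rpois(60, 4), 10, 6,
              dimnames = list(paste0("c", 1:10), paste0("s", 1:6)))
  mine <- bray_curtis(m, transform = "none")$s
  ref <- 100 * (1 - as.matrix(vegan::vegdist(t(m), "bray")))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-12)
})

test_that("profile dendrogram separates planted blocks", {
  # two blocks on disjoint taxa: within-similarity high, between zero
  set.seed(11)
  base1 <- c(rpois(6, 20) + 1, rep(0, 6))
  base2 <- c(rep(0, 6), rpois(6, 20) + 1)
  block <- function(base, k) vapply(1:k, function(i)
    pmax(0, base + sample(-1:1, 12, TRUE) * (base > 0)), numeric(12))
  m <- cbind(block(base1, 3), block(base2, 3))
  colnames(m) <- paste0("s", 1:6)
  rownames(m) <- paste0("c", 1:12)
  bc <- bray_curtis(m)
  tree <- profile_dendrogram(bc$s)
  grp <- cut_dendrogram_at_similarity(tree, 50)
  expect_identical(length(unique(grp[1:3])), 1L)
  expect_identical(length(unique(grp[4:6])), 1L)
  expect_false(grp[[1]] == grp[[4]])

  # identical profiles collapse at height zero
  m4 <- cbind(a = c(2, 1), b = c(2, 1))
  rownames(m4) <- c("c1", "c2")
  t4 <- profile_dendrogram(bray_curtis(m4)$s)
  expect_equal(t4$heights, 0)
})

test_that("dendrogram heights equal hclust average linkage on dissimilarity", {
  set.seed(12)
  m <- matrix(rpois(70, 5), 10, 7,
              dimnames = list(paste0("c", 1:10), paste0("s", 1:7)))
  bc <- bray_curtis(m)
  tree <- profile_dendrogram(bc$s)
  hc <- stats::hclust(stats::as.dist(100 - bc$s), method = "average")
  expect_equal(sort(tree$heights), sort(hc$height))
})

test_that("pairwise permutation test pins fully separated groups", {
  set.seed(21)
  blockA <- vapply(1:5, function(i) c(rpois(4, 8) + 1, rep(0, 4)),
                   numeric(8))
  blockB <- vapply(1:5, function(i) c(rep(0, 4), rpois(4, 8) + 1),
                   numeric(8))
  m <- cbind(blockA, blockB)
  colnames(m) <- c(paste0("a", 1:5), paste0("b", 1:5))
  rownames(m) <- paste0("c", 1:8)
  bc <- bray_curtis(m)
  g <- stats::setNames(rep(c("a", "b"), each = 5), colnames(m))
  pt <- pairwise_permutation_test(g, bc$s, n_perm = 199, seed = 4)
  # F is maximal on the true labelling; only a re-draw of the same split
  # can tie it, so p sits at the permutation floor
  expect_gte(pt$p_value, 1 / 200)
  expect_lt(pt$p_value, 0.05)
  expect_true(pt$significant)

  # determinism under a fixed seed
  pt2 <- pairwise_permutation_test(g, bc$s, n_perm = 199, seed = 4)
  expect_identical(pt, pt2)

  # groups of size one are skipped with a warning
  g2 <- stats::setNames(c("a", rep("b", 9)), colnames(m))
  expect_warning(out <- pairwise_permutation_test(g2, bc$s, n_perm = 19,
                                                  seed = 1), "size 1")
  expect_identical(nrow(out), 0L)
})

test_that("permutation p-values match the exhaustive label-permutation oracle", {
  # n = 6 samples, 2 groups of 3: only 20 distinct labellings
  set.seed(13)
  m <- matrix(rpois(36, 6), 6, 6,
              dimnames = list(paste0("c", 1:6), paste0("s", 1:6)))
  bc <- bray_curtis(m)
  d2 <- (100 - bc$s)^2
  g <- rep(c("a", "b"), each = 3)
  F_obs <- meiobar:::permanova_F(d2, g)
  labels <- utils::combn(6, 3)
  F_all <- apply(labels, 2, function(idx) {
    gg <- rep("b", 6); gg[idx] <- "a"
    meiobar:::permanova_F(d2, gg)
  })
  p_exact <- mean(F_all >= F_obs - 1e-12)
  gnames <- stats::setNames(g, colnames(m))
  pt <- pairwise_permutation_test(gnames, bc$s, n_perm = 9999, seed = 2)
  # Monte-Carlo permutation p within binomial error of the exact p
  expect_lt(abs(pt$p_value - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 9999) + 2e-4)
})

test_that("BIOENV finds a perfectly rank-correlated subset", {
  set.seed(14)
  n <- 9
  grad <- seq_len(n)
  m <- t(vapply(1:12, function(c0) 10 + c0 * grad + rnorm(n, 0, 0.01),
                numeric(n)))
  colnames(m) <- paste0("s", 1:n)
  rownames(m) <- paste0("c", 1:12)
  # abiotic variable = Euclidean coordinate reproducing the biotic ranks
  env <- data.frame(v1 = grad, v2 = rnorm(n))
  bc <- bray_curtis(m)
  be <- bioenv(bc$s, env, n_perm = 19, seed = 5)
  expect_identical(be$best_subset, "v1")
  expect_gt(be$rho, 0.9)
  expect_true(be$significant)

  # independent abiotic table: non-significant against the threshold
  env0 <- data.frame(v1 = rnorm(n), v2 = rnorm(n))
  be0 <- bioenv(bc$s, env0, n_perm = 99, seed = 6)
  expect_false(isTRUE(be0$significant) && be0$rho > 0.9)

  # constant columns are dropped with a warning
  expect_warning(bioenv(bc$s, data.frame(v1 = grad, v2 = rep(1, n)),
                        n_perm = 0), "constant")
})

test_that("BIOENV equals the vegan implementation on random studies", {
  skip_if_not_installed("vegan")
  set.seed(15)
  for (r in 1:5) {
    n <- sample(8:12, 1)
    comm <- matrix(rpois(n * 10, 4), nrow = n)
    env <- as.data.frame(matrix(rnorm(n * 4), ncol = 4))
    names(env) <- paste0("v", 1:4)
    m <- t(comm)
    colnames(m) <- paste0("s", 1:n); rownames(m) <- paste0("c", 1:10)
    bc <- bray_curtis(m, transform = "none")
    mine <- bioenv(bc$s, env, n_perm = 0)
    vg <- vegan::bioenv(vegan::vegdist(comm, "bray"), env,
                        method = "spearman", metric = "euclidean",
                        trace = FALSE)
    vbest <- vg$models[[which.max(vapply(vg$models, `[[`, numeric(1),
                                         "est"))]]
    expect_setequal(mine$best_subset, vg$names[vbest$best])
    expect_equal(mine$rho, vbest$est, tolerance = 1e-10)
  }
})

test_that("tie-free Spearman rho equals cor(method = 'spearman')", {
  set.seed(16)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(meiobar:::spearman_rho(a, b),
               stats::cor(a, b, method = "spearman"))
})

test_that("shared-ASV percentages follow the chosen convention", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c", "d"),
               C = c("a", "b", "c"), D = c("x"))
  out <- shared_asv_matrix(sets)
  expect_equal(out$pct["A", "C"], 100)
  expect_equal(out$pct["A", "D"], 0)
  expect_equal(out$pct["A", "B"], 50)          # 2 shared / 4 in union
  expect_equal(out$pct, t(out$pct))
  sm <- shared_asv_matrix(sets, convention = "smaller")
  expect_equal(sm$pct["A", "B"], 100 * 2 / 3)

  withE <- shared_asv_matrix(list(A = "a", E = character(0)))
  expect_identical(withE$flagged, "E")
})

test_that("Newick export reproduces the dendrogram in ape", {
  skip_if_not_installed("ape")
  set.seed(17)
  m <- matrix(rpois(50, 5), 10, 5,
              dimnames = list(paste0("c", 1:10), paste0("s", 1:5)))
  tree <- profile_dendrogram(bray_curtis(m)$s)
  nwk <- upgma_newick(tree)
  ph <- ape::read.tree(text = nwk)
  expect_setequal(ph$tip.label, colnames(m))
  expect_true(ape::is.ultrametric(ph, tol = 1e-6))
  # root-to-tip depth equals the top merge height
  depths <- ape::node.depth.edgelength(ph)[seq_along(ph$tip.label)]
  expect_equal(unname(depths), rep(max(tree$heights), 5), tolerance = 1e-8)
})
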