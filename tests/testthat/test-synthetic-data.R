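test_that("planted within- and between-species divergences hold on emitted sequences", {
  cfg <- sim_config(n_sites = 1, depths_m = 100, n_cores_per_site = 1,
                    n_species = 2, n_background_species = 0,
                    n_other_species = 0, n_asvs_per_species = 3,
                    within_cluster_divergence = 0.01,
                    between_cluster_divergence = 0.10,
                    reads_per_slice = 10, seed = 3)
  ref <- simulate_reference_sequences(cfg)
  asvs <- ref$asvs
  # primers are planted verbatim at both ends
  expect_true(all(grepl("^CCGCGGTAAT", asvs$sequence)))
  core <- substr(asvs$sequence, asvs$core_start, asvs$core_end)
  for (i in 1:5) for (j in (i + 1):6) {
    d <- p_distance(core[i], core[j])
    if (asvs$species_id[i] == asvs$species_id[j]) {
      expect_lte(d, 0.01)
    } else {
      expect_gte(d, 0.10 - 1e-9)
    }
  }
})

test_that("single-species configuration yields one tight cluster", {
  cfg <- sim_config(n_sites = 1, depths_m = 50, n_cores_per_site = 1,
                    n_species = 1, n_background_species = 0,
                    n_other_species = 0, n_asvs_per_species = 3,
                    within_cluster_divergence = 0.01, reads_per_slice = 10,
                    seed = 5)
  ref <- simulate_reference_sequences(cfg)
  core <- substr(ref$asvs$sequence, ref$asvs$core_start, ref$asvs$core_end)
  for (i in 1:2) for (j in (i + 1):3)
    expect_lte(p_distance(core[i], core[j]), 0.01)
})

test_that("infeasible divergence demands are rejected", {
  expect_error(
    simulate_reference_sequences(
      sim_config(n_species = 200, n_background_species = 0,
                 n_other_species = 0,
                 depths_m = rep(100, 6),
                 barcode_length_range = c(325L, 325L),
                 within_cluster_divergence = 0.029,
                 between_cluster_divergence = 0.9,
                 n_asvs_per_species = 4, seed = 1)),
    "infeasible")
})

test_that("same seed reproduces the study byte-for-byte", {
  cfg <- tiny_cfg(seed = 11)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$ref, s2$ref)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$count_table, s2$count_table)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  }
})

test_that("community expectation follows the configured decay model", {
  # zero decay rates: one shared expectation everywhere
  cfg0 <- tiny_cfg(seed = 2, abundance_decay_depth = 0,
                   abundance_decay_horizon = 0)
  ref <- simulate_reference_sequences(cfg0)
  com <- simulate_community(cfg0, ref)
  for (sp in dimnames(com$expected)[[1]])
    expect_equal(max(com$expected[sp, , , ]) - min(com$expected[sp, , , ]), 0)

  # with uniform niches, doubling depth with k_d = ln(2)/depth halves lambda
  cfg2 <- sim_config(n_sites = 2, depths_m = c(100, 200),
                     n_cores_per_site = 1, n_species = 4,
                     n_background_species = 0, n_other_species = 0,
                     abundance_decay_depth = log(2) / 100,
                     abundance_decay_horizon = 0, species_niche_sd = 0,
                     reads_per_slice = 10, seed = 4)
  ref2 <- simulate_reference_sequences(cfg2)
  com2 <- simulate_community(cfg2, ref2)
  expect_equal(com2$expected[, 2, 1, 1], com2$expected[, 1, 1, 1] / 2)

  # expectation is monotone non-increasing in depth and horizon
  cfg3 <- tiny_cfg(seed = 9)
  com3 <- simulate_community(cfg3, simulate_reference_sequences(cfg3))
  lam <- com3$expected
  expect_true(all(lam[, 2, , ] <= lam[, 1, , ] + 1e-12))
  nh <- dim(lam)[4]
  expect_true(all(lam[, , , 2:nh] <= lam[, , , 1:(nh - 1)] + 1e-12))
})

test_that("count draws match the configured expectation (Monte Carlo)", {
  cfg <- tiny_cfg(seed = 1)
  ref <- simulate_reference_sequences(cfg)
  tot_c <- 0; tot_l <- 0
  for (r in 1:40) {
    cfg$seed <- 100 + r
    com <- simulate_community(cfg, ref)
    tot_c <- tot_c + sum(com$counts)
    tot_l <- tot_l + sum(com$expected)
  }
  # Poisson sum: 3 sigma band around the summed expectation
  expect_lt(abs(tot_c - tot_l), 3 * sqrt(tot_l))
})

test_that("emitted count tables equal the true-count marginals exactly", {
  cfg <- tiny_cfg(seed = 21)
  sim <- simulate_study(cfg)
  counted <- unique(sim$ref$asvs$species_id[sim$ref$asvs$counted])
  expect_identical(sum(sim$count_table$count),
                   as.integer(sum(sim$community$counts[counted, , , ])))
  # spot-check one slice
  r1 <- sim$count_table[sim$count_table$site == "HS54" &
                          sim$count_table$core == "A" &
                          sim$count_table$horizon_top_cm == 0, ]
  expect_identical(sum(r1$count),
                   as.integer(sum(sim$community$counts[counted, "HS54", "A", 1])))
})

test_that("no-noise reads are exact amplicons in exact proportion", {
  sim <- simulate_study(no_noise(tiny_cfg(seed = 13)))
  refseq <- stats::setNames(sim$ref$asvs$sequence, sim$ref$asvs$asv_id)
  df <- sim$reads[[which.max(vapply(sim$reads, nrow, integer(1)))]]
  amp <- refseq[df$true_asv]
  expect_identical(df$fwd_seq, unname(substr(amp, 1, 250)))
  expect_identical(unname(df$rev_seq),
                   unname(revcomp(substr(amp, nchar(amp) - 249, nchar(amp)))))
})

test_that("background read fraction matches its configuration", {
  cfg <- tiny_cfg(seed = 17, reads_per_slice = 400)
  sim <- simulate_study(cfg)
  bg <- tapply(sim$read_truth$n_reads, sim$read_truth$background, sum)
  frac <- bg[["TRUE"]] / sum(bg)
  # binomial sampling over ~11k reads: generous 4-sigma band
  n <- sum(bg)
  expect_lt(abs(frac - 0.089), 4 * sqrt(0.089 * 0.911 / n))

  sim0 <- simulate_study(no_noise(tiny_cfg(seed = 17)))
  expect_equal(sum(sim0$read_truth$n_reads[sim0$read_truth$background]), 0)
})

test_that("sequencing errors land at the configured per-base rate", {
  cfg <- tiny_cfg(seed = 23, seq_error_rate = 0.01)
  sim <- simulate_study(cfg)
  refseq <- stats::setNames(sim$ref$asvs$sequence, sim$ref$asvs$asv_id)
  dsum <- 0; nsum <- 0
  for (sl in names(sim$reads)[1:6]) {
    df <- sim$reads[[sl]]
    if (!nrow(df)) next
    tmpl <- substr(refseq[df$true_asv], 1, nchar(df$fwd_seq))
    for (i in seq_len(nrow(df))) {
      dsum <- dsum + sum(strsplit(df$fwd_seq[i], "")[[1]] !=
                           strsplit(tmpl[i], "")[[1]])
      nsum <- nsum + nchar(tmpl[i])
    }
  }
  expect_lt(abs(dsum / nsum - 0.01), 0.004)
})
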