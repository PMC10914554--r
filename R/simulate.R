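# Synthetic-data generator: reference barcodes with planted species-proxy
# structure, depth/horizon-structured communities, paired reads with a
# background fraction, and abiotic covariates with tunable coupling.

# Concretise an IUPAC string by picking one admissible base per position.
concretize_primer <- function(primer) {
  paste(vapply(chars(primer), function(ch) {
    opts <- IUPAC_SETS[[ch]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# substitute the bases at `pos` with a different random base
substitute_at <- function(seq, pos) {
  if (length(pos) == 0L) return(seq)
  v <- chars(seq)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  paste(v, collapse = "")
}

#' Simulate reference barcode sequences with planted species-proxy clusters
#'
#' Builds, for every species in the pool (counted hard-bodied, soft-bodied
#' background and non-meiofaunal "other" species), a set of amplicon sequence
#' variants such that pairwise p-distance within a species is below
#' `within_cluster_divergence` (< 3%) and between species is at least
#' `between_cluster_divergence` (> 3%). Each amplicon starts with the forward
#' primer and ends with the reverse complement of the reverse primer, so that
#' primer removal is exercised downstream.
#'
#' The construction is combinatorial rather than stochastic in its
#' guarantees. On a shared ancestral core, `ceiling(log4(n_species))` blocks
#' of `ceiling(between * L)` positions each carry a base-4 codeword per
#' species (every species writes its own base into every block position), so
#' any two species differ across at least one full block; each ASV
#' additionally receives a private set of substitution positions outside the
#' code blocks (disjoint within its species). Within-species p-distances are
#' then exactly `2 * floor(within * L / 2) / L` and between-species
#' p-distances at least `between`.
#'
#' @param cfg a [sim_config()].
#' @return a list with `asvs` (data.frame: asv_id, species_id, sequence,
#'   core_start, core_end, taxonomy_label, functional_group, counted) and
#'   `membership` (named character: asv_id -> species_id).
#' @export
simulate_reference_sequences <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(cfg$seed, {
    n_total <- cfg$n_species + cfg$n_background_species + cfg$n_other_species
    fp_len <- nchar(cfg$forward_primer)
    rp_len <- nchar(cfg$reverse_primer)
    len_rng <- cfg$barcode_length_range
    amp_len <- if (diff(len_rng) == 0) rep(len_rng[1], n_total) else
      sample(seq(len_rng[1], len_rng[2]), n_total, replace = TRUE)
    core_len <- amp_len - fp_len - rp_len
    core_min <- min(core_len)

    k_per <- floor(cfg$within_cluster_divergence * core_len / 2)
    # base-4 code: k_blocks blocks of D positions each on the shared core
    # prefix; species differing in a block digit differ at all D positions
    D <- ceiling(cfg$between_cluster_divergence * core_min)
    k_blocks <- max(1L, ceiling(log(n_total, base = 4)))
    need <- k_blocks * D + max(k_per) * cfg$n_asvs_per_species
    if (need > core_min) {
      stop("infeasible simulation configuration: ", need,
           " distinct substitution positions required but the shortest ",
           "barcode core has only ", core_min, " bp; reduce n_species, ",
           "divergences or n_asvs_per_species, or lengthen the barcode",
           call. = FALSE)
    }

    ancestor <- random_dna(max(core_len))
    code_pos <- matrix(sample(seq_len(core_min), k_blocks * D),
                       nrow = k_blocks)
    BASES <- c("A", "C", "G", "T")
    # base-4 digits (least significant first) of each species index
    digits <- vapply(seq_len(n_total) - 1L, function(s)
      as.integer((s %/% 4^(seq_len(k_blocks) - 1L)) %% 4L),
      integer(k_blocks))
    digits <- matrix(digits, nrow = k_blocks)
    free_pool <- setdiff(seq_len(core_min), as.vector(code_pos))

    sp_ids <- sprintf("sp%02d", seq_len(n_total))
    counted <- c(rep(TRUE, cfg$n_species),
                 rep(FALSE, cfg$n_background_species + cfg$n_other_species))
    group <- c(rep_len(HARD_GROUPS, cfg$n_species),
               rep_len(SOFT_GROUPS, cfg$n_background_species),
               rep_len(OTHER_GROUPS, cfg$n_other_species))
    func <- c(rep("meiofauna", cfg$n_species + cfg$n_background_species),
              rep("other", cfg$n_other_species))

    rows <- vector("list", n_total)
    membership <- character(0)
    for (s in seq_len(n_total)) {
      v <- chars(substr(ancestor, 1, core_len[s]))
      for (b in seq_len(k_blocks)) v[code_pos[b, ]] <- BASES[digits[b, s] + 1L]
      core_s <- paste(v, collapse = "")
      fp <- concretize_primer(cfg$forward_primer)
      rp <- concretize_primer(cfg$reverse_primer)
      asvs <- character(cfg$n_asvs_per_species)
      ids <- sprintf("%s_asv%d", sp_ids[s], seq_len(cfg$n_asvs_per_species))
      # per-ASV private substitution positions, disjoint within the species
      sub_pos <- matrix(sample(free_pool,
                               k_per[s] * cfg$n_asvs_per_species),
                        ncol = cfg$n_asvs_per_species)
      for (a in seq_len(cfg$n_asvs_per_species)) {
        core_a <- substitute_at(core_s, sub_pos[, a])
        if (cfg$indels && a > 1L) {
          # short deletion well inside the core, beyond the reserved prefix
          del_len <- sample(1:3, 1L)
          at <- core_min + 1L
          if (nchar(core_a) > at + del_len)
            core_a <- paste0(substr(core_a, 1, at - 1),
                             substr(core_a, at + del_len, nchar(core_a)))
        }
        asvs[a] <- paste0(fp, core_a, revcomp(rp))
      }
      membership[ids] <- sp_ids[s]
      rows[[s]] <- data.frame(
        asv_id = ids, species_id = sp_ids[s], sequence = asvs,
        core_start = fp_len + 1L,
        core_end = nchar(asvs) - rp_len,
        taxonomy_label = sprintf("%s_%d", group[s], s),
        functional_group = func[s], counted = counted[s],
        stringsAsFactors = FALSE
      )
    }
    list(asvs = do.call(rbind, rows), membership = membership)
  })
}

#' Simulate a depth- and horizon-structured community
#'
#' Draws specimen counts per species, site, core and slice from independent
#' Poisson distributions whose expectation decays exponentially with bottom
#' depth and with the midpoint of the sub-bottom horizon:
#' `lambda = baseline_s * exp(-k_d,s * depth) * exp(-k_h,s * horizon_mid)`,
#' where the per-species rates `k_d,s`, `k_h,s` are the configured rates
#' times lognormal niche multipliers (spread `species_niche_sd`; zero makes
#' all species share the configured rates exactly). With niche variation the
#' community composition, not just its total abundance, turns over along
#' depth and horizon.
#'
#' @param cfg a [sim_config()].
#' @param ref output of [simulate_reference_sequences()] (for the species
#'   pool); only species identities are used.
#' @return a list with `counts` (4-d array species x site x core x slice),
#'   `baselines` (named numeric), `decay_depth` and `decay_horizon`
#'   (per-species rates) and `expected` (array of the Poisson means).
#' @export
simulate_community <- function(cfg, ref) {
  validate_sim_config(cfg)
  sp <- unique(ref$asvs$species_id)
  with_seed(cfg$seed + 1L, {
    base <- stats::rlnorm(length(sp),
                          meanlog = log(cfg$baseline_mean) -
                            cfg$baseline_sdlog^2 / 2,
                          sdlog = cfg$baseline_sdlog)
    names(base) <- sp
    niche <- function() {
      if (cfg$species_niche_sd == 0) rep(1, length(sp)) else
        stats::rlnorm(length(sp), -cfg$species_niche_sd^2 / 2,
                      cfg$species_niche_sd)
    }
    kd <- stats::setNames(cfg$abundance_decay_depth * niche(), sp)
    kh <- stats::setNames(cfg$abundance_decay_horizon * niche(), sp)
    mids <- horizon_midpoints(cfg$horizon_scheme)
    dims <- c(length(sp), cfg$n_sites, cfg$n_cores_per_site, length(mids))
    lam <- array(0, dims,
                 dimnames = list(sp, site_names(cfg), core_names(cfg),
                                 as.character(mids)))
    for (i in seq_len(cfg$n_sites))
      for (l in seq_along(mids))
        lam[, i, , l] <- base * exp(-kd * cfg$depths_m[i]) *
          exp(-kh * mids[l])
    counts <- array(stats::rpois(length(lam), lam), dims,
                    dimnames = dimnames(lam))
    list(counts = counts, baselines = base, decay_depth = kd,
         decay_horizon = kh, expected = lam)
  })
}

# introduce substitution errors into a vector of sequences
seq_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hits <- which(stats::runif(n) < rate)
    substitute_at(s, hits)
  }, character(1), USE.NAMES = FALSE)
}

make_quality <- function(len, degrade) {
  if (!degrade) return(int_to_qual(rep(37L, len)))
  tail_len <- min(60L, len)
  q <- c(rep(37L, len - tail_len),
         round(seq(37L, 8L, length.out = tail_len)))
  int_to_qual(q)
}

# deterministic largest-remainder allocation of `n` items over weights `w`
allocate_exact <- function(n, w) {
  if (n == 0L || sum(w) == 0) return(integer(length(w)))
  raw <- n * w / sum(w)
  out <- floor(raw)
  rem <- n - sum(out)
  if (rem > 0) {
    ord <- order(raw - out, decreasing = TRUE)
    out[ord[seq_len(rem)]] <- out[ord[seq_len(rem)]] + 1L
  }
  as.integer(out)
}

#' Simulate paired amplicon reads and the sorted-specimen count table
#'
#' For each slice, read pairs are generated from the species' ASV amplicons
#' in proportion to the planted specimen counts, plus a background fraction
#' drawn from species absent from the count table (soft-bodied meiofauna and
#' non-meiofaunal taxa). Forward reads are the 5' `read_length` bp of the
#' amplicon; reverse reads the reverse complement of the 3' `read_length` bp,
#' so mates always overlap and merging reconstructs the amplicon.
#' Substitution errors are applied at `seq_error_rate`.
#'
#' @param cfg a [sim_config()].
#' @param ref output of [simulate_reference_sequences()].
#' @param community output of [simulate_community()].
#' @return a list with `reads` (per-slice list of data.frames: id, fwd_seq,
#'   fwd_qual, rev_seq, rev_qual, true_asv, true_species), `count_table`
#'   (data.frame: site, core, horizon_top_cm, horizon_bottom_cm, taxon_group,
#'   count — hard-bodied species only), and `read_truth` (per-slice species
#'   read totals including background).
#' @export
simulate_reads <- function(cfg, ref, community) {
  validate_sim_config(cfg)
  asvs <- ref$asvs
  counts <- community$counts
  bounds <- horizon_bounds(cfg$horizon_scheme)
  mids <- horizon_midpoints(cfg$horizon_scheme)
  sites <- site_names(cfg)
  cores <- core_names(cfg)
  counted_sp <- unique(asvs$species_id[asvs$counted])
  bg_sp <- setdiff(unique(asvs$species_id), counted_sp)
  sp_group <- tapply(asvs$taxonomy_label, asvs$species_id, function(x)
    sub("_[0-9]+$", "", x[1]))

  with_seed(cfg$seed + 2L, {
    reads <- list()
    ct_rows <- list()
    truth_rows <- list()
    for (i in seq_along(sites)) for (j in seq_along(cores)) {
      for (l in seq_along(mids)) {
        sl <- slice_label(sites[i], cores[j], bounds[l])
        cvec <- counts[counted_sp, i, j, l]
        total <- sum(cvec)
        # background pool weighted by the same community gradient
        bg_w <- community$expected[bg_sp, i, j, l]
        if (sum(bg_w) == 0) bg_w <- rep(1, length(bg_sp))

        if (cfg$read_allocation == "exact") {
          per_ind <- max(1L, round(cfg$reads_per_slice / max(total, 1L)))
          n_counted <- as.integer(cvec * per_ind)
          n_bg_total <- round(sum(n_counted) *
                                cfg$background_read_fraction /
                                (1 - cfg$background_read_fraction))
          n_bg <- allocate_exact(n_bg_total, bg_w)
        } else {
          n_bg_total <- stats::rbinom(1L, cfg$reads_per_slice,
                                      cfg$background_read_fraction)
          n_fg_total <- cfg$reads_per_slice - n_bg_total
          n_counted <- if (total > 0)
            as.vector(stats::rmultinom(1L, n_fg_total, cvec))
          else integer(length(cvec))
          n_bg <- as.vector(stats::rmultinom(1L, n_bg_total, bg_w))
        }
        names(n_counted) <- counted_sp
        names(n_bg) <- bg_sp
        n_sp <- c(n_counted, n_bg)

        # spread each species' reads over its ASVs (deterministic split)
        ids <- character(0); tmpl <- character(0); tsp <- character(0)
        for (s in names(n_sp)) {
          if (n_sp[[s]] == 0L) next
          sa <- asvs[asvs$species_id == s, , drop = FALSE]
          per <- allocate_exact(n_sp[[s]], rep(1, nrow(sa)))
          tmpl <- c(tmpl, rep(sa$sequence, per))
          tsp <- c(tsp, rep(sa$species_id, per))
          ids <- c(ids, rep(sa$asv_id, per))
        }
        nr <- length(tmpl)
        if (nr > 0) {
          fwd <- substr(tmpl, 1L, pmin(cfg$read_length, nchar(tmpl)))
          rev_ <- revcomp(substr(tmpl,
                                 pmax(1L, nchar(tmpl) - cfg$read_length + 1L),
                                 nchar(tmpl)))
          fwd <- seq_errors(fwd, cfg$seq_error_rate)
          rev_ <- seq_errors(rev_, cfg$seq_error_rate)
          df <- data.frame(
            id = sprintf("SIM:%s:%s:%s:%d", sites[i], cores[j], bounds[l],
                         seq_len(nr)),
            fwd_seq = fwd,
            fwd_qual = vapply(nchar(fwd), make_quality,
                              character(1), degrade = cfg$degrade_quality_tail),
            rev_seq = rev_,
            rev_qual = vapply(nchar(rev_), make_quality,
                              character(1), degrade = cfg$degrade_quality_tail),
            true_asv = ids, true_species = tsp,
            stringsAsFactors = FALSE
          )
        } else {
          df <- data.frame(id = character(0), fwd_seq = character(0),
                           fwd_qual = character(0), rev_seq = character(0),
                           rev_qual = character(0), true_asv = character(0),
                           true_species = character(0))
        }
        reads[[sl]] <- df
        truth_rows[[sl]] <- data.frame(
          slice = sl, species_id = names(n_sp), n_reads = as.integer(n_sp),
          background = names(n_sp) %in% bg_sp, stringsAsFactors = FALSE)

        # count table: hard-bodied groups only, summed within group
        grp <- sp_group[counted_sp]
        agg <- tapply(cvec, grp, sum)
        ct_rows[[sl]] <- data.frame(
          site = sites[i], core = cores[j],
          horizon_top_cm = bounds[l], horizon_bottom_cm = bounds[l + 1L],
          taxon_group = names(agg), count = as.integer(agg),
          stringsAsFactors = FALSE)
      }
    }
    list(reads = reads,
         count_table = do.call(rbind, c(ct_rows, list(make.row.names = FALSE))),
         read_truth = do.call(rbind, c(truth_rows,
                                       list(make.row.names = FALSE))))
  })
}

#' Simulate abiotic covariate and grain-size tables
#'
#' One row per site and horizon. Depth and horizon midpoint are exact; the
#' remaining variables (protein, carbohydrate, silt/clay ratio, sand percent,
#' oxygen) are generated as `rho * g + sqrt(1 - rho^2) * noise` on a latent
#' standardised scale, where `g` is the standardised community gradient
#' `-(k_d * depth + k_h * horizon)` and `rho` the configured coupling, then
#' mapped to plausible units. The grain-size table is a three-point spectrum
#' per slice consistent with the generated silt/clay ratio and sand fraction.
#'
#' @param cfg a [sim_config()].
#' @return list with `abiotic` (data.frame) and `grainsize` (long data.frame:
#'   slice_id, size_um, fraction).
#' @export
simulate_abiotics <- function(cfg) {
  validate_sim_config(cfg)
  bounds <- horizon_bounds(cfg$horizon_scheme)
  mids <- horizon_midpoints(cfg$horizon_scheme)
  sites <- site_names(cfg)
  grid <- expand.grid(site = sites, horizon = seq_along(mids),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  depth <- cfg$depths_m[match(grid$site, sites)]
  hmid <- mids[grid$horizon]
  g <- -(cfg$abundance_decay_depth * depth + cfg$abundance_decay_horizon * hmid)
  g <- as.vector(scale(g))

  with_seed(cfg$seed + 3L, {
    couple <- function(name) {
      rho <- cfg$abiotic_coupling[[name]]
      rho * g + sqrt(1 - rho^2) * stats::rnorm(length(g))
    }
    z_prot <- couple("protein"); z_carb <- couple("carbohydrate")
    z_sc <- couple("silt_clay_ratio"); z_sand <- couple("sand_percent")
    z_oxy <- couple("oxygen")
    ab <- data.frame(
      site = grid$site,
      horizon_top_cm = bounds[grid$horizon],
      horizon_bottom_cm = bounds[grid$horizon + 1L],
      depth_m = depth,
      horizon_cm = hmid,
      protein = round(exp(0.3 + 0.35 * z_prot), 3),          # mg/g dry
      carbohydrate = round(200 * exp(0.3 * z_carb), 1),      # ug/g dry
      silt_clay_ratio = round(1.1 * exp(0.2 * z_sc), 3),
      sand_percent = round(100 * stats::plogis(-1.5 + 0.8 * z_sand), 2),
      oxygen = round(120 * exp(0.4 * z_oxy), 1),             # uM
      stringsAsFactors = FALSE
    )
    gs <- do.call(rbind, lapply(seq_len(nrow(ab)), function(r) {
      sand <- ab$sand_percent[r] / 100
      clay <- (1 - sand) / (1 + ab$silt_clay_ratio[r])
      silt <- 1 - sand - clay
      data.frame(
        slice_id = paste0(ab$site[r], "_", ab$horizon_top_cm[r]),
        size_um = c(2, 20, 100),
        fraction = c(clay, silt, sand))
    }))
    list(abiotic = ab, grainsize = gs)
  })
}

#' Simulate a complete synthetic metabarcoding study
#'
#' Runs all generator stages under the configuration's seed and returns a
#' single study object. The same configuration (seed included) always yields
#' identical output.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `meiobar_sim`: list with `cfg`, `ref`,
#'   `community`, `reads`, `count_table`, `read_truth`, `abiotic`,
#'   `grainsize`.
#' @export
simulate_study <- function(cfg) {
  ref <- simulate_reference_sequences(cfg)
  community <- simulate_community(cfg, ref)
  rd <- simulate_reads(cfg, ref, community)
  ab <- simulate_abiotics(cfg)
  out <- list(cfg = cfg, ref = ref, community = community,
              reads = rd$reads, count_table = rd$count_table,
              read_truth = rd$read_truth,
              abiotic = ab$abiotic, grainsize = ab$grainsize)
  class(out) <- "meiobar_sim"
  out
}

#' Write a synthetic study to disk
#'
#' Emits the reference ASV FASTA, per-slice paired FASTQ files, the
#' specimen-count TSV, the abiotic and grain-size TSVs and a JSON
#' ground-truth sidecar. Output is deterministic for a fixed configuration.
#'
#' @param sim a `meiobar_sim` object from [simulate_study()].
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "meiobar_sim"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fa <- Biostrings::DNAStringSet(sim$ref$asvs$sequence)
  names(fa) <- paste(sim$ref$asvs$asv_id, sim$ref$asvs$taxonomy_label,
                     sim$ref$asvs$functional_group, sep = "|")
  Biostrings::writeXStringSet(fa, file.path(outdir, "reference_asvs.fasta"))
  rdir <- file.path(outdir, "reads")
  dir.create(rdir, showWarnings = FALSE)
  for (sl in names(sim$reads)) {
    df <- sim$reads[[sl]]
    write_fastq(data.frame(id = paste0(df$id, " 1"), seq = df$fwd_seq,
                           qual = df$fwd_qual),
                file.path(rdir, paste0(sl, "_R1.fastq")))
    write_fastq(data.frame(id = paste0(df$id, " 2"), seq = df$rev_seq,
                           qual = df$rev_qual),
                file.path(rdir, paste0(sl, "_R2.fastq")))
  }
  utils::write.table(sim$count_table, file.path(outdir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$abiotic, file.path(outdir, "abiotic.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$grainsize, file.path(outdir, "grainsize.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(
    membership = as.list(sim$ref$membership),
    baselines = as.list(sim$community$baselines),
    true_counts = as.data.frame.table(sim$community$counts,
                                      responseName = "count",
                                      stringsAsFactors = FALSE)
  )
  jsonlite::write_json(truth, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
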