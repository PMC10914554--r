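# Count normalization of read profiles, the iterative background-zeroing
# rule on the counts/ASV-3 index, and areal abundance.

CORE_DIAMETER_CM <- 9.4
CORE_AREA_M2 <- pi * (CORE_DIAMETER_CM / 2 / 100)^2  # ~6.94e-3 m^2

#' Normalize a slice read profile by counted specimens
#'
#' Converts per-cluster read counts into estimated specimen counts by
#' proportional allocation: `estimate(c) = reads(c) / sum(reads) *
#' total_count`. Estimates sum exactly to the counted total. A slice with
#' counted specimens but no mapped meiofaunal reads carries no information
#' and is flagged.
#'
#' @param reads_per_cluster named numeric of mapped meiofaunal reads.
#' @param total_count counted specimens in the slice (non-negative integer).
#' @return list with `estimate` (named numeric) and `flagged` (logical:
#'   `TRUE` when `total_count > 0` but no reads mapped).
#' @export
normalize_profile <- function(reads_per_cluster, total_count) {
  assert_that(total_count >= 0, "total_count must be non-negative")
  assert_that(all(reads_per_cluster >= 0), "read counts must be non-negative")
  tot_reads <- sum(reads_per_cluster)
  if (total_count == 0)
    return(list(estimate = reads_per_cluster * 0, flagged = FALSE))
  if (tot_reads == 0)
    return(list(estimate = reads_per_cluster * 0, flagged = TRUE))
  list(estimate = reads_per_cluster / tot_reads * total_count,
       flagged = FALSE)
}

#' Normalize a read-count matrix into an estimated-count matrix
#'
#' Applies [normalize_profile()] column-wise.
#'
#' @param m cluster-by-slice read-count matrix.
#' @param totals named numeric: counted specimens per slice (names matching
#'   `colnames(m)`).
#' @return list with `estimates` (matrix), `totals`, `flagged_slices`
#'   (character).
#' @export
normalize_matrix <- function(m, totals) {
  assert_that(all(colnames(m) %in% names(totals)),
              "every slice needs a specimen total")
  est <- m * 0
  flagged <- character(0)
  for (s in colnames(m)) {
    r <- normalize_profile(m[, s], totals[[s]])
    est[, s] <- r$estimate
    if (r$flagged) flagged <- c(flagged, s)
  }
  list(estimates = est, totals = totals[colnames(m)],
       flagged_slices = flagged)
}

# per-slice counts/ASV-3 index for an estimate matrix (NA where nnz = 0)
slice_index <- function(est, totals) {
  nnz <- colSums(est > 0)
  idx <- ifelse(nnz > 0, totals[colnames(est)] / nnz, NA_real_)
  stats::setNames(idx, colnames(est))
}

#' Background zeroing of an estimated-count matrix
#'
#' Low estimated counts are interpreted as background reads not originating
#' from counted individuals (soft-bodied taxa, gut contents, adsorbed DNA).
#' The rule zeroes every cell strictly below a single global threshold
#' `tau`, chosen as the smallest value from the multiset of cell values
#' (plus zero) such that the per-slice index `total_counts / nnz` exceeds 1
#' in every informative slice. Slices whose counted total is 0 or 1 can
#' never satisfy the index and are zeroed entirely and flagged, as are
#' slices for which no threshold works (possible only when all surviving
#' cells tie).
#'
#' @param est cluster-by-slice estimated-count matrix (from
#'   [normalize_matrix()]).
#' @param totals named numeric of counted specimens per slice.
#' @param per_slice if `TRUE`, a separate threshold is chosen per slice
#'   (sensitivity-analysis variant); the default is the single global
#'   threshold.
#' @param renormalize if `TRUE`, surviving cells of each slice are rescaled
#'   to sum to the slice total again; by default zeroed mass is discarded so
#'   that each surviving cell keeps its original estimate.
#' @return list with `zeroed` (matrix), `tau` (threshold; per-slice vector
#'   when `per_slice = TRUE`), `index` (per-slice counts/ASV-3 index after
#'   zeroing; `NA` for empty slices) and `flagged_slices`.
#' @export
background_zero <- function(est, totals, per_slice = FALSE,
                            renormalize = FALSE) {
  totals <- totals[colnames(est)]
  informative <- !is.na(totals) & totals > 1 & colSums(est > 0) > 0
  # slices that cannot satisfy the index: zeroed entirely, flagged
  hopeless <- colnames(est)[!informative & colSums(est > 0) > 0]

  # candidate thresholds: zero plus the multiset of all positive cell values
  taus <- sort(unique(c(0, est[est > 0])))
  satisfied <- function(cols, tau) {
    z <- est[, cols, drop = FALSE]
    z[z < tau] <- 0
    nnz <- colSums(z > 0)
    all(nnz > 0 & totals[cols] / nnz > 1)
  }
  solve_cols <- function(cols) {
    for (tau in taus) if (satisfied(cols, tau)) return(tau)
    NA_real_
  }

  cols <- colnames(est)[informative]
  zeroed <- est
  zeroed[, !informative] <- 0
  if (per_slice) {
    tau <- stats::setNames(rep(NA_real_, ncol(est)), colnames(est))
    for (s in cols) {
      t_s <- solve_cols(s)
      if (is.na(t_s)) {
        zeroed[, s] <- 0
        hopeless <- c(hopeless, s)
      } else {
        tau[s] <- t_s
        zeroed[zeroed[, s] < t_s, s] <- 0
      }
    }
  } else {
    tau <- NA_real_
    work <- cols
    repeat {
      tau <- solve_cols(work)
      if (!is.na(tau) || !length(work)) break
      # no single global threshold satisfies every slice jointly. First
      # drop slices that no threshold can fix on their own (tied cells);
      # if all are individually solvable the conflict is between slices
      # needing a high threshold and slices whose largest cell is small --
      # drop (zero and flag) the slice with the smallest maximum cell, as
      # its profile carries the least reliable signal, and retry.
      bad <- work[vapply(work, function(s) is.na(solve_cols(s)), logical(1))]
      if (!length(bad)) {
        maxcell <- vapply(work, function(s) max(est[, s]), numeric(1))
        bad <- work[which.min(maxcell)]
      }
      zeroed[, bad] <- 0
      hopeless <- c(hopeless, bad)
      work <- setdiff(work, bad)
    }
    if (is.na(tau)) tau <- 0
    if (length(work)) {
      z <- zeroed[, work, drop = FALSE]
      z[z < tau] <- 0
      zeroed[, work] <- z
    }
  }
  if (renormalize) {
    for (s in colnames(zeroed)) {
      cs <- sum(zeroed[, s])
      if (cs > 0) zeroed[, s] <- zeroed[, s] / cs * totals[[s]]
    }
  }
  list(zeroed = zeroed, tau = tau,
       index = slice_index(zeroed, totals),
       flagged_slices = unique(hopeless))
}

#' Areal abundance from a specimen-count table
#'
#' Converts sorted-specimen counts into individuals per square metre,
#' normalized to 1 cm of horizon thickness, given the 9.4-cm-diameter core:
#' `value = sum(counts) / (n_cores * core_area_m2 * thickness_cm)`.
#'
#' @param counts a count table (data.frame with columns `site`, `core`,
#'   `horizon_top_cm`, `horizon_bottom_cm`, `taxon_group`, `count`).
#' @param n_cores number of replicate cores pooled per site.
#' @param horizon_scheme slice thicknesses defining the admissible horizon
#'   intervals.
#' @return data.frame: site, horizon_top_cm, horizon_bottom_cm,
#'   individuals_per_m2_per_cm.
#' @export
areal_abundance <- function(counts, n_cores,
                            horizon_scheme = c(1, 2, 2, 2, 3, 3, 4)) {
  assert_that(n_cores >= 1, "n_cores must be >= 1")
  b <- horizon_bounds(horizon_scheme)
  ok <- paste(counts$horizon_top_cm, counts$horizon_bottom_cm) %in%
    paste(b[-length(b)], b[-1])
  if (!all(ok))
    stop("unknown horizon interval in rows: ",
         paste(which(!ok), collapse = ", "), call. = FALSE)
  agg <- stats::aggregate(
    list(count = counts$count),
    by = list(site = counts$site, horizon_top_cm = counts$horizon_top_cm,
              horizon_bottom_cm = counts$horizon_bottom_cm),
    FUN = sum)
  thick <- agg$horizon_bottom_cm - agg$horizon_top_cm
  agg$individuals_per_m2_per_cm <-
    agg$count / (n_cores * CORE_AREA_M2 * thick)
  agg[order(agg$site, agg$horizon_top_cm),
      c("site", "horizon_top_cm", "horizon_bottom_cm",
        "individuals_per_m2_per_cm")]
}

#' Sum a specimen-count table
#'
#' @param counts count table (any data.frame with a non-negative integer
#'   `count` column plus `site` and `taxon_group`).
#' @return list with `grand_total`, `per_site` and `per_taxon` margins.
#' @export
sum_count_table <- function(counts) {
  if (nrow(counts) == 0)
    return(list(grand_total = 0L,
                per_site = integer(0), per_taxon = integer(0)))
  assert_that(all(counts$count >= 0), "negative count in table")
  list(grand_total = sum(as.integer(counts$count)),
       per_site = vapply(split(counts$count, counts$site), sum, numeric(1)),
       per_taxon = vapply(split(counts$count, counts$taxon_group), sum,
                          numeric(1)))
}

#' Per-slice specimen totals from a count table
#'
#' @param counts count table.
#' @param site_col,core_col,top_col grouping columns.
#' @return named numeric: slice label (site + core + horizon top) -> total.
#' @export
slice_totals <- function(counts, site_col = "site", core_col = "core",
                         top_col = "horizon_top_cm") {
  key <- paste0(counts[[site_col]], counts[[core_col]], counts[[top_col]])
  vapply(split(counts$count, key), sum, numeric(1))
}
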