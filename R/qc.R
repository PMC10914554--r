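# Read filtering and pair merging: 3' quality truncation, anchored primer
# removal under IUPAC degeneracy, length / N-run filters, and exhaustive
# overlap merging of mate pairs.

#' Quality-control parameters
#'
#' @param quality_cutoff Phred threshold for 3' quality truncation
#'   (running-sum rule); the study default is 25.
#' @param min_length_bp minimum read length after trimming; reads shorter
#'   than this are rejected (default 180).
#' @param max_consecutive_n longest tolerated run of Ns (default 3; a run of
#'   more than 3 Ns rejects the read).
#' @param forward_primer,reverse_primer IUPAC primer sequences anchored at
#'   the 5' end of the respective mate.
#' @param primer_max_mismatch substitutions tolerated in the primer match.
#' @param merge_min_overlap_bp minimum mate overlap in bp.
#' @param merge_max_mismatch_fraction maximum mismatch fraction tolerated in
#'   the overlap.
#' @return an object of class `qc_params`.
#' @export
qc_params <- function(quality_cutoff = 25L,
                      min_length_bp = 180L,
                      max_consecutive_n = 3L,
                      forward_primer = "CCGCGGTAATWCCAGCHY",
                      reverse_primer = "TTGGCAAATGCYTTCGCAKTHG",
                      primer_max_mismatch = 1L,
                      merge_min_overlap_bp = 20L,
                      merge_max_mismatch_fraction = 0.1) {
  assert_that(quality_cutoff >= 0 && quality_cutoff <= 41,
              "quality_cutoff must be a Phred value in [0, 41]")
  assert_that(min_length_bp > 0, "min_length_bp must be positive")
  assert_that(is_iupac(forward_primer) && is_iupac(reverse_primer),
              "primers must contain only IUPAC nucleotide codes")
  out <- list(quality_cutoff = as.integer(quality_cutoff),
              min_length_bp = as.integer(min_length_bp),
              max_consecutive_n = as.integer(max_consecutive_n),
              forward_primer = toupper(forward_primer),
              reverse_primer = toupper(reverse_primer),
              primer_max_mismatch = as.integer(primer_max_mismatch),
              merge_min_overlap_bp = as.integer(merge_min_overlap_bp),
              merge_max_mismatch_fraction = merge_max_mismatch_fraction)
  class(out) <- "qc_params"
  out
}

#' Truncate the low-quality 3' end of a read
#'
#' Running-sum truncation: the retained prefix ends just before the suffix
#' that maximises the cumulative sum of `(cutoff - quality)` taken from the
#' 3' end (the rule used by BWA-style `-q` trimming). A read whose qualities
#' all reach the cutoff is returned unchanged; a read entirely below it is
#' trimmed to length zero.
#'
#' @param seq nucleotide string.
#' @param qual Phred+33 quality string of the same length.
#' @param cutoff Phred threshold.
#' @return list with `seq` and `qual` of the retained prefix.
#' @export
trim_quality_3prime <- function(seq, qual, cutoff) {
  if (nchar(seq) != nchar(qual))
    stop("malformed record: sequence and quality lengths differ",
         call. = FALSE)
  n <- nchar(seq)
  if (n == 0L) return(list(seq = seq, qual = qual))
  q <- qual_to_int(qual)
  # running sum of (cutoff - q) over suffixes, from the 3' end inwards
  s <- cumsum(cutoff - rev(q))
  best <- max(s)
  if (best <= 0) return(list(seq = seq, qual = qual))
  cut_len <- max(which(s == best))   # longest suffix attaining the max
  keep <- n - cut_len
  list(seq = substr(seq, 1L, keep), qual = substr(qual, 1L, keep))
}

# mismatch count of `prefix` characters against an IUPAC pattern;
# an N in the read never matches a non-N pattern position is too strict --
# here N in the read matches any pattern letter (standard degenerate rule:
# intersection of base sets non-empty).
iupac_mismatches <- function(prefix, pattern) {
  pv <- chars(pattern)
  rv <- chars(prefix)
  n <- length(pv)
  mism <- 0L
  for (k in seq_len(n)) {
    pset <- IUPAC_SETS[[pv[k]]]
    rset <- IUPAC_SETS[[rv[k]]]
    if (is.null(rset) || length(intersect(pset, rset)) == 0L)
      mism <- mism + 1L
  }
  mism
}

#' Remove a 5'-anchored primer from a read
#'
#' The primer (IUPAC degeneracy respected) must match the start of the read
#' with at most `max_mismatch` substitutions; the matched prefix is removed.
#' Reads without an admissible match are rejected.
#'
#' @param seq nucleotide string.
#' @param qual optional quality string trimmed alongside.
#' @param primer IUPAC primer string.
#' @param max_mismatch tolerated substitutions.
#' @return list with `seq`, `qual` (primer removed) and `rejected` flag.
#' @export
remove_primer <- function(seq, qual = NULL, primer, max_mismatch = 1L) {
  assert_that(nchar(primer) > 0, "primer must be non-empty")
  if (!is_iupac(primer))
    stop("configuration error: primer contains non-IUPAC characters",
         call. = FALSE)
  plen <- nchar(primer)
  if (nchar(seq) < plen)
    return(list(seq = seq, qual = qual, rejected = TRUE))
  mism <- iupac_mismatches(substr(seq, 1L, plen), toupper(primer))
  if (mism > max_mismatch)
    return(list(seq = seq, qual = qual, rejected = TRUE))
  list(seq = substr(seq, plen + 1L, nchar(seq)),
       qual = if (is.null(qual)) NULL else substr(qual, plen + 1L, nchar(qual)),
       rejected = FALSE)
}

#' Length and N-run read filter
#'
#' Rejects a (trimmed) read iff it is shorter than `min_length_bp` or
#' contains a run of more than `max_consecutive_n` Ns.
#'
#' @param seq nucleotide string.
#' @param params a [qc_params()].
#' @return list with `pass` (logical) and `reason` (`NA`, `"short"` or
#'   `"n_run"`).
#' @export
filter_read <- function(seq, params) {
  if (nchar(seq) < params$min_length_bp)
    return(list(pass = FALSE, reason = "short"))
  n_run <- strrep("N", params$max_consecutive_n + 1L)
  if (grepl(n_run, seq, fixed = TRUE))
    return(list(pass = FALSE, reason = "n_run"))
  list(pass = TRUE, reason = NA_character_)
}

# count mismatches between two equal-length strings (byte-wise)
str_mismatches <- function(a, b) sum(charToRaw(a) != charToRaw(b))

#' Merge a mate pair by exhaustive ungapped overlap scan
#'
#' The reverse mate is reverse-complemented; every overlap length from the
#' maximum possible down to `merge_min_overlap_bp` is scored, and the overlap
#' maximising `matches - mismatches` subject to the mismatch-fraction bound
#' is accepted. Inside the overlap the base with the higher Phred quality
#' wins (ties go to the forward mate). Amplicons here are short enough
#' (<= 445 bp) that the exhaustive scan is cheap.
#'
#' @param fwd_seq,fwd_qual forward mate and its qualities.
#' @param rev_seq,rev_qual reverse mate and its qualities (as sequenced;
#'   reverse-complemented internally).
#' @param params a [qc_params()].
#' @return list with `merged` (sequence or `NA` on rejection), `qual`,
#'   `overlap` (bp) and `rejected` flag.
#' @export
merge_pair <- function(fwd_seq, fwd_qual, rev_seq, rev_qual, params) {
  rc <- revcomp(rev_seq)
  rcq <- paste(rev(chars(rev_qual)), collapse = "")
  lf <- nchar(fwd_seq); lr <- nchar(rc)
  best_o <- 0L; best_score <- -Inf; best_mism <- 0L
  o_max <- min(lf, lr)
  if (o_max < params$merge_min_overlap_bp)
    return(list(merged = NA_character_, qual = NA_character_,
                overlap = 0L, rejected = TRUE))
  for (o in seq.int(o_max, params$merge_min_overlap_bp)) {
    a <- substr(fwd_seq, lf - o + 1L, lf)
    b <- substr(rc, 1L, o)
    mism <- if (a == b) 0L else str_mismatches(a, b)
    if (mism / o > params$merge_max_mismatch_fraction) next
    score <- o - 2L * mism
    if (score > best_score) {
      best_score <- score; best_o <- o; best_mism <- mism
    }
    if (mism == 0L) break  # no longer-scoring exact overlap can follow
  }
  if (best_o == 0L)
    return(list(merged = NA_character_, qual = NA_character_,
                overlap = 0L, rejected = TRUE))
  o <- best_o
  fa <- chars(substr(fwd_seq, lf - o + 1L, lf))
  fb <- chars(substr(rc, 1L, o))
  qa <- qual_to_int(substr(fwd_qual, lf - o + 1L, lf))
  qb <- qual_to_int(substr(rcq, 1L, o))
  take_b <- qb > qa
  cons <- ifelse(take_b, fb, fa)
  consq <- pmax(qa, qb)
  merged <- paste0(substr(fwd_seq, 1L, lf - o),
                   paste(cons, collapse = ""),
                   substr(rc, o + 1L, lr))
  mq <- paste0(substr(fwd_qual, 1L, lf - o), int_to_qual(consq),
               substr(rcq, o + 1L, lr))
  list(merged = merged, qual = mq, overlap = o, rejected = FALSE,
       mismatches = best_mism)
}

#' Run the full QC stage on one slice's mate pairs
#'
#' Applies, in order: 3' quality truncation on both mates, anchored primer
#' removal (forward primer on R1, reverse primer on R2), the length and
#' N-run filter on both mates, and pair merging. A failure in either mate
#' rejects the pair.
#'
#' @param fwd,rev data.frames with columns `id`, `seq`, `qual` (equal row
#'   order; mates of a pair share a row).
#' @param params a [qc_params()].
#' @return list with `merged` (data.frame: id, seq, qual), and `stats`
#'   (named counts: n_raw_pairs, n_filtered_pairs, n_merged).
#' @export
qc_slice <- function(fwd, rev, params = qc_params()) {
  stopifnot(nrow(fwd) == nrow(rev))
  n_raw <- nrow(fwd)
  # identical pairs (common for low-error amplicon data) are processed once
  key <- paste(fwd$seq, fwd$qual, rev$seq, rev$qual, sep = "\r")
  first <- !duplicated(key)
  uidx <- which(first)
  umap <- match(key, key[first])
  u_out <- vector("list", length(uidx))
  for (k in seq_along(uidx)) {
    r <- uidx[k]
    f <- trim_quality_3prime(fwd$seq[r], fwd$qual[r], params$quality_cutoff)
    b <- trim_quality_3prime(rev$seq[r], rev$qual[r], params$quality_cutoff)
    f <- remove_primer(f$seq, f$qual, params$forward_primer,
                       params$primer_max_mismatch)
    if (f$rejected) { u_out[[k]] <- list(stage = 0L); next }
    b <- remove_primer(b$seq, b$qual, params$reverse_primer,
                       params$primer_max_mismatch)
    if (b$rejected) { u_out[[k]] <- list(stage = 0L); next }
    if (!filter_read(f$seq, params)$pass ||
        !filter_read(b$seq, params)$pass) {
      u_out[[k]] <- list(stage = 0L); next
    }
    m <- merge_pair(f$seq, f$qual, b$seq, b$qual, params)
    u_out[[k]] <- if (m$rejected) list(stage = 1L)
    else list(stage = 2L, seq = m$merged, qual = m$qual)
  }
  stage <- vapply(u_out, `[[`, integer(1), "stage")[umap]
  keep <- stage == 2L
  merged <- data.frame(
    id = fwd$id[keep],
    seq = vapply(u_out[umap[keep]], `[[`, character(1), "seq"),
    qual = vapply(u_out[umap[keep]], `[[`, character(1), "qual"),
    stringsAsFactors = FALSE)
  list(merged = merged,
       stats = c(n_raw_pairs = n_raw,
                 n_filtered_pairs = sum(stage >= 1L),
                 n_merged = sum(keep)))
}
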