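# Abiotic covariate ingestion: grain-size fractionation into clay/silt/sand
# with the silt/clay ratio, and validation of the per-slice abiotic table.

CLAY_CUT_UM <- 4
SAND_CUT_UM <- 63

#' Fractionate a grain-size spectrum into clay, silt and sand
#'
#' Clay is mass below 4 um, silt between 4 and 63 um, sand above 63 um.
#' Point bins are classified by their size; bins given with explicit
#' (`size_low_um`, `size_high_um`) edges that straddle a cut point are split
#' pro-rata on the log-size axis. The silt/clay ratio is `silt% / clay%`,
#' undefined (flagged `NA`) when the clay fraction is zero.
#'
#' @param spectrum data.frame with columns `size_um` and `fraction`
#'   (mass fractions summing to 1 within 1e-6), optionally `size_low_um` and
#'   `size_high_um` bin edges.
#' @return list with `clay_percent`, `silt_percent`, `sand_percent` (summing
#'   to 100) and `silt_clay_ratio` (`NA` when clay is absent).
#' @export
fractionate <- function(spectrum) {
  f <- spectrum$fraction
  assert_that(all(f >= 0), "mass fractions must be non-negative")
  assert_that(abs(sum(f) - 1) <= 1e-6, "mass fractions must sum to 1")
  clay <- silt <- sand <- 0
  has_edges <- all(c("size_low_um", "size_high_um") %in% names(spectrum))
  for (r in seq_len(nrow(spectrum))) {
    if (has_edges) {
      lo <- spectrum$size_low_um[r]; hi <- spectrum$size_high_um[r]
      part <- split_bin_log(lo, hi) * f[r]
    } else {
      s <- spectrum$size_um[r]
      part <- c(clay = 0, silt = 0, sand = 0)
      part[if (s < CLAY_CUT_UM) "clay"
           else if (s <= SAND_CUT_UM) "silt" else "sand"] <- f[r]
    }
    clay <- clay + part[["clay"]]
    silt <- silt + part[["silt"]]
    sand <- sand + part[["sand"]]
  }
  list(clay_percent = 100 * clay, silt_percent = 100 * silt,
       sand_percent = 100 * sand,
       silt_clay_ratio = if (clay > 0) silt / clay else NA_real_)
}

# proportion of a (lo, hi) um bin falling in each class, log-linear split
split_bin_log <- function(lo, hi) {
  assert_that(lo > 0 && hi > lo, "bin edges must satisfy 0 < low < high")
  ll <- log(lo); lh <- log(hi)
  seg <- function(a, b) max(0, min(lh, log(b)) - max(ll, log(a))) / (lh - ll)
  c(clay = seg(1e-12, CLAY_CUT_UM),
    silt = seg(CLAY_CUT_UM, SAND_CUT_UM),
    sand = seg(SAND_CUT_UM, Inf))
}

# dominant Shepard class from the three fractions (convenience label)
shepard_class <- function(clay, silt, sand) {
  c("clay", "silt", "sand")[which.max(c(clay, silt, sand))]
}

ABIOTIC_REQUIRED <- c("site", "horizon_top_cm", "horizon_bottom_cm",
                      "depth_m", "protein", "carbohydrate",
                      "silt_clay_ratio", "sand_percent", "oxygen")

#' Validate and enrich an abiotic table
#'
#' Checks required columns and numeric types, computes horizon midpoints
#' from the slice boundaries (e.g. the 7-10 cm slice has midpoint 8.5 cm)
#' and appends standardised (zero-mean, unit-sd) copies of every analysis
#' variable, suffixed `_z`.
#'
#' @param table data.frame with the columns listed in `ABIOTIC_REQUIRED`.
#' @param horizon_scheme slice thicknesses the horizons must conform to.
#' @return the validated, enriched data.frame (adds `horizon_cm` midpoint
#'   and `*_z` columns).
#' @export
validate_abiotic_table <- function(table,
                                   horizon_scheme = c(1, 2, 2, 2, 3, 3, 4)) {
  assert_that(nrow(table) > 0, "empty abiotic table")
  missing <- setdiff(ABIOTIC_REQUIRED, names(table))
  if (length(missing))
    stop("missing abiotic column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  num_cols <- setdiff(ABIOTIC_REQUIRED, "site")
  for (cc in num_cols)
    if (!is.numeric(table[[cc]]))
      stop("non-numeric values in abiotic column '", cc, "'", call. = FALSE)
  b <- horizon_bounds(horizon_scheme)
  ok <- paste(table$horizon_top_cm, table$horizon_bottom_cm) %in%
    paste(b[-length(b)], b[-1])
  if (!all(ok))
    stop("horizon interval not in the slicing scheme, rows: ",
         paste(which(!ok), collapse = ", "), call. = FALSE)
  table$horizon_cm <- (table$horizon_top_cm + table$horizon_bottom_cm) / 2
  vars <- c("protein", "carbohydrate", "silt_clay_ratio", "sand_percent",
            "oxygen", "depth_m", "horizon_cm")
  for (v in vars) table[[paste0(v, "_z")]] <- as.vector(scale(table[[v]]))
  table
}
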