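# Hill-number diversity (q = 0, 1): observed values, asymptotic (Chao-type)
# estimates, hypergeometric rarefaction with Chao-style extrapolation, and
# bootstrap uncertainty on the estimator.

#' Combine replicate cores into one slice abundance vector
#'
#' Element-wise sum of the per-core estimated counts, normalized per 1 cm of
#' horizon thickness, then rounded half-to-even to integers (the frequency-
#' count estimators require integer abundances). Slices where rounding
#' changes the observed richness are flagged.
#'
#' @param profiles list of named numeric vectors (one per core) sharing the
#'   same cluster index, or a matrix with clusters as rows and cores as
#'   columns.
#' @param thickness_cm slice thickness in cm.
#' @return list with `x` (named integer abundances) and
#'   `rounding_changed_richness` (logical).
#' @export
combine_replicates <- function(profiles, thickness_cm = 1) {
  if (is.list(profiles)) {
    ids <- names(profiles[[1]])
    for (p in profiles)
      if (!identical(names(p), ids))
        stop("replicate profiles have mismatched cluster indices",
             call. = FALSE)
    m <- do.call(cbind, profiles)
  } else m <- profiles
  combined <- rowSums(m) / thickness_cm
  x <- round(combined)  # round() is half-to-even in R
  list(x = stats::setNames(as.integer(x), rownames(m) %||% names(x)),
       rounding_changed_richness = sum(x > 0) != sum(combined > 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

freq_counts <- function(x) {
  x <- x[x > 0]
  list(n = sum(x), S_obs = length(x),
       f1 = sum(x == 1), f2 = sum(x == 2), x = x)
}

#' Observed Hill number
#'
#' `q = 0`: number of species with positive abundance. `q = 1`: exponential
#' of the Shannon entropy of the relative abundances.
#'
#' @param x non-negative abundance vector.
#' @param q Hill order, 0 or 1.
#' @return observed diversity (effective number of species).
#' @export
hill_observed <- function(x, q) {
  assert_that(q %in% c(0, 1), "only Hill orders 0 and 1 are supported")
  x <- x[x > 0]
  assert_that(length(x) > 0, "diversity of an all-zero vector is undefined")
  if (q == 0) return(length(x))
  p <- x / sum(x)
  exp(-sum(p * log(p)))
}

# Chao1 lower-bound richness estimator (classic form)
chao1 <- function(x) {
  f <- freq_counts(x)
  if (f$f2 > 0) f$S_obs + f$f1^2 / (2 * f$f2)
  else f$S_obs + f$f1 * (f$f1 - 1) / 2
}

# Chao-Jost low-bias entropy estimator (singleton-corrected)
chao_entropy <- function(x) {
  f <- freq_counts(x)
  n <- f$n; xs <- f$x
  if (n <= 1) return(0)
  part1 <- sum(vapply(xs[xs <= n - 1], function(xi)
    xi / n * sum(1 / seq.int(xi, n - 1L)), numeric(1)))
  f1 <- f$f1; f2 <- f$f2
  A <- if (f2 > 0) 2 * f2 / ((n - 1) * f1 + 2 * f2)
  else if (f1 > 0) 2 / ((n - 1) * (f1 - 1) + 2)
  else 1
  part2 <- 0
  if (f1 > 0 && A < 1) {
    r <- seq_len(n - 1L)
    part2 <- f1 / n * (1 - A)^(1 - n) *
      (-log(A) - sum((1 - A)^r / r))
  }
  part1 + part2
}

#' Estimated (asymptotic) Hill number
#'
#' `q = 0`: the Chao1 richness estimator, `S_obs + f1^2 / (2 f2)` (or the
#' `f1 (f1 - 1) / 2` correction when doubletons are absent). `q = 1`: the
#' exponential of the singleton-corrected low-bias Shannon entropy
#' estimator.
#'
#' @inheritParams hill_observed
#' @return estimated asymptotic diversity.
#' @export
hill_estimated <- function(x, q) {
  assert_that(q %in% c(0, 1), "only Hill orders 0 and 1 are supported")
  assert_that(sum(x) > 0, "diversity of an all-zero vector is undefined")
  if (q == 0) chao1(x) else exp(chao_entropy(x))
}

# expected richness of a hypergeometric subsample of size m (rarefaction)
rarefy_q0 <- function(x, m) {
  f <- freq_counts(x)
  n <- f$n; xs <- f$x
  if (m >= n) return(f$S_obs)
  # S_obs - sum_i C(n - x_i, m) / C(n, m), computed on log scale
  lc <- function(a, b) ifelse(b > a, -Inf, lchoose(a, b))
  f$S_obs - sum(exp(lc(n - xs, m) - lchoose(n, m)))
}

# interpolated Hill q=1 at subsample size m (expected entropy of the
# subsample via expected subsample frequency counts)
rarefy_q1 <- function(x, m) {
  f <- freq_counts(x)
  n <- f$n; xs <- f$x
  if (m >= n) return(hill_observed(x, 1))
  if (m == 1) return(1)
  k <- seq_len(m)
  h <- 0
  for (xi in xs) {
    # E[#individuals k of species i in subsample] ~ hypergeometric
    lp <- lchoose(xi, k) + lchoose(n - xi, m - k) - lchoose(n, m)
    pk <- exp(lp)
    ok <- is.finite(lp)
    h <- h - sum(pk[ok] * (k[ok] / m) * log(k[ok] / m))
  }
  exp(h)
}

# extrapolated richness at n + mstar (Chao-style, approaches Chao1)
extrapolate_q0 <- function(x, m) {
  f <- freq_counts(x)
  n <- f$n
  mstar <- m - n
  if (mstar <= 0) return(rarefy_q0(x, m))
  f0 <- chao1(x) - f$S_obs
  if (f0 <= 0 || f$f1 == 0) return(f$S_obs)
  f$S_obs + f0 * (1 - (1 - f$f1 / (n * f0 + f$f1))^mstar)
}

# extrapolated q=1 at n + mstar: entropy blended towards its asymptotic
# estimate with weights n/(n+m*) and m*/(n+m*); anchors at the observed
# value and approaches exp(chao_entropy) as m* grows
extrapolate_q1 <- function(x, m) {
  f <- freq_counts(x)
  n <- f$n
  mstar <- m - n
  if (mstar <= 0) return(rarefy_q1(x, m))
  h_obs <- log(hill_observed(x, 1))
  h_inf <- max(chao_entropy(x), h_obs)
  exp((n / (n + mstar)) * h_obs + (mstar / (n + mstar)) * h_inf)
}

#' Rarefaction / extrapolation curve of a Hill number
#'
#' For `m <= n` the expected diversity of a hypergeometric subsample of size
#' `m`; for `m > n` a Chao-style extrapolation approaching the asymptotic
#' estimate. The curve equals the observed value at `m = n` and is
#' non-decreasing in `m`. Extrapolation beyond `2n` is reported but marked
#' unreliable.
#'
#' @param x non-negative integer abundance vector.
#' @param q Hill order (0 or 1).
#' @param m_grid positive integer sample sizes.
#' @return data.frame: m, method (`"rarefaction"`, `"observed"`,
#'   `"extrapolation"`), diversity, reliable.
#' @export
rarefy_extrapolate <- function(x, q, m_grid) {
  assert_that(all(m_grid >= 1), "sample sizes must be positive integers")
  assert_that(q %in% c(0, 1), "only Hill orders 0 and 1 are supported")
  n <- sum(x)
  fn <- if (q == 0) function(m)
    if (m <= n) rarefy_q0(x, m) else extrapolate_q0(x, m)
  else function(m) if (m <= n) rarefy_q1(x, m) else extrapolate_q1(x, m)
  data.frame(
    m = as.integer(m_grid),
    method = ifelse(m_grid < n, "rarefaction",
                    ifelse(m_grid == n, "observed", "extrapolation")),
    diversity = vapply(as.numeric(m_grid), fn, numeric(1)),
    reliable = m_grid <= 2 * n,
    stringsAsFactors = FALSE)
}

# Chao-adjusted bootstrap community: detection-adjusted probabilities for
# observed species plus f0 equally likely undetected species
bootstrap_community <- function(x) {
  f <- freq_counts(x)
  n <- f$n; xs <- f$x
  C_hat <- if (f$f1 == 0) 1 else {
    denom <- (n - 1) * f$f1 + 2 * f$f2
    1 - f$f1 / n * (if (denom > 0) (n - 1) * f$f1 / denom else 1)
  }
  p_obs <- xs / n
  w <- p_obs * (1 - p_obs)^n
  lambda <- if (sum(w) > 0) (1 - C_hat) / sum(w) else 0
  p_adj <- pmax(p_obs * (1 - lambda * (1 - p_obs)^n), 0)
  f0 <- max(0L, ceiling(chao1(x) - f$S_obs))
  p0 <- if (f0 > 0) rep((1 - C_hat) / f0, f0) else numeric(0)
  p <- c(p_adj, p0)
  p / sum(p)
}

#' Bootstrap standard error and confidence interval of a Hill estimate
#'
#' Resamples `n` individuals from the Chao-adjusted community (observed
#' species with detection-adjusted probabilities plus the estimated number
#' of undetected species) `B` times, recomputes the asymptotic estimator on
#' each replicate, and reports the standard deviation and the percentile
#' 95% interval.
#'
#' @param x non-negative integer abundance vector.
#' @param q Hill order (0 or 1).
#' @param B bootstrap replicates (>= 50).
#' @param seed RNG seed for reproducibility.
#' @param ci `"percentile"` (default) or `"normal"`.
#' @return list with `estimate`, `se`, `ci95` (length-2 numeric).
#' @export
bootstrap_se <- function(x, q, B = 200L, seed = NULL, ci = c("percentile",
                                                             "normal")) {
  ci <- match.arg(ci)
  assert_that(B >= 50, "B must be at least 50")
  est <- hill_estimated(x, q)
  n <- sum(x)
  p <- bootstrap_community(x)
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      xb <- as.vector(stats::rmultinom(1L, n, p))
      hill_estimated(xb, q)
    }, numeric(1))
  })
  se <- stats::sd(reps)
  ci95 <- if (ci == "percentile")
    unname(stats::quantile(reps, c(0.025, 0.975), type = 7))
  else est + c(-1.96, 1.96) * se
  list(estimate = est, se = se, ci95 = ci95)
}

#' Full diversity estimate for one sample
#'
#' Bundles the observed and estimated Hill numbers, bootstrap uncertainty
#' and the rarefaction/extrapolation curve.
#'
#' @param x non-negative integer abundance vector.
#' @param q Hill order (0 or 1).
#' @param B bootstrap replicates.
#' @param seed RNG seed.
#' @param m_grid sample-size grid for the curve; default 20 points up to 2n.
#' @return object of class `diversity_estimate`.
#' @export
diversity_estimate <- function(x, q, B = 200L, seed = NULL, m_grid = NULL) {
  n <- sum(x)
  assert_that(n > 0, "diversity of an all-zero vector is undefined")
  if (is.null(m_grid))
    m_grid <- unique(pmax(1L, round(seq(1L, 2L * n, length.out = 20L))))
  bs <- bootstrap_se(x, q, B = B, seed = seed)
  structure(list(q = q,
                 observed = hill_observed(x, q),
                 estimated = bs$estimate,
                 se = bs$se, ci95 = bs$ci95,
                 curve = rarefy_extrapolate(x, q, m_grid),
                 n = n),
            class = "diversity_estimate")
}
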