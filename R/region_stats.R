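#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided KS test of whether two samples share a distribution,
#' used to compare per-gene expression levels of a chromosome region
#' between the variant and the control. The statistic D is the
#' supremum distance between the two empirical distribution functions.
#' The p-value is computed exactly when the effective sample size
#' n_x*n_y/(n_x+n_y) is below `exact_threshold` and by the asymptotic
#' Kolmogorov distribution otherwise (both via [stats::ks.test()]).
#'
#' @param x,y numeric samples.
#' @param exact_threshold effective-sample-size cutoff below which the
#'   exact null distribution is used; default 35.
#' @return A list of class `ks_result`: `D`, `p_value`, `n_x`, `n_y`,
#'   `direction` (sign of median(x) - median(y)).
#' @export
ks_two_sample <- function(x, y, exact_threshold = 35) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1 || length(y) < 1) stop("empty sample in KS test")
  ne <- length(x) * length(y) / (length(x) + length(y))
  kt <- suppressWarnings(
    stats::ks.test(x, y, alternative = "two.sided",
                   exact = ne < exact_threshold)
  )
  structure(list(D = unname(kt$statistic),
                 p_value = kt$p.value,
                 n_x = length(x), n_y = length(y),
                 direction = sign(stats::median(x) - stats::median(y))),
            class = "ks_result")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test of association, used to compare up-regulated
#' gene proportions between chromosome regions (e.g. duplicated vs
#' non-duplicated arm). The two-sided p-value follows the probability
#' criterion: the sum of hypergeometric probabilities of all tables
#' with the observed margins whose probability does not exceed that of
#' the observed table (within a small relative tolerance for ties),
#' as in [stats::fisher.test()]. The reported odds ratio is the
#' sample odds ratio (a*d)/(b*c), not the conditional MLE.
#'
#' @param a,b,c,d cell counts, row-wise: `rbind(c(a, b), c(c, d))`.
#' @return A list of class `fisher_result`: `table`, `odds_ratio`
#'   (Inf when b*c = 0 with a*d > 0, NaN for degenerate tables),
#'   `p_value`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("all-zero 2x2 table")
  tab <- matrix(as.numeric(counts), nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  or <- (a * d) / (b * c)  # sample OR; 0/0 -> NaN, x/0 -> Inf
  structure(list(table = tab, odds_ratio = or, p_value = ft$p.value),
            class = "fisher_result")
}

#' Binomial proportion with Wilson 95% confidence interval
#'
#' Point estimate k/n with the Wilson score interval, the appropriate
#' choice for the small cytological counts summarized here (n of a
#' few dozen cells).
#'
#' @param k number of successes.
#' @param n number of trials, >= 1.
#' @param conf confidence level, default 0.95.
#' @return A list of class `proportion_result`: `k`, `n`, `estimate`,
#'   `ci_low`, `ci_high`.
#' @export
proportion_ci <- function(k, n, conf = 0.95) {
  if (n < 1) stop("n must be >= 1")
  if (k < 0 || k > n) stop("k must be in [0, n]")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  ci_low <- if (k == 0) 0 else max(0, center - half)
  ci_high <- if (k == n) 1 else min(1, center + half)
  structure(list(k = k, n = n, estimate = p,
                 ci_low = min(ci_low, p), ci_high = max(ci_high, p)),
            class = "proportion_result")
}

#' Region-stratified KS tests of expression change
#'
#' For each region, tests variant vs control expression values of the
#' region's genes (the default mode), or alternatively the region's
#' ratio distribution against the pooled genome-background ratio
#' distribution (`mode = "ratio_vs_background"`). Only genes expressed
#' in both samples enter.
#'
#' @param pair an `expression_pair`.
#' @param region_map named character vector `gene_id -> region_id`.
#' @param regions region ids to test (default: all in `region_map`).
#' @param mode `"paired_expression"` (default) or
#'   `"ratio_vs_background"`.
#' @return A `data.frame`: `region_id`, `n`, `D`, `p_value`,
#'   `direction`.
#' @export
ks_region_scan <- function(pair, region_map, regions = NULL,
                           mode = c("paired_expression", "ratio_vs_background")) {
  mode <- match.arg(mode)
  reg <- region_map[match(pair$gene_id, names(region_map))]
  if (is.null(regions)) regions <- unique(unname(region_map))
  both <- pair$control > 0 & pair$variant > 0
  rows <- lapply(regions, function(rid) {
    sel <- both & reg == rid
    if (sum(sel) < 2) {
      return(data.frame(region_id = rid, n = sum(sel), D = NA_real_,
                        p_value = NA_real_, direction = NA_real_))
    }
    if (mode == "paired_expression") {
      res <- ks_two_sample(pair$variant[sel], pair$control[sel])
    } else {
      ratio <- pair$variant / pair$control
      res <- ks_two_sample(ratio[sel], ratio[both & !sel])
    }
    data.frame(region_id = rid, n = sum(sel), D = res$D,
               p_value = res$p_value, direction = res$direction)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
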