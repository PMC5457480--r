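# Round half-up to `digits` decimals; base round() is round-half-even,
# which would render 34.5972 -> 34.6 but 8.265 -> 8.26 vs 8.27
# inconsistently with the printed tables.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Per-gene expression ratio scores with dosage classification
#'
#' Computes the ratio score r = variant/control for every gene
#' expressed in both samples, and assigns each gene one of six
#' mutually exclusive classes:
#' \describe{
#'   \item{up}{r >= `theta_up` (default 2), or expressed only in the
#'     variant (`control_zero`, an extreme up-regulation)}
#'   \item{down}{r <= `theta_down` (default 0.5), or expressed only in
#'     the control (`variant_zero`)}
#'   \item{neutral}{ratio defined, between the thresholds}
#'   \item{control_zero / variant_zero / both_zero}{zero-handling
#'     classes; the first two count as up/down respectively in region
#'     summaries but carry no finite ratio}
#' }
#' Thresholds are inclusive: a gene at exactly 2.0 is a positive
#' dosage effect (4 copies vs 2), one at exactly 0.5 an inverse
#' dosage effect.
#'
#' @param pair an `expression_pair`.
#' @param theta_up,theta_down classification thresholds on the ratio.
#' @return A `data.frame` of class `ratio_table`: `gene_id`, `control`,
#'   `variant`, `ratio` (NA when undefined), `class`.
#' @export
compute_ratios <- function(pair, theta_up = 2.0, theta_down = 0.5) {
  stopifnot(inherits(pair, "data.frame"),
            all(c("gene_id", "control", "variant") %in% names(pair)))
  ctl <- pair$control
  var <- pair$variant
  ratio <- ifelse(ctl > 0 & var > 0, var / ctl, NA_real_)
  class_ <- rep("neutral", nrow(pair))
  class_[ctl == 0 & var == 0] <- "both_zero"
  class_[ctl == 0 & var > 0] <- "control_zero"
  class_[ctl > 0 & var == 0] <- "variant_zero"
  defined <- !is.na(ratio)
  class_[defined & ratio >= theta_up] <- "up"
  class_[defined & ratio <= theta_down] <- "down"
  out <- data.frame(gene_id = pair$gene_id, control = ctl, variant = var,
                    ratio = ratio, class = class_, stringsAsFactors = FALSE)
  attr(out, "theta_up") <- theta_up
  attr(out, "theta_down") <- theta_down
  class(out) <- c("ratio_table", "data.frame")
  out
}

# up/down indicator on the summary-table semantics: zero-handling
# classes count toward up/down, both_zero genes are not expressed.
.is_up <- function(rt) rt$class %in% c("up", "control_zero")
.is_down <- function(rt) rt$class %in% c("down", "variant_zero")
.is_expressed <- function(rt) rt$class != "both_zero"

#' Sliding-window median ratio profile along chromosomes
#'
#' Slides a window of `W` genes (default 100) in steps of `step` genes
#' (default 1) over the coordinate-ordered genes with defined ratios,
#' independently per chromosome (windows never span chromosomes), and
#' records the median ratio of each window. Chromosomes with fewer
#' than `W` usable genes produce no windows. Genes with undefined
#' ratios (zero in either sample) are skipped, so adding such genes
#' leaves the profile unchanged.
#'
#' @param ratios a `ratio_table` from [compute_ratios()].
#' @param catalog the [gene_catalog()] giving gene order.
#' @param W window size in genes.
#' @param step slide step in genes.
#' @return A `data.frame`: `chrom`, `start_gene`, `end_gene`,
#'   `center_index` (index of the window center among the chromosome's
#'   usable genes), `median_ratio`.
#' @export
sliding_window_median <- function(ratios, catalog, W = 100, step = 1) {
  if (W < 1) stop("window size W must be >= 1")
  if (step < 1) stop("step must be >= 1")
  stopifnot(inherits(catalog, "gene_catalog"))
  r <- ratios$ratio[match(catalog$gene_id, ratios$gene_id)]
  keep <- !is.na(r)
  chrom <- catalog$chrom[keep]
  gid <- catalog$gene_id[keep]
  r <- r[keep]
  out <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    n <- length(idx)
    if (n < W) next
    starts <- seq.int(1L, n - W + 1L, by = step)
    med <- vapply(starts, function(s) {
      stats::median(r[idx[s:(s + W - 1L)]])
    }, numeric(1))
    out[[ch]] <- data.frame(chrom = ch,
                            start_gene = gid[idx[starts]],
                            end_gene = gid[idx[starts + W - 1L]],
                            center_index = starts + (W - 1) / 2,
                            median_ratio = med,
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start_gene = character(),
                      end_gene = character(), center_index = numeric(),
                      median_ratio = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Binned ratio distribution
#'
#' Histograms the defined ratio scores of a gene set into right-open
#' bins `[k*w, (k+1)*w)` of width `w` (default 0.05), with a single
#' overflow bin for ratios at or above `cap` (default 5.0). Counts sum
#' to the number of defined ratios among the selected genes.
#'
#' @param ratios a `ratio_table`.
#' @param region_genes optional character vector of gene ids to
#'   restrict to (default: all genes in the table).
#' @param w bin width.
#' @param cap overflow threshold; must be a positive multiple of `w`.
#' @return A `data.frame` of class `ratio_histogram`: `bin_low`,
#'   `bin_high`, `bin_center`, `count`, `overflow`; attribute
#'   `n_total`.
#' @export
bin_ratio_distribution <- function(ratios, region_genes = NULL,
                                   w = 0.05, cap = 5.0) {
  if (w <= 0) stop("bin width w must be > 0")
  if (cap <= 0 || abs(cap / w - round(cap / w)) > 1e-8) {
    stop("cap must be a positive multiple of w")
  }
  r <- ratios$ratio
  if (!is.null(region_genes)) r <- r[ratios$gene_id %in% region_genes]
  r <- r[!is.na(r)]
  n_bins <- as.integer(round(cap / w))
  # floor(r/w) with guard against 0.15/0.05 -> 2.9999... landing one
  # bin low
  bin <- floor(r / w + 1e-9)
  bin[r >= cap] <- n_bins  # overflow
  counts <- tabulate(bin + 1L, nbins = n_bins + 1L)
  lo <- (0:n_bins) * w
  hi <- c((1:n_bins) * w, Inf)
  out <- data.frame(bin_low = lo, bin_high = hi,
                    bin_center = ifelse(is.finite(hi), (lo + hi) / 2, NA_real_),
                    count = counts,
                    overflow = c(rep(FALSE, n_bins), TRUE))
  attr(out, "n_total") <- length(r)
  attr(out, "w") <- w
  class(out) <- c("ratio_histogram", "data.frame")
  out
}

#' Region-stratified differential-expression summary table
#'
#' For each region: the number of expressed genes (FPKM > 0 in at
#' least one sample), the up- and down-regulated counts under the
#' ratio classification, and their percentages rounded half-up to two
#' decimals. A `Total` row sums all regions.
#'
#' @param ratios a `ratio_table`.
#' @param region_map named character vector `gene_id -> region_id`
#'   from [assign_regions()]; must cover every gene in `ratios`.
#' @param region_order optional ordering of region ids for the output
#'   rows; defaults to first appearance in `region_map`.
#' @return A `data.frame`: `region_id`, `n_expressed`, `n_up`,
#'   `up_pct`, `n_down`, `down_pct`, plus a final `Total` row.
#'   Empty regions report 0.00 percentages with `empty = TRUE`.
#' @export
summarize_regions <- function(ratios, region_map, region_order = NULL) {
  reg <- region_map[match(ratios$gene_id, names(region_map))]
  if (anyNA(reg)) {
    stop("region_map does not cover gene(s): ",
         ratios$gene_id[is.na(reg)][1])
  }
  if (is.null(region_order)) region_order <- unique(unname(region_map))
  expressed <- .is_expressed(ratios)
  up <- .is_up(ratios)
  down <- .is_down(ratios)
  rows <- lapply(region_order, function(rid) {
    sel <- reg == rid
    n_exp <- sum(sel & expressed)
    n_up <- sum(sel & up)
    n_down <- sum(sel & down)
    data.frame(region_id = rid, n_expressed = n_exp,
               n_up = n_up,
               up_pct = if (n_exp > 0) round_half_up(100 * n_up / n_exp) else 0.00,
               n_down = n_down,
               down_pct = if (n_exp > 0) round_half_up(100 * n_down / n_exp) else 0.00,
               empty = n_exp == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n_exp <- sum(expressed); n_up <- sum(up); n_down <- sum(down)
  total <- data.frame(region_id = "Total", n_expressed = n_exp,
                      n_up = n_up,
                      up_pct = if (n_exp > 0) round_half_up(100 * n_up / n_exp) else 0.00,
                      n_down = n_down,
                      down_pct = if (n_exp > 0) round_half_up(100 * n_down / n_exp) else 0.00,
                      empty = n_exp == 0, stringsAsFactors = FALSE)
  out <- rbind(out, total)
  rownames(out) <- NULL
  out
}

#' Dosage-effect fraction of a region
#'
#' The fraction of a region's expressed genes classified up-regulated
#' (ratio at or above the dosage threshold, or variant-only
#' expression). Under a pure dosage effect of a 2x duplication this
#' fraction approaches the proportion of genes whose expression scales
#' with copy number.
#'
#' @param ratios a `ratio_table`.
#' @param region_genes character vector of the region's gene ids.
#' @return A list with `k` (up genes), `n` (expressed genes in the
#'   region), `fraction` = k/n, and `pct` = 100*k/n rounded half-up to
#'   2 decimals.
#' @export
dosage_effect_fraction <- function(ratios, region_genes) {
  sel <- ratios$gene_id %in% region_genes
  n <- sum(sel & .is_expressed(ratios))
  if (n == 0) stop("no expressed genes in region")
  k <- sum(sel & .is_up(ratios))
  list(k = k, n = n, fraction = k / n, pct = round_half_up(100 * k / n))
}

#' Dosage-compensation call from a ratio histogram
#'
#' Locates the modal (highest-count, non-overflow) bin of a ratio
#' histogram; ties break toward the smaller bin center. The region is
#' called compensated when the modal bin center lies within `tau` of
#' 1.0 (expression buffered back to the diploid level) and
#' dosage-responding when it lies within `tau` of 2.0 (expression
#' tracking the doubled copy number).
#'
#' @param hist a `ratio_histogram` from [bin_ratio_distribution()].
#' @param tau peak tolerance around 1.0 / 2.0, default 0.10.
#' @return A list: `modal_bin_center`, `modal_count`,
#'   `has_peak_at_one`, `has_peak_at_two`, `tau`.
#' @export
assess_compensation <- function(hist, tau = 0.10) {
  stopifnot(inherits(hist, "ratio_histogram"))
  h <- hist[!hist$overflow, , drop = FALSE]
  if (sum(hist$count) == 0) stop("empty ratio histogram")
  best <- which(h$count == max(h$count))[1]  # rows ordered by center
  center <- h$bin_center[best]
  list(modal_bin_center = center,
       modal_count = h$count[best],
       has_peak_at_one = abs(center - 1.0) <= tau,
       has_peak_at_two = abs(center - 2.0) <= tau,
       tau = tau)
}
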