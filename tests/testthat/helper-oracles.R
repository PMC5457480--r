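# Independent brute-force oracles, kept free of package internals.

# KS statistic as the supremum ECDF distance evaluated at every pooled
# data point.
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}

# Two-sided Fisher p by full enumeration of all 2x2 tables with the
# observed margins, summing those no more probable than the observed
# table (probability criterion, relative tie tolerance 1e-7).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Changepoint by explicit loops over split points and segment means,
# written independently of detect_breakpoint().
oracle_changepoint <- function(R) {
  y <- log2(R)
  n <- length(y)
  best_j <- NA
  best_sse <- Inf
  for (j in 1:(n - 1)) {
    left <- y[1:j]; right <- y[(j + 1):n]
    sse <- sum((left - mean(left))^2) + sum((right - mean(right))^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best_j <- j
    }
  }
  list(j = best_j, sse = best_sse)
}

# Small temp-file writers for IO tests.
write_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal GFF3 text for n gene features.
gff3_lines <- function(chrom, start, end, id, strand = "+") {
  c("##gff-version 3",
    sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            chrom, start, end, strand, id))
}
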