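toy_pair <- function(ctl, var) {
  expression_pair(paste0("g", seq_along(ctl)), ctl,
                  paste0("g", seq_along(var)), var)
}

test_that("ratio classes follow the stated rules on the six-gene table", {
  rt <- compute_ratios(toy_pair(c(1, 1, 2, 0, 1, 0), c(1, 2, 1, 1, 0, 0)))
  expect_equal(rt$class, c("neutral", "up", "down", "control_zero",
                           "variant_zero", "both_zero"))
  expect_equal(sum(!is.na(rt$ratio)), 3)
  expect_equal(rt$ratio[1:3], c(1, 2, 0.5))
})

test_that("classification thresholds are inclusive", {
  rt <- compute_ratios(toy_pair(c(1, 1, 1, 1.9999), c(2, 0.5, 1.9999, 1)))
  expect_equal(rt$class, c("up", "down", "neutral", "neutral"))
})

test_that("class partition is exhaustive over random pairs", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    ctl <- ifelse(runif(n) < 0.2, 0, rlnorm(n))
    var <- ifelse(runif(n) < 0.2, 0, rlnorm(n))
    rt <- compute_ratios(toy_pair(ctl, var))
    counts <- table(factor(rt$class, levels = c("up", "down", "neutral",
                                                "control_zero",
                                                "variant_zero", "both_zero")))
    expect_equal(sum(counts), n)
    expect_equal(sum(!is.na(rt$ratio)),
                 sum(rt$class %in% c("up", "down", "neutral")))
  }
})

test_that("window medians are plain order statistics per chromosome", {
  cat <- gene_catalog(paste0("g", 1:4), rep("Chr1", 4),
                      (1:4) * 100, (1:4) * 100 + 50)
  rt <- compute_ratios(toy_pair(rep(1, 4), c(1, 1, 1, 5)))
  prof <- sliding_window_median(rt, cat, W = 3, step = 1)
  expect_equal(prof$median_ratio, c(1, 1))

  rt2 <- compute_ratios(toy_pair(rep(1, 4), rep(1, 4)))
  expect_equal(sliding_window_median(rt2, cat, W = 2)$median_ratio,
               rep(1, 3))
})

test_that("windows never span chromosomes and need W usable genes", {
  cat <- gene_catalog(paste0("g", 1:6), rep(c("Chr1", "Chr2"), each = 3),
                      rep((1:3) * 100, 2), rep((1:3) * 100 + 50, 2))
  rt <- compute_ratios(toy_pair(rep(1, 6), c(1, 2, 3, 4, 5, 6)))
  prof <- sliding_window_median(rt, cat, W = 3)
  expect_equal(nrow(prof), 2)  # one window per chromosome
  expect_equal(prof$chrom, c("Chr1", "Chr2"))
  expect_equal(prof$median_ratio, c(2, 5))
  expect_equal(nrow(sliding_window_median(rt, cat, W = 4)), 0)
  expect_error(sliding_window_median(rt, cat, W = 0), "W")
  expect_error(sliding_window_median(rt, cat, W = 3, step = 0), "step")
})

test_that("window medians are bounded and ignore undefined ratios", {
  set.seed(55)
  for (i in 1:10) {
    n <- 60
    cat <- gene_catalog(paste0("g", 1:n), rep("Chr1", n),
                        (1:n) * 1000, (1:n) * 1000 + 100)
    var <- rlnorm(n)
    rt <- compute_ratios(toy_pair(rep(1, n), var))
    prof <- sliding_window_median(rt, cat, W = 7)
    r <- rt$ratio[match(cat$gene_id, rt$gene_id)]
    for (k in seq_len(nrow(prof))) {
      i0 <- match(prof$start_gene[k], cat$gene_id)
      i1 <- match(prof$end_gene[k], cat$gene_id)
      expect_gte(prof$median_ratio[k], min(r[i0:i1]))
      expect_lte(prof$median_ratio[k], max(r[i0:i1]))
    }
    # interleave genes with undefined ratios: profile unchanged
    cat2 <- gene_catalog(c(cat$gene_id, paste0("z", 1:20)),
                         rep("Chr1", n + 20),
                         c(cat$start, (1:20) * 1000 + 500),
                         c(cat$end, (1:20) * 1000 + 600))
    rt2 <- compute_ratios(toy_pair(c(rep(1, n), rep(0, 20)),
                                   c(var, rep(1, 20))))
    rt2$gene_id <- c(paste0("g", 1:n), paste0("z", 1:20))
    prof2 <- sliding_window_median(rt2, cat2, W = 7)
    expect_equal(prof2$median_ratio, prof$median_ratio)
  }
})

test_that("ratio binning uses right-open 0.05 bins with an overflow cap", {
  rt <- compute_ratios(toy_pair(rep(1, 5), c(1.00, 0.02, 0.04, 0.06, 7)))
  h <- bin_ratio_distribution(rt, w = 0.05, cap = 5)
  expect_equal(h$count[h$bin_low == 1.00], 1)  # 1.00 -> [1.00, 1.05)
  expect_equal(h$count[h$bin_low == 0.00], 2)  # 0.02, 0.04
  expect_equal(h$count[h$bin_low == 0.05], 1)  # 0.06
  expect_equal(h$count[h$overflow], 1)         # 7 >= cap
  expect_equal(sum(h$count), attr(h, "n_total"))
  expect_error(bin_ratio_distribution(rt, w = 0.05, cap = 0.07), "multiple")
})

test_that("histogram mass equals the region's defined-ratio count", {
  set.seed(77)
  for (i in 1:10) {
    n <- sample(20:300, 1)
    ctl <- ifelse(runif(n) < 0.15, 0, rlnorm(n))
    var <- ifelse(runif(n) < 0.15, 0, rlnorm(n))
    rt <- compute_ratios(toy_pair(ctl, var))
    genes <- sample(rt$gene_id, sample(n, 1))
    h <- bin_ratio_distribution(rt, genes)
    expect_equal(sum(h$count),
                 sum(!is.na(rt$ratio) & rt$gene_id %in% genes))
  }
})

test_that("region summary reproduces the published percentages", {
  t1 <- make_table1_pair()
  rt <- compute_ratios(t1$pair)
  st <- summarize_regions(rt, t1$region_map)
  ref <- table1_counts()
  for (i in seq_len(nrow(ref))) {
    row <- st[st$region_id == ref$region_id[i], ]
    expect_equal(row$n_expressed, ref$n_expressed[i])
    expect_equal(row$n_up, ref$n_up[i])
    expect_equal(row$n_down, ref$n_down[i])
  }
  s2 <- st[st$region_id == "11S-2", ]
  expect_equal(c(s2$up_pct, s2$down_pct), c(34.60, 3.79))
  tot <- st[st$region_id == "Total", ]
  expect_equal(c(tot$n_expressed, tot$up_pct, tot$down_pct),
               c(23604, 5.55, 4.18))
})

test_that("zero-only genes count toward up/down but not histograms", {
  pair <- toy_pair(c(0, 1, 1, 0), c(1, 0, 1, 0))
  rt <- compute_ratios(pair)
  st <- summarize_regions(rt, setNames(rep("R", 4), pair$gene_id))
  row <- st[st$region_id == "R", ]
  expect_equal(row$n_expressed, 3)  # both_zero gene not expressed
  expect_equal(row$n_up, 1)         # control_zero
  expect_equal(row$n_down, 1)       # variant_zero
  expect_equal(sum(bin_ratio_distribution(rt)$count), 1)
})

test_that("empty regions render flagged 0.00 rows", {
  pair <- toy_pair(1, 2)
  rt <- compute_ratios(pair)
  map <- setNames("A", pair$gene_id)
  st <- summarize_regions(rt, map, region_order = c("A", "B"))
  b <- st[st$region_id == "B", ]
  expect_equal(c(b$n_expressed, b$up_pct, b$down_pct), c(0, 0, 0))
  expect_true(b$empty)
})

test_that("compensation call picks the modal bin with ties to smaller center", {
  rt <- compute_ratios(toy_pair(rep(1, 3), rep(1, 3)))
  call <- assess_compensation(bin_ratio_distribution(rt))
  expect_true(call$has_peak_at_one)
  expect_false(call$has_peak_at_two)
  expect_equal(call$modal_bin_center, 1.025)

  # bins centered 0.975 and 2.025 tied -> smaller center wins
  rt2 <- compute_ratios(toy_pair(rep(1, 4), c(0.96, 0.97, 2.01, 2.02)))
  call2 <- assess_compensation(bin_ratio_distribution(rt2))
  expect_equal(call2$modal_bin_center, 0.975)

  empty <- compute_ratios(toy_pair(0, 1))
  expect_error(assess_compensation(bin_ratio_distribution(empty)), "empty")
})

test_that("dosage-effect fraction matches hand arithmetic", {
  ctl <- rep(1, 211)
  var <- c(rep(2, 73), rep(0.6, 138))
  rt <- compute_ratios(toy_pair(ctl, var))
  res <- dosage_effect_fraction(rt, rt$gene_id)
  expect_equal(res$k, 73)
  expect_equal(res$n, 211)
  expect_equal(res$pct, 34.60)

  rt2 <- compute_ratios(toy_pair(rep(1, 10), rep(1, 10)))
  expect_equal(dosage_effect_fraction(rt2, rt2$gene_id)$pct, 0)
  expect_error(dosage_effect_fraction(rt2, character(0)), "no expressed")
})

test_that("noiseless dosage fraction equals the realized truth fraction", {
  cfg <- expression_sim_config(
    n_genes_per_region = c("11S-2" = 211, "Chr1" = 500),
    pi_dosage = 0.346, noise_log_sd = 0, seed = 13)
  sim <- simulate_expression_pair(cfg)
  rt <- compute_ratios(sim$pair)
  dup <- sim$truth$gene_id[sim$truth$region == "11S-2"]
  res <- dosage_effect_fraction(rt, dup)
  expect_equal(res$fraction,
               mean(sim$truth$multiplier[sim$truth$region == "11S-2"] == 2))
})

test_that("noisy dosage-fraction estimates track their sampling expectation", {
  # With multiplicative noise, genes at multiplier exactly 2 exceed the
  # inclusive threshold with probability 1/2 and partial-effect genes
  # occasionally cross it, so the naive up-fraction estimates
  # p_up = pi_d/2 + (1-pi_d) E[Phi(log(d/2)/sigma)], not pi_d itself.
  sigma <- 0.25
  pi_d <- 0.346
  p_partial <- integrate(function(d) pnorm(log(d / 2) / sigma), 1, 2)$value
  p_up <- pi_d * 0.5 + (1 - pi_d) * p_partial
  est <- vapply(1:30, function(s) {
    sim <- simulate_expression_pair(expression_sim_config(
      n_genes_per_region = c("11S-2" = 211, "Chr1" = 50),
      pi_dosage = pi_d, noise_log_sd = sigma, seed = 1000 + s))
    rt <- compute_ratios(sim$pair)
    dup <- sim$truth$gene_id[sim$truth$region == "11S-2"]
    dosage_effect_fraction(rt, dup)$fraction
  }, numeric(1))
  se <- sqrt(p_up * (1 - p_up) / 211)
  expect_lt(abs(mean(est) - p_up), 4 * se / sqrt(30))
})
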