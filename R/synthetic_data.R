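# Independent sub-streams per component (control expression, dosage
# assignment, noise, qPCR) derived from one master seed, so e.g.
# enlarging the gene catalog does not perturb qPCR draws.
sub_seed <- function(seed, component) {
  offsets <- c(control = 1L, dosage = 2L, noise = 3L, qpcr = 4L)
  if (!component %in% names(offsets)) stop("unknown RNG component")
  as.integer((as.numeric(seed) * 48271 + offsets[[component]] * 7919) %%
               2147483629)
}

#' Configuration for the expression-pair simulator
#'
#' Defaults encode the study conditions the analysis was designed
#' for: one control and one variant library, 23,604 expressed genes
#' over 12 chromosomes with the chromosome-11 arm split into 11S-1 /
#' 11S-2 / 11L, the 211-gene 11S-2 segment duplicated, 34.6% of its
#' genes showing a full 2x dosage effect, genome-wide background
#' up/down fractions of 5.55% / 4.18%, and multiplicative log-normal
#' expression noise.
#'
#' @param n_genes_per_region named integer vector, region -> gene
#'   count. Region names matching `partition` rows are placed inside
#'   that interval of the partition's chromosome; other names are
#'   whole chromosomes.
#' @param duplicated_regions regions carrying the 2x duplication.
#' @param pi_dosage fraction of duplicated-region genes with a full
#'   dosage multiplier of 2.0.
#' @param pi_compensated fraction with multiplier 1.0 (fully
#'   buffered); the remainder get a partial effect, uniform in (1, 2).
#' @param background_up_fraction,background_down_fraction genome-wide
#'   trans-effect fractions outside duplicated regions; up genes draw
#'   a multiplier 2*U(1,2), down genes 0.5*U(0.5,1).
#' @param baseline_log_mean,baseline_log_sd natural-log-scale mean and
#'   sd of control FPKM (log-normal baseline).
#' @param noise_log_sd natural-log-scale sd of the multiplicative
#'   noise applied to the variant; 0 gives a noiseless simulation.
#' @param partition a [region_partition()] giving coordinates for the
#'   named regions; default [chr11_partition()].
#' @param seed master RNG seed (mandatory).
#' @return A list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes_per_region = NULL,
                                  duplicated_regions = "11S-2",
                                  pi_dosage = 0.346,
                                  pi_compensated = 0.0,
                                  background_up_fraction = 0.0555,
                                  background_down_fraction = 0.0418,
                                  baseline_log_mean = 1.0,
                                  baseline_log_sd = 1.2,
                                  noise_log_sd = 0.25,
                                  partition = chr11_partition(),
                                  seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(n_genes_per_region)) {
    tc <- table1_counts()
    n_genes_per_region <- stats::setNames(tc$n_expressed, tc$region_id)
  }
  fr <- c(pi_dosage, pi_compensated, background_up_fraction,
          background_down_fraction)
  if (any(fr < 0) || any(fr > 1)) stop("fractions must be in [0, 1]")
  if (pi_dosage + pi_compensated > 1) {
    stop("pi_dosage + pi_compensated must be <= 1")
  }
  if (noise_log_sd < 0) stop("noise_log_sd must be >= 0")
  bad <- setdiff(duplicated_regions, names(n_genes_per_region))
  if (length(bad) > 0) {
    stop("duplicated region(s) with no genes declared: ",
         paste(bad, collapse = ", "))
  }
  if (any(n_genes_per_region[duplicated_regions] == 0)) {
    stop("duplicated region declared with zero genes")
  }
  structure(list(n_genes_per_region = n_genes_per_region,
                 duplicated_regions = duplicated_regions,
                 pi_dosage = pi_dosage, pi_compensated = pi_compensated,
                 background_up_fraction = background_up_fraction,
                 background_down_fraction = background_down_fraction,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 noise_log_sd = noise_log_sd,
                 partition = partition, seed = as.integer(seed)),
            class = "expression_sim_config")
}

# Catalog skeleton: evenly spaced genes per region. Regions listed in
# the partition sit inside their interval on the partition chromosome;
# any other region name is treated as a whole chromosome of that name.
.sim_catalog <- function(n_genes_per_region, partition,
                         chrom_length = 3e7, gene_width = 2000L) {
  regions <- names(n_genes_per_region)
  rows <- lapply(regions, function(rid) {
    n <- n_genes_per_region[[rid]]
    if (n == 0) return(NULL)
    in_part <- !is.null(partition) && rid %in% partition$region_id
    if (in_part) {
      p <- partition[partition$region_id == rid, ]
      chrom <- p$chrom; lo <- p$start; hi <- p$end
    } else {
      chrom <- rid; lo <- 1; hi <- chrom_length
    }
    start <- floor(seq(lo, hi - gene_width, length.out = n))
    safe <- gsub("[^A-Za-z0-9]", "", rid)
    data.frame(gene_id = sprintf("%s_g%05d", safe, seq_len(n)),
               chrom = chrom, start = as.integer(start),
               end = as.integer(start + gene_width - 1L),
               region = rid, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a matched control/variant expression pair
#'
#' Control FPKM values are drawn log-normally; each gene carries a
#' true dosage multiplier d and the variant value is
#' control * d * noise with log-normal multiplicative noise. Inside
#' duplicated regions d = 2 with probability `pi_dosage` (full dosage
#' effect), 1 with probability `pi_compensated` (full compensation),
#' and uniform in (1, 2) otherwise (partial effect). Outside, d = 1
#' except for the background up/down fractions. Fully reproducible
#' from the config seed; the control-expression, dosage-assignment
#' and noise draws use separate sub-streams.
#'
#' @param config an [expression_sim_config()].
#' @return A list: `catalog` ([gene_catalog()]), `pair`
#'   (`expression_pair`), `truth` (`data.frame` with `gene_id`,
#'   `region`, `multiplier`), `region_map`, `config`.
#' @export
simulate_expression_pair <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  skel <- .sim_catalog(config$n_genes_per_region, config$partition)
  n <- nrow(skel)

  set.seed(sub_seed(config$seed, "dosage"))
  d <- rep(1.0, n)
  dup <- skel$region %in% config$duplicated_regions
  if (any(dup)) {
    u <- stats::runif(sum(dup))
    kind <- ifelse(u < config$pi_dosage, "dosage",
                   ifelse(u < config$pi_dosage + config$pi_compensated,
                          "compensated", "partial"))
    dd <- rep(NA_real_, sum(dup))
    dd[kind == "dosage"] <- 2.0
    dd[kind == "compensated"] <- 1.0
    npart <- sum(kind == "partial")
    dd[kind == "partial"] <- stats::runif(npart, 1, 2)
    d[dup] <- dd
  }
  if (any(!dup)) {
    u <- stats::runif(sum(!dup))
    bg <- rep("none", sum(!dup))
    bg[u < config$background_up_fraction] <- "up"
    bg[u >= config$background_up_fraction &
         u < config$background_up_fraction + config$background_down_fraction] <- "down"
    db <- rep(1.0, sum(!dup))
    db[bg == "up"] <- 2 * stats::runif(sum(bg == "up"), 1, 2)
    db[bg == "down"] <- 0.5 * stats::runif(sum(bg == "down"), 0.5, 1)
    d[!dup] <- db
  }

  set.seed(sub_seed(config$seed, "control"))
  control <- stats::rlnorm(n, config$baseline_log_mean,
                           config$baseline_log_sd)

  set.seed(sub_seed(config$seed, "noise"))
  eps <- if (config$noise_log_sd > 0) {
    stats::rlnorm(n, 0, config$noise_log_sd)
  } else {
    rep(1.0, n)
  }
  variant <- control * d * eps

  catalog <- gene_catalog(skel$gene_id, skel$chrom, skel$start, skel$end)
  pair <- expression_pair(skel$gene_id, control, skel$gene_id, variant)
  truth <- data.frame(gene_id = skel$gene_id, region = skel$region,
                      multiplier = d, stringsAsFactors = FALSE)
  region_map <- stats::setNames(skel$region, skel$gene_id)[catalog$gene_id]
  list(catalog = catalog, pair = pair, truth = truth,
       region_map = region_map, config = config)
}

#' Configuration for the qPCR plate simulator
#'
#' Defaults mirror the breakpoint-mapping design: 21 markers ordered
#' along the chromosome arm, relative copy level stepping from 1.0
#' (2:2) to 2.0 (2:4) after the 10th marker, 4 experiments with
#' technical triplicates, and Gaussian Ct noise per well.
#'
#' @param n_markers number of ordered markers (>= 2).
#' @param breakpoint_after_index the step lies between this marker and
#'   the next; 0 puts the whole panel at the right level, `n_markers`
#'   at the left level (no step within the panel).
#' @param copy_levels numeric length-2 `(left_ratio, right_ratio)`.
#' @param ct_noise_sd per-well Ct noise sd, in cycles.
#' @param n_experiments,n_replicates experiment and technical
#'   replicate counts.
#' @param ct_base,ct_ref_base noiseless Ct of a single-copy marker
#'   assay and of the reference assay.
#' @param seed master RNG seed (mandatory).
#' @return A list of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(n_markers = 21, breakpoint_after_index = 10,
                            copy_levels = c(1.0, 2.0), ct_noise_sd = 0.1,
                            n_experiments = 4, n_replicates = 3,
                            ct_base = 25, ct_ref_base = 20, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_markers < 2) stop("n_markers must be >= 2")
  if (breakpoint_after_index < 0 || breakpoint_after_index > n_markers) {
    stop("breakpoint_after_index must be in [0, n_markers]")
  }
  if (length(copy_levels) != 2 || any(copy_levels <= 0)) {
    stop("copy_levels must be two positive ratios")
  }
  if (ct_noise_sd < 0) stop("ct_noise_sd must be >= 0")
  structure(list(n_markers = as.integer(n_markers),
                 breakpoint_after_index = as.integer(breakpoint_after_index),
                 copy_levels = copy_levels, ct_noise_sd = ct_noise_sd,
                 n_experiments = as.integer(n_experiments),
                 n_replicates = as.integer(n_replicates),
                 ct_base = ct_base, ct_ref_base = ct_ref_base,
                 seed = as.integer(seed)),
            class = "qpcr_sim_config")
}

#' Simulate a qPCR plate over an ordered marker panel
#'
#' Template amount maps to threshold cycle as Ct = base - log2(T) +
#' noise: in the test sample marker i carries relative amount
#' `left_ratio` up to the breakpoint and `right_ratio` beyond it; the
#' origin sample and the reference assay sit at T = 1. Wells are laid
#' out as experiments x replicates for every marker and for the
#' reference in both samples.
#'
#' @param config a [qpcr_sim_config()].
#' @return A list: `plate` (a [qpcr_plate()]), `truth` (list with
#'   `breakpoint_after_index`, `left_ratio`, `right_ratio`,
#'   `marker_levels`).
#' @export
simulate_qpcr_plate <- function(config) {
  stopifnot(inherits(config, "qpcr_sim_config"))
  set.seed(sub_seed(config$seed, "qpcr"))
  markers <- sprintf("M%02d", seq_len(config$n_markers))
  levels <- ifelse(seq_len(config$n_markers) <= config$breakpoint_after_index,
                   config$copy_levels[1], config$copy_levels[2])
  grid <- expand.grid(experiment = seq_len(config$n_experiments),
                      replicate = seq_len(config$n_replicates),
                      sample = c("test", "origin"),
                      stringsAsFactors = FALSE)
  rows <- list()
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    T_marker <- if (g$sample == "test") levels else rep(1, config$n_markers)
    ct_m <- config$ct_base - log2(T_marker) +
      stats::rnorm(config$n_markers, 0, config$ct_noise_sd)
    ct_r <- config$ct_ref_base + stats::rnorm(1, 0, config$ct_noise_sd)
    rows[[k]] <- data.frame(
      marker_id = c(markers, "REF"),
      sample = g$sample,
      target = c(rep("marker", config$n_markers), "reference"),
      experiment = g$experiment, replicate = g$replicate,
      ct = c(ct_m, ct_r), stringsAsFactors = FALSE)
  }
  wells <- do.call(rbind, rows)
  truth <- list(breakpoint_after_index = config$breakpoint_after_index,
                left_ratio = config$copy_levels[1],
                right_ratio = config$copy_levels[2],
                marker_levels = stats::setNames(levels, markers))
  list(plate = qpcr_plate(wells, markers), truth = truth)
}

#' Published per-region differential-expression counts
#'
#' The per-chromosome counts of expressed, up-regulated and
#' down-regulated genes reported for the duplication variant, with
#' chromosome 11 split into 11L, 11S-1 (non-duplicated short arm) and
#' 11S-2 (duplicated segment). These printed counts drive the
#' count-matched fixture ([make_table1_pair()]) and the default
#' region sizes of the simulator.
#'
#' @return A `data.frame`: `region_id`, `n_expressed`, `n_up`,
#'   `n_down`.
#' @export
table1_counts <- function() {
  data.frame(
    region_id = c(paste0("Chr", 1:10), "11L", "11S-1", "11S-2", "Chr12"),
    n_expressed = c(3386, 2763, 3016, 2047, 1952, 1927, 1789, 1557,
                    1332, 1223, 646, 448, 211, 1307),
    n_up = c(179, 118, 141, 121, 91, 99, 98, 80, 73, 77, 60, 37, 73, 64),
    n_down = c(145, 103, 95, 78, 70, 76, 94, 84, 48, 62, 39, 23, 8, 61),
    stringsAsFactors = FALSE)
}

#' Count-matched expression-pair fixture
#'
#' Builds a deterministic catalog and expression pair whose per-region
#' up/down/neutral counts equal the published summary table exactly:
#' up genes get (control, variant) = (1, 2) (ratio 2.0, the inclusive
#' up threshold), down genes (2, 1) (ratio 0.5), neutral genes (1, 1).
#' Used to validate the summary arithmetic end to end.
#'
#' @param counts a `data.frame` like [table1_counts()].
#' @param partition a [region_partition()] placing the named regions.
#' @return A list: `catalog`, `pair`, `region_map`, `counts`.
#' @export
make_table1_pair <- function(counts = table1_counts(),
                             partition = chr11_partition()) {
  skel <- .sim_catalog(stats::setNames(counts$n_expressed, counts$region_id),
                       partition)
  ctl <- numeric(nrow(skel)); var <- numeric(nrow(skel))
  for (i in seq_len(nrow(counts))) {
    idx <- which(skel$region == counts$region_id[i])
    n_up <- counts$n_up[i]; n_down <- counts$n_down[i]
    cls <- rep("neutral", length(idx))
    cls[seq_len(n_up)] <- "up"
    cls[n_up + seq_len(n_down)] <- "down"
    ctl[idx] <- ifelse(cls == "down", 2, 1)
    var[idx] <- ifelse(cls == "up", 2, 1)
  }
  catalog <- gene_catalog(skel$gene_id, skel$chrom, skel$start, skel$end)
  pair <- expression_pair(skel$gene_id, ctl, skel$gene_id, var)
  region_map <- stats::setNames(skel$region, skel$gene_id)[catalog$gene_id]
  list(catalog = catalog, pair = pair, region_map = region_map,
       counts = counts)
}
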