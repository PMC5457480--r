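#' Load a pipeline configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file. Recognized fields:
#'   `paths` (annotation, control, variant, qpcr_plate, panel_order),
#'   `partition` (list with region_id, chrom, start, end vectors),
#'   `params` (W, step, w, cap, theta_up, theta_down, tau, ks_mode,
#'   fisher_pairs), `out_dir`, `seed`.
#' @return A named list (class `pipeline_config`) with defaults
#'   filled in.
#' @export
load_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  pipeline_config(paths = cfg$paths, partition = cfg$partition,
                  params = cfg$params, out_dir = cfg$out_dir,
                  seed = cfg$seed)
}

#' Assemble a pipeline configuration
#'
#' @param paths named list of input paths (`annotation`, `control`,
#'   `variant`, optionally `qpcr_plate` and `panel_order`).
#' @param partition a [region_partition()], or a list of vectors to
#'   build one, or `NULL` for chromosome-only regions.
#' @param params named list of analysis parameters; unset entries get
#'   the documented defaults (W = 100, step = 1, w = 0.05, cap = 5,
#'   theta_up = 2, theta_down = 0.5, tau = 0.1,
#'   ks_mode = "paired_expression", fisher_pairs = NULL).
#' @param out_dir output directory for stage files and the report.
#' @param seed seed echoed into the report (the analysis itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(paths, partition = NULL, params = list(),
                            out_dir = ".", seed = 1L) {
  defaults <- list(W = 100, step = 1, w = 0.05, cap = 5,
                   theta_up = 2, theta_down = 0.5, tau = 0.1,
                   ks_mode = "paired_expression", fisher_pairs = NULL)
  for (nm in names(defaults)) {
    if (is.null(params[[nm]])) params[[nm]] <- defaults[[nm]]
  }
  if (!is.null(partition) && !inherits(partition, "region_partition")) {
    partition <- region_partition(partition$region_id, partition$chrom,
                                  partition$start, partition$end)
  }
  structure(list(paths = paths, partition = partition, params = params,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full dosage-analysis pipeline
#'
#' Executes annotation/expression loading, ratio computation,
#' sliding-window profiling, per-region histograms and compensation
#' calls, the summary table, region-stratified KS tests, Fisher
#' enrichment tests between configured region pairs, and (when a
#' plate is configured) qPCR breakpoint mapping. All stage outputs
#' are written under `out_dir` as TSV/JSON plus a machine-readable
#' `report.json`; the run is deterministic given the inputs.
#'
#' @param config a [pipeline_config()].
#' @return The report, invisibly (a named list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$params
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  report <- list(package_version = as.character(utils::packageVersion("segdosage")),
                 seed = config$seed, params = p[names(p) != "fisher_pairs"])

  catalog <- load_gene_annotation(config$paths$annotation)
  region_map <- assign_regions(catalog, config$partition)
  pair <- load_expression_pair(config$paths$control, config$paths$variant)
  # restrict to cataloged genes so windows and regions are defined
  pair <- pair[pair$gene_id %in% catalog$gene_id, , drop = FALSE]
  report$counts <- list(catalog_genes = nrow(catalog),
                        joined_genes = nrow(pair))

  ratios <- compute_ratios(pair, theta_up = p$theta_up,
                           theta_down = p$theta_down)
  utils::write.table(ratios, file.path(out, "ratio_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  profile <- sliding_window_median(ratios, catalog, W = p$W, step = p$step)
  utils::write.table(profile, file.path(out, "window_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$counts$windows <- nrow(profile)

  summary_tab <- summarize_regions(ratios, region_map)
  utils::write.table(summary_tab, file.path(out, "summary_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$summary_table <- summary_tab

  region_ids <- unique(unname(region_map))
  comp <- lapply(region_ids, function(rid) {
    genes <- names(region_map)[region_map == rid]
    hist <- bin_ratio_distribution(ratios, genes, w = p$w, cap = p$cap)
    utils::write.table(
      hist, file.path(out, paste0("histogram_", gsub("[^A-Za-z0-9-]", "_", rid), ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (attr(hist, "n_total") == 0) return(NULL)
    c(list(region_id = rid), assess_compensation(hist, tau = p$tau))
  })
  comp <- Filter(Negate(is.null), comp)
  jsonlite::write_json(comp, file.path(out, "compensation_calls.json"),
                       auto_unbox = TRUE, digits = NA)
  report$compensation <- comp

  ks <- ks_region_scan(pair, region_map, mode = p$ks_mode)
  jsonlite::write_json(ks, file.path(out, "ks_tests.json"),
                       auto_unbox = TRUE, digits = NA)
  report$ks_tests <- ks

  if (!is.null(p$fisher_pairs)) {
    ft <- lapply(p$fisher_pairs, function(pr) {
      ra <- summary_tab[summary_tab$region_id == pr[1], ]
      rb <- summary_tab[summary_tab$region_id == pr[2], ]
      res <- fisher_exact_2x2(ra$n_up, ra$n_expressed - ra$n_up,
                              rb$n_up, rb$n_expressed - rb$n_up)
      list(region_a = pr[1], region_b = pr[2],
           odds_ratio = res$odds_ratio, p_value = res$p_value)
    })
    jsonlite::write_json(ft, file.path(out, "fisher_tests.json"),
                         auto_unbox = TRUE, digits = NA)
    report$fisher_tests <- ft
  }

  if (!is.null(config$paths$qpcr_plate)) {
    plate <- read_qpcr_plate(config$paths$qpcr_plate,
                             config$paths$panel_order)
    profile_q <- relative_copy_profile(plate)
    utils::write.table(profile_q, file.path(out, "copy_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bp <- detect_breakpoint(profile_q)
    jsonlite::write_json(unclass(bp), file.path(out, "breakpoint.json"),
                         auto_unbox = TRUE, digits = NA)
    report$breakpoint <- unclass(bp)
  } else {
    report$breakpoint <- "not run"
  }

  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

#' Write the canonical synthetic fixtures to disk
#'
#' Emits, under `out_dir`: the count-matched expression-pair fixture
#' (annotation BED + control/variant TSV), a noiseless duplication
#' simulation with its ground-truth JSON, and a 21-marker qPCR plate
#' with the copy-level step after marker 10 plus its panel-order file
#' and truth JSON.
#'
#' @param out_dir writable output directory.
#' @param seed master seed for the simulated fixtures.
#' @return Named character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()

  t1 <- make_table1_pair()
  paths["table1_bed"] <- write_catalog_bed(
    t1$catalog, file.path(out_dir, "table1_annotation.bed"))
  paths["table1_control"] <- write_expression_tsv(
    t1$pair$gene_id, t1$pair$control, file.path(out_dir, "table1_control.tsv"))
  paths["table1_variant"] <- write_expression_tsv(
    t1$pair$gene_id, t1$pair$variant, file.path(out_dir, "table1_variant.tsv"))

  sim <- simulate_expression_pair(
    expression_sim_config(noise_log_sd = 0, seed = seed))
  paths["sim_bed"] <- write_catalog_bed(
    sim$catalog, file.path(out_dir, "sim_annotation.bed"))
  paths["sim_control"] <- write_expression_tsv(
    sim$pair$gene_id, sim$pair$control, file.path(out_dir, "sim_control.tsv"))
  paths["sim_variant"] <- write_expression_tsv(
    sim$pair$gene_id, sim$pair$variant, file.path(out_dir, "sim_variant.tsv"))
  jsonlite::write_json(sim$truth, file.path(out_dir, "sim_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  paths["sim_truth"] <- file.path(out_dir, "sim_truth.json")

  q <- simulate_qpcr_plate(qpcr_sim_config(seed = seed))
  utils::write.csv(q$plate$wells, file.path(out_dir, "qpcr_plate.csv"),
                   row.names = FALSE, quote = FALSE)
  paths["qpcr_plate"] <- file.path(out_dir, "qpcr_plate.csv")
  writeLines(q$plate$marker_order, file.path(out_dir, "qpcr_panel_order.txt"))
  paths["qpcr_panel"] <- file.path(out_dir, "qpcr_panel_order.txt")
  jsonlite::write_json(q$truth, file.path(out_dir, "qpcr_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  paths["qpcr_truth"] <- file.path(out_dir, "qpcr_truth.json")

  invisible(paths)
}
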