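#' Construct a gene catalog
#'
#' A gene catalog is the ordered spatial backbone for all downstream
#' positional analyses (sliding windows, region assignment). Genes are
#' stored 1-based inclusive and sorted by (chrom, start, gene_id); the
#' sort is total and deterministic so window profiles are reproducible.
#'
#' @param gene_id character vector of unique locus identifiers.
#' @param chrom character vector of chromosome names.
#' @param start,end integer start/end coordinates, 1-based inclusive.
#' @param strand strand codes; anything other than "+" or "-" is stored
#'   as "*" (unknown).
#' @return A `data.frame` of class `gene_catalog` with columns
#'   `gene_id`, `chrom`, `start`, `end`, `strand`, sorted.
#' @export
gene_catalog <- function(gene_id, chrom, start, end,
                         strand = rep("*", length(gene_id))) {
  stopifnot(length(gene_id) == length(chrom),
            length(gene_id) == length(start),
            length(gene_id) == length(end))
  gene_id <- as.character(gene_id)
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  strand <- as.character(strand)
  strand[!strand %in% c("+", "-")] <- "*"
  if (anyNA(start) || anyNA(end)) {
    stop("non-numeric or missing coordinates in gene catalog")
  }
  if (any(start > end)) {
    bad <- gene_id[start > end][1L]
    stop("gene '", bad, "' has start > end")
  }
  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup) > 0) {
    stop("duplicate gene_id in catalog: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  df <- data.frame(gene_id = gene_id, chrom = chrom, start = start,
                   end = end, strand = strand, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$gene_id, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_catalog", "data.frame")
  df
}

#' Load a gene annotation from GFF3 or BED
#'
#' Reads gene models from a GFF3 file (keeping features of type
#' `feature_filter`) or a BED file (all intervals). BED's 0-based
#' half-open coordinates are converted to the 1-based inclusive
#' convention used internally; GFF3 is already 1-based inclusive.
#' Parsing goes through [rtracklayer::import()]; a light pre-validation
#' pass reports the first malformed line by number.
#'
#' @param path path to a `.gff`/`.gff3` or `.bed` file. The format is
#'   taken from the extension unless `format` is given.
#' @param feature_filter GFF3 feature type to keep (column 3), default
#'   `"gene"`. Ignored for BED input.
#' @param id_attribute GFF3 attribute key holding the gene identifier,
#'   default `"ID"`.
#' @param format `"gff3"`, `"bed"`, or `NULL` to infer from extension.
#' @return A [gene_catalog()].
#' @export
load_gene_annotation <- function(path, feature_filter = "gene",
                                 id_attribute = "ID", format = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  format <- match.arg(format, c("gff3", "bed"))
  .validate_annotation_lines(path, format)
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    keep <- as.character(gr$type) == feature_filter
    gr <- gr[keep]
    if (length(gr) == 0) {
      stop("no '", feature_filter, "' features found in ", path)
    }
    ids <- GenomicRanges::mcols(gr)[[id_attribute]]
    if (is.null(ids) || anyNA(ids)) {
      stop("GFF3 attribute '", id_attribute, "' missing for some features")
    }
    ids <- sub("^gene:", "", as.character(ids))
  } else {
    ids <- gr$name
    if (is.null(ids) || anyNA(ids)) {
      stop("BED input must carry a name column (BED6) with gene ids")
    }
  }
  gene_catalog(gene_id = ids,
               chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)))
}

# Pre-pass over annotation text to produce line-numbered parse errors;
# rtracklayer's own errors do not name the offending line.
.validate_annotation_lines <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (format == "bed") {
      if (length(fields) < 3 ||
          is.na(suppressWarnings(as.integer(fields[2]))) ||
          is.na(suppressWarnings(as.integer(fields[3])))) {
        stop("malformed BED line ", i, " in ", path)
      }
    } else {
      if (length(fields) != 9 ||
          is.na(suppressWarnings(as.integer(fields[4]))) ||
          is.na(suppressWarnings(as.integer(fields[5])))) {
        stop("malformed GFF3 line ", i, " in ", path)
      }
    }
  }
  invisible(TRUE)
}

#' Write a gene catalog as BED6
#'
#' Coordinates are converted back to BED's 0-based half-open
#' convention, so a write/reload round trip is the identity.
#'
#' @param catalog a [gene_catalog()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog_bed <- function(catalog, path) {
  stopifnot(inherits(catalog, "gene_catalog"))
  df <- data.frame(chrom = catalog$chrom,
                   start = catalog$start - 1L,
                   end = catalog$end,
                   name = catalog$gene_id,
                   score = 0L,
                   strand = ifelse(catalog$strand == "*", ".", catalog$strand))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Define a chromosome region partition
#'
#' Regions are named half-closed intervals `[start, end]` on a
#' chromosome. Genes whose chromosome has no listed region fall back to
#' a default region named after the chromosome itself, so the partition
#' is always total over a catalog.
#'
#' @param region_id,chrom character vectors naming each region and its
#'   chromosome.
#' @param start,end 1-based inclusive bounds.
#' @return A `data.frame` of class `region_partition`.
#' @export
region_partition <- function(region_id, chrom, start, end) {
  df <- data.frame(region_id = as.character(region_id),
                   chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (any(df$start > df$end)) stop("region with start > end")
  if (anyDuplicated(df$region_id)) stop("duplicate region_id in partition")
  for (ch in unique(df$chrom)) {
    r <- df[df$chrom == ch, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1 && any(r$start[-1] <= r$end[-nrow(r)])) {
      stop("overlapping regions on chromosome ", ch)
    }
  }
  class(df) <- c("region_partition", "data.frame")
  df
}

#' Chromosome 11 arm partition used throughout the analysis
#'
#' The short arm of chromosome 11 is split at the duplication
#' boundaries: `11S-1` is the distal non-duplicated part of the short
#' arm, `11S-2` the duplicated segment spanning 5.4-12.1 Mb, and `11L`
#' the long arm. Other chromosomes fall back to their own name.
#'
#' @param chrom chromosome name carrying the duplication, default
#'   `"Chr11"`.
#' @param dup_start,dup_end duplicated-segment bounds in bp (defaults
#'   5.4e6 and 12.1e6).
#' @param chrom_end last coordinate treated as part of the long arm.
#' @return A [region_partition()] with regions `11S-1`, `11S-2`, `11L`.
#' @export
chr11_partition <- function(chrom = "Chr11", dup_start = 5.4e6,
                            dup_end = 12.1e6, chrom_end = 3.2e7) {
  region_partition(region_id = c("11S-1", "11S-2", "11L"),
                   chrom = rep(chrom, 3),
                   start = c(1, dup_start, dup_end + 1),
                   end = c(dup_start - 1, dup_end, chrom_end))
}

#' Assign every gene to a region
#'
#' A gene belongs to a region iff its start coordinate lies within
#' `[start, end]` of that region (start-anchored assignment avoids
#' ambiguity for genes straddling a boundary). Genes not covered by any
#' listed region get their chromosome name as region, so the map is a
#' total partition of the catalog.
#'
#' @param catalog a [gene_catalog()].
#' @param partition a [region_partition()], or `NULL` for
#'   chromosome-only regions.
#' @return Named character vector, `gene_id -> region_id`, in catalog
#'   order.
#' @export
assign_regions <- function(catalog, partition = NULL) {
  stopifnot(inherits(catalog, "gene_catalog"))
  region <- catalog$chrom
  if (!is.null(partition)) {
    stopifnot(inherits(partition, "region_partition"))
    for (k in seq_len(nrow(partition))) {
      hit <- catalog$chrom == partition$chrom[k] &
        catalog$start >= partition$start[k] &
        catalog$start <= partition$end[k]
      region[hit] <- partition$region_id[k]
    }
  }
  stats::setNames(region, catalog$gene_id)
}

#' Load a matched control/variant expression pair
#'
#' Each file is a two-column TSV (`gene_id`, value; header optional)
#' of FPKM-like non-negative expression values. The two tables are
#' inner-joined on `gene_id`; genes present in only one file are
#' excluded and counted in the attached join log (absence is not
#' evidence of zero expression).
#'
#' @param control_path,variant_path paths to the two TSVs.
#' @return A `data.frame` of class `expression_pair` with columns
#'   `gene_id`, `control`, `variant`; attribute `join_log` records
#'   per-file exclusion counts.
#' @export
load_expression_pair <- function(control_path, variant_path) {
  ctl <- .read_expression_tsv(control_path)
  var <- .read_expression_tsv(variant_path)
  expression_pair(ctl$gene_id, ctl$value, var$gene_id, var$value)
}

#' Build an expression pair from in-memory vectors
#'
#' @param control_ids,control_values gene ids and values of the control
#'   sample.
#' @param variant_ids,variant_values same for the variant sample.
#' @return An `expression_pair`; see [load_expression_pair()].
#' @export
expression_pair <- function(control_ids, control_values,
                            variant_ids, variant_values) {
  stopifnot(length(control_ids) == length(control_values),
            length(variant_ids) == length(variant_values))
  if (anyDuplicated(control_ids)) stop("duplicate gene_id in control table")
  if (anyDuplicated(variant_ids)) stop("duplicate gene_id in variant table")
  if (any(control_values < 0) || any(variant_values < 0)) {
    stop("negative expression value")
  }
  common <- intersect(control_ids, variant_ids)
  m_ctl <- match(common, control_ids)
  m_var <- match(common, variant_ids)
  df <- data.frame(gene_id = as.character(common),
                   control = as.numeric(control_values[m_ctl]),
                   variant = as.numeric(variant_values[m_var]),
                   stringsAsFactors = FALSE)
  attr(df, "join_log") <- c(control_only = length(control_ids) - length(common),
                            variant_only = length(variant_ids) - length(common))
  class(df) <- c("expression_pair", "data.frame")
  df
}

.read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("gene_id", "value"),
                          colClasses = c("character", "character"))
  # tolerate an optional header row
  if (nrow(df) > 0 && is.na(suppressWarnings(as.numeric(df$value[1])))) {
    df <- df[-1, , drop = FALSE]
  }
  value <- suppressWarnings(as.numeric(df$value))
  if (anyNA(value)) {
    stop("non-numeric expression value at line ",
         which(is.na(value))[1], " of ", path)
  }
  if (any(value < 0)) {
    stop("negative expression value at line ",
         which(value < 0)[1], " of ", path)
  }
  data.frame(gene_id = df$gene_id, value = value, stringsAsFactors = FALSE)
}

#' Write an expression table as two-column TSV
#'
#' @param ids,values gene ids and expression values.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(ids, values, path) {
  utils::write.table(data.frame(ids, values), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
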