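#!/usr/bin/env Rscript
# Stage 1: write the canonical inputs every later stage consumes:
# the count-matched expression fixture (annotation + control/variant
# FPKM tables), a noiseless duplication simulation with ground truth,
# and a 21-marker qPCR plate with the copy step after marker 10.

suppressPackageStartupMessages(library(segdosage))
seed <- 1L

paths <- make_fixtures("results/fixtures", seed = seed)
cat("Wrote", length(paths), "fixture files under results/fixtures:\n")
cat(paste(" -", basename(paths)), sep = "\n")

t1 <- read.table(paths[["table1_control"]], sep = "\t")
cat(sprintf("\nExpression fixture: %d genes (expected 23604).\n", nrow(t1)))
plate <- read.csv(paths[["qpcr_plate"]])
cat(sprintf("qPCR fixture: %d wells, %d markers, %d experiments x %d replicates.\n",
            nrow(plate),
            length(unique(plate$marker_id[plate$target == "marker"])),
            max(plate$experiment), max(plate$replicate)))
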