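#!/usr/bin/env Rscript
# Summarise the genomic-island genotyping: archetype proportions among the
# island panel, island size range, and agreement with the planted truth.

library(t6sscan)

run_dir <- "results/run"
set_dir <- "results/synthetic_set"
if (!dir.exists(run_dir)) stop("run analysis/02_detect_and_type.R first")

gt <- read.delim(file.path(run_dir, "genotypes.tsv"))
cat(sprintf("genotyped %d genomes into %d island genotypes\n",
            nrow(gt), length(unique(gt$genotype))))
tab <- table(gt$genotype, gt$archetype)
print(tab)
prop <- 100 * table(gt$genotype) / nrow(gt)
cat("genotype proportions (%):",
    paste(sprintf("%s: %.1f", names(prop), prop), collapse = ", "), "\n")
cat(sprintf("island sizes (flank-inclusive): %.1f - %.1f kbp\n",
            min(gt$island_length_bp) / 1000, max(gt$island_length_bp) / 1000))

truth <- jsonlite::read_json(file.path(set_dir, "truth.json"))
planted <- vapply(gt$genome_id, function(g)
  as.integer(truth$genomes[[g]]$genotype), 0L)
cat(sprintf("adjusted Rand index vs planted archetypes: %.3f\n",
            mclust::adjustedRandIndex(gt$genotype, planted)))

pm <- read.delim(file.path(run_dir, "presence_matrix.tsv"), check.names = FALSE)
cat(sprintf("presence/absence matrix: %d genomes x %d homolog families\n",
            nrow(pm) - 1, ncol(pm) - 1))
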