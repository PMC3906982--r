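#!/usr/bin/env Rscript
# Stage 5: call binding genes (>= 1 FDR-passing peak within +/- 5 kb of the
# gene locus), intersect with the responsive genes, and summarize the
# direct-target bookkeeping.

suppressPackageStartupMessages(library(tfdirect))
datadir <- "results/data"
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

models <- read_gene_models(file.path(datadir, "genes.bed12"), "bed12")
peaks <- read_peaks(file.path(datadir, "peaks_rep1.bed"), fdr_max = 0.01)
de <- read.table("results/tables/de_results.tsv", header = TRUE, sep = "\t",
                 stringsAsFactors = FALSE)
sets <- read_gmt(file.path(datadir, "gene_sets.gmt"))

binding <- binding_genes(peaks, models, flank = 5000)
targets <- call_direct_targets(binding, de)
write_target_calls(targets, "results/tables/target_calls.tsv")

s <- summarize_targets(targets, gene_sets = sets$sets)
jsonlite::write_json(s, "results/tables/target_summary.json",
                     auto_unbox = TRUE, digits = NA, force = TRUE)

cat(sprintf("bound genes: %d; responsive: %d (%d up, %d down)\n",
            s$n_bound, s$n_responsive, s$n_up, s$n_down))
cat(sprintf("direct targets: %d (%d up, %d down) = %.1f%% of responsive\n",
            s$n_targets, s$n_targets_up, s$n_targets_down,
            s$pct_targets_of_responsive))
stopifnot(s$n_targets_up + s$n_targets_down == s$n_targets,
          s$n_targets <= s$n_bound, s$n_targets <= s$n_responsive)
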