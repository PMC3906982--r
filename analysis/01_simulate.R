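#!/usr/bin/env Rscript
# Stage 1: generate the ground-truthed synthetic study (toy genome, gene
# models, two ChIP replicates targeting an inter-replicate window
# correlation of 0.93, a 3-vs-3 expression matrix with planted fold
# changes, and gene sets) and write every artifact under results/data/.

suppressPackageStartupMessages(library(tfdirect))
seed <- 1
outdir <- "results/data"

ds <- simulate_dataset(synthetic_config(), seed = seed, outdir = outdir)

cat("synthetic study written to", outdir, "\n")
cat(sprintf("  genome: %d chromosomes x %d bp, %d genes\n",
            length(ds$chrom_sizes), ds$chrom_sizes[[1]], nrow(ds$models)))
cat(sprintf("  truth: %d bound genes, %d responsive genes, %d direct targets\n",
            length(ds$truth$bound_genes), nrow(ds$truth$responsive_genes),
            length(ds$truth$direct_targets)))
cat(sprintf("  ChIP: %d true sites (%d with planted WTTTAT), %d + %d peaks\n",
            nrow(ds$truth$true_sites), sum(ds$truth$true_sites$motif_planted),
            nrow(ds$peaks_rep1), nrow(ds$peaks_rep2)))
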