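#!/usr/bin/env Rscript
# Stage 3: quantify agreement between the two ChIP replicates as the
# Pearson correlation of tag densities in 200 bp non-overlapping windows,
# genome-wide and restricted to covered windows.

suppressPackageStartupMessages(library(tfdirect))
datadir <- "results/data"
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

sizes <- read_chrom_sizes(file.path(datadir, "chrom.sizes"))
d1 <- window_tag_density(read_tags(file.path(datadir, "tags_rep1.bed")), sizes)
d2 <- window_tag_density(read_tags(file.path(datadir, "tags_rep2.bed")), sizes)

all_win <- replicate_correlation(d1, d2)
covered <- replicate_correlation(d1, d2, nonzero_only = TRUE)

write.table(all_win$per_chrom, "results/tables/replicate_correlation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("genome-wide R = %.4f over %d windows (highly correlated: %s)\n",
            all_win$r, all_win$n_windows, all_win$highly_correlated))
cat(sprintf("covered-windows R = %.4f over %d windows\n",
            covered$r, covered$n_windows))
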