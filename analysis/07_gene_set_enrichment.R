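#!/usr/bin/env Rscript
# Stage 7: hypergeometric over-representation of the direct-target list
# against the gene-set collection, with BH FDR and the fold > 2 / FDR < 1%
# screen.

suppressPackageStartupMessages(library(tfdirect))
datadir <- "results/data"
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

targets <- read.table("results/tables/target_calls.tsv", header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
cond <- read.table(file.path(datadir, "conditions.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
expr <- read_expression(file.path(datadir, "expression.tsv"),
                        setNames(cond$condition, cond$sample))
sets <- read_gmt(file.path(datadir, "gene_sets.gmt"))

study <- targets$gene_id[targets$direct_target]
coll <- gene_set_collection(sets$sets, universe = rownames(expr$values))
ora <- hypergeom_ora(study, coll)
write.table(ora, "results/tables/ora_results.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

kept <- filter_enriched(ora, fold_min = 2.0, fdr_max = 0.01)
cat(sprintf("%d of %d sets pass fold > 2 and FDR < 1%%\n",
            nrow(kept), nrow(ora)))
if (nrow(kept) > 0) {
  for (i in seq_len(nrow(kept))) {
    cat(sprintf("  %-18s k=%d/%d K=%d fold=%.2f fdr=%.3g\n",
                kept$set_name[i], kept$k[i], kept$n[i], kept$K[i],
                kept$fold[i], kept$fdr[i]))
  }
}
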