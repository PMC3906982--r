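#!/usr/bin/env Rscript
# Stage 2: call induction-responsive genes from the expression matrix by
# per-gene ANOVA on log2 intensities and signed fold change of the linear
# condition means, at |FC| >= 1.5 and P < 0.01.

suppressPackageStartupMessages(library(tfdirect))
datadir <- "results/data"
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

cond <- read.table(file.path(datadir, "conditions.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
expr <- read_expression(file.path(datadir, "expression.tsv"),
                        setNames(cond$condition, cond$sample))

de <- call_responsive(expr, control = "control")
write_de_results(de, "results/tables/de_results.tsv")

s <- summarize_de(de)
cat(sprintf("responsive genes: %d of %d (%d up, %d down)\n",
            s$n_responsive, nrow(de), s$n_up, s$n_down))
stopifnot(s$n_up + s$n_down == s$n_responsive)
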