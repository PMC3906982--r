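#!/usr/bin/env Rscript
# Stage 8: one-shot end-to-end run through run_pipeline() on the same seed,
# writing all tables plus the self-validated summary report.  Confirms the
# orchestrated run agrees with stages 1-7.

suppressPackageStartupMessages(library(tfdirect))

report <- run_pipeline(default_config(), seed = 1, outdir = "results/pipeline")
val <- validate_report(report)

cat("pipeline report written to results/pipeline/report.json\n")
cat(sprintf("  identities validated: %s\n", val$pass))
cat(sprintf("  responsive %d (%d up / %d down); bound %d; targets %d (%.1f%%)\n",
            report$targets$n_responsive, report$targets$n_up,
            report$targets$n_down, report$targets$n_bound,
            report$targets$n_targets,
            report$targets$pct_targets_of_responsive))
cat(sprintf("  replicate R = %.3f; motif fold = %.2f; top set: %s\n",
            report$replicate_r, report$motif$fold,
            report$ora_top$set_name))
stopifnot(val$pass)
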