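# The ground-truthed generators: determinism, planted structure, and
# compatibility with the package's own readers.

small_cfg <- function(...) {
  synthetic_config(
    genome = list(n_chroms = 2L, chrom_len = 200000L, genes_per_chrom = 6L),
    ...
  )
}

test_that("generators are fully deterministic under a fixed seed", {
  d1 <- simulate_dataset(small_cfg(), seed = 11)
  d2 <- simulate_dataset(small_cfg(), seed = 11)
  expect_identical(as.character(d1$genome), as.character(d2$genome))
  expect_identical(d1$models, d2$models)
  expect_identical(d1$peaks_rep1, d2$peaks_rep1)
  expect_identical(d1$tags_rep2, d2$tags_rep2)
  expect_identical(d1$expression$values, d2$expression$values)
  expect_identical(d1$truth, d2$truth)
  d3 <- simulate_dataset(small_cfg(), seed = 12)
  expect_false(identical(d1$peaks_rep1, d3$peaks_rep1))
})

test_that("degenerate and infeasible genome configs are handled", {
  g0 <- synthetic_config(genome = list(genes_per_chrom = 0L))$genome
  gm <- generate_genome(g0, seed = 3)
  expect_equal(nrow(gm$models), 0)
  expect_equal(length(gm$genome), g0$n_chroms)
  bad <- synthetic_config(genome = list(chrom_len = 30000L))$genome
  expect_error(generate_genome(bad, seed = 1), "infeasible packing")
  bad2 <- synthetic_config(genome = list(gap_min = 6000L, gap_max = 8000L))$genome
  expect_error(generate_genome(bad2, seed = 1), "12 kb")
})

test_that("rho = 1 with zero jitter yields identical replicates", {
  cfg <- small_cfg(chip = list(rho = 1, summit_jitter_sd = 0,
                               n_noise_peaks = 0L))
  ds <- simulate_dataset(cfg, seed = 5)
  expect_identical(ds$tags_rep1, ds$tags_rep2)
  d1 <- window_tag_density(ds$tags_rep1, ds$chrom_sizes)
  d2 <- window_tag_density(ds$tags_rep2, ds$chrom_sizes)
  expect_equal(replicate_correlation(d1, d2)$r, 1.0)
  expect_equal(ds$peaks_rep1$summit, ds$peaks_rep2$summit)
})

test_that("rho outside [0,1] is rejected", {
  gm <- generate_genome(small_cfg()$genome, seed = 1)
  expect_error(generate_chip(gm, synthetic_config(chip = list(rho = 1.2))$chip),
               "rho")
})

test_that("motif planting at probability 1 puts a consensus under every summit", {
  cfg <- small_cfg(chip = list(motif_prob = 1.0))
  ds <- simulate_dataset(cfg, seed = 9)
  chrom_seq <- as.character(ds$genome)
  sites <- ds$truth$true_sites
  expect_true(all(sites$motif_planted))
  for (j in seq_len(nrow(sites))) {
    lo <- max(sites$summit[j] - 100, 0)
    hi <- min(sites$summit[j] + 100, nchar(chrom_seq[[sites$chrom[j]]]))
    window <- substr(chrom_seq[[sites$chrom[j]]], lo + 1, hi)
    hits <- oracle_scan(setNames(list(window), "w"), "WTTTAT")
    expect_gt(nrow(hits), 0)
  }
})

test_that("noiseless expression reproduces planted folds exactly", {
  cfg <- small_cfg(expression = list(noise_cv = 0))
  ds <- simulate_dataset(cfg, seed = 21)
  de <- call_responsive(ds$expression)
  truth <- ds$truth$responsive_genes
  for (k in seq_len(nrow(truth))) {
    expect_equal(de$fold_change[de$gene_id == truth$gene_id[k]],
                 truth$fold_change[k])
  }
  flat <- setdiff(de$gene_id, truth$gene_id)
  expect_true(all(de$fold_change[de$gene_id %in% flat] == 1))
  # degenerate ANOVA rule: planted genes p = 0, flat genes p = 1
  expect_true(all(de$p_value[de$gene_id %in% truth$gene_id] == 0))
  expect_true(all(de$p_value[de$gene_id %in% flat] == 1))
})

test_that("negative noise CV is rejected", {
  gm <- generate_genome(small_cfg()$genome, seed = 2)
  expect_error(
    generate_expression(gm$models,
                        config = synthetic_config(
                          expression = list(noise_cv = -0.1))$expression),
    "noise_cv")
})

test_that("planted responder fraction matches its rate within a binomial band", {
  n_bound_total <- 0; n_resp_bound <- 0
  for (s in 1:10) {
    ds <- simulate_dataset(small_cfg(), seed = 100 + s)
    bound <- ds$truth$bound_genes
    n_bound_total <- n_bound_total + length(bound)
    n_resp_bound <- n_resp_bound +
      length(intersect(bound, ds$truth$responsive_genes$gene_id))
  }
  rate <- synthetic_config()$expression$frac_bound_responsive
  phat <- n_resp_bound / n_bound_total
  band <- 1.96 * sqrt(rate * (1 - rate) / n_bound_total)
  expect_lt(abs(phat - rate), band + 1e-12)
})

test_that("generated files parse through the readers without errors", {
  outdir <- withr::local_tempdir()
  ds <- simulate_dataset(small_cfg(), seed = 31, outdir = outdir)
  m <- read_gene_models(file.path(outdir, "genes.bed12"), "bed12")
  expect_equal(m$start, ds$models$start)
  p1 <- read_peaks(file.path(outdir, "peaks_rep1.bed"))
  expect_equal(p1$summit, ds$peaks_rep1$summit)
  expect_equal(round(p1$fdr, 6), round(ds$peaks_rep1$fdr, 6))
  genome <- read_fasta(file.path(outdir, "genome.fa"))
  expect_identical(as.character(genome), as.character(ds$genome))
  cond <- utils::read.table(file.path(outdir, "conditions.tsv"),
                            header = TRUE, sep = "\t")
  et <- read_expression(file.path(outdir, "expression.tsv"),
                        setNames(cond$condition, cond$sample))
  expect_equal(dim(et$values), dim(ds$expression$values))
  sets <- read_gmt(file.path(outdir, "gene_sets.gmt"))
  expect_true("planted_process" %in% names(sets$sets))
  tags <- read_tags(file.path(outdir, "tags_rep1.bed"))
  expect_equal(nrow(tags), nrow(ds$tags_rep1))
})
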