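# Readers, writers and the invariants of the in-memory genomic model.

test_that("BED12 gene models parse with exons, CDS and strand-aware TSS", {
  f <- withr::local_tempfile()
  writeLines(c(
    "chr1\t100\t1000\tgeneA\t0\t+\t200\t900\t0\t2\t100,100\t0,800",
    "chr1\t100\t1000\tgeneB\t0\t-\t200\t900\t0\t1\t900\t0"
  ), f)
  m <- read_gene_models(f, "bed12")
  expect_equal(nrow(m), 2)
  expect_equal(m$exon_starts[[1]], c(100L, 900L))
  expect_equal(m$exon_ends[[1]], c(200L, 1000L))
  expect_equal(gene_tss(m), c(100L, 999L))
})

test_that("malformed and invariant-violating gene records are rejected", {
  f <- withr::local_tempfile()
  # block extends past chromEnd (second block reaches 1100 > 1000)
  writeLines("chr1\t100\t1000\tgeneA\t0\t+\t200\t900\t0\t2\t100,200\t0,800", f)
  expect_error(read_gene_models(f, "bed12"), "exon outside gene bounds")
  writeLines("chr1\t100\t1000\tgeneA\t0\t+", f)
  expect_error(read_gene_models(f, "bed12"), "line 1")
  writeLines("chr1\t100\t1000\tgeneA\t0\t+\t950\t900\t0\t1\t900\t0", f)
  expect_error(read_gene_models(f, "bed12"), "CDS")
})

test_that("refFlat records map to the same model as equivalent BED12", {
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeLines("chr2\t500\t2000\tgeneC\t0\t-\t600\t1800\t0\t2\t300,500\t0,1000", f1)
  writeLines("geneC\tnm1\tchr2\t-\t500\t2000\t600\t1800\t2\t500,1500\t800,2000", f2)
  m1 <- read_gene_models(f1, "bed12")
  m2 <- read_gene_models(f2, "refflat")
  expect_equal(m1[c("gene_id", "chrom", "start", "end", "strand")],
               m2[c("gene_id", "chrom", "start", "end", "strand")])
  expect_equal(m1$exon_starts[[1]], m2$exon_starts[[1]])
  expect_equal(m1$exon_ends[[1]], m2$exon_ends[[1]])
})

test_that("peaks parse with summit defaulting and FDR filtering", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t500\t700\tp1\t50",
               "chr1\t800\t900\tp2\t30\t20\t0.002",
               "chr1\t950\t990\tp3\t20\t10\t0.009",
               "chr2\t10\t200\tp4\t10\t100\t0.02"), f)
  p <- read_peaks(f)
  expect_equal(p$summit, c(600L, 820L, 960L, 110L))
  # of the fdr-bearing peaks (0.002, 0.009, 0.02), two survive the 1% cut;
  # p1 carries no fdr field and is kept unconditionally
  expect_equal(read_peaks(f, fdr_max = 0.01)$name, c("p1", "p2", "p3"))
  expect_equal(sum(!is.na(read_peaks(f, fdr_max = 0.01)$fdr)), 2)
})

test_that("invalid peak records are rejected with their line number", {
  f <- withr::local_tempfile()
  writeLines("chr1\t700\t500\tp2\t50", f)
  expect_error(read_peaks(f), "line 1.*invalid interval")
  writeLines(c("chr1\t1\t2\tok\t1", "chr1\t10\t90\tbad\t1\t5\t1.7"), f)
  expect_error(read_peaks(f), "line 2.*fdr")
})

test_that("peak tables round-trip through write_peaks bit-exactly", {
  set.seed(42)
  start <- sort(sample(0:10000, 30))
  p <- make_peaks_df("chr1", start, start + sample(50:500, 30, replace = TRUE),
                     summit = start + 10L,
                     fdr = round(runif(30), 4), tags = sample(0:99, 30))
  f <- withr::local_tempfile()
  write_peaks(p, f)
  expect_equal(read_peaks(f), p)
})

test_that("expression tables validate conditions and replicate counts", {
  f <- withr::local_tempfile()
  vals <- matrix(1:24, 4, 6,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  utils::write.table(data.frame(gene_id = rownames(vals), vals),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  cmap <- setNames(rep(c("a", "b"), each = 3), paste0("s", 1:6))
  et <- read_expression(f, cmap)
  expect_s3_class(et, "expression_table")
  expect_equal(dim(et$values), c(4, 6))
  expect_error(read_expression(f, cmap[-1]), "missing from condition map")
  # one sample per condition: ANOVA impossible
  cmap2 <- setNames(c("a", rep("b", 5)), paste0("s", 1:6))
  expect_error(read_expression(f, cmap2), "at least 2 replicate")
  # duplicated gene row
  writeLines(c("gene_id\ts1\ts2\ts3\ts4", "g1\t1\t2\t3\t4", "g1\t5\t6\t7\t8"), f)
  expect_error(read_expression(f, setNames(rep(c("a", "b"), each = 2),
                                           paste0("s", 1:4))),
               "duplicated gene id")
})

test_that("FASTA round-trips with uppercase normalization", {
  f <- withr::local_tempfile()
  write_fasta(c(one = "acgtACGT", two = "TTTTAAAA"), f)
  seqs <- read_fasta(f)
  expect_equal(as.character(seqs), c(one = "ACGTACGT", two = "TTTTAAAA"))
  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(c(">a", "ACXT"), f)
  expect_error(read_fasta(f))
})

test_that("GMT collections round-trip and enforce universe subsetting", {
  coll <- gene_set_collection(
    list(s1 = c("a", "b", "c"), s2 = c("c", "d"), s3 = "zzz"),
    universe = c("a", "b", "c", "d", "e"))
  expect_named(coll$sets, c("s1", "s2"))  # s3 empty after intersection
  f <- withr::local_tempfile()
  write_gmt(coll, f)
  back <- read_gmt(f, universe = coll$universe)
  expect_equal(back$sets, coll$sets)
})

test_that("random valid BED12 round-trips and satisfies model invariants", {
  set.seed(7)
  for (rep in 1:20) {
    m <- random_models(6, 50000)
    expect_silent(validate_gene_models(m))
    f <- withr::local_tempfile()
    write_gene_models(m, f)
    m2 <- read_gene_models(f, "bed12")
    expect_equal(m2$start, m$start)
    expect_equal(m2$end, m$end)
    expect_equal(m2$exon_starts, m$exon_starts, ignore_attr = TRUE)
    expect_equal(m2$exon_ends, m$exon_ends, ignore_attr = TRUE)
    # strand flip moves the TSS from start to end - 1
    flipped <- m
    flipped$strand <- ifelse(m$strand == "+", "-", "+")
    expect_equal(gene_tss(flipped),
                 ifelse(m$strand == "+", m$end - 1L, m$start))
  }
})
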