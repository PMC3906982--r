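# Feature classification, size-normalized distributions, nearest-TSS
# histogram, and the per-bp brute-force equivalences.

test_that("a single plus-strand gene produces the expected feature layout", {
  m <- make_models(gene_row("g1", "chr1", 10000, 20000, "+",
                            cds_start = 12000, cds_end = 18000))
  sizes <- c(chr1 = 50000L)
  idx <- build_feature_index(m, sizes)
  expect_equal(unname(idx$sizes[c("promoter", "utr5", "utr3", "exon",
                                  "intron", "downstream", "intergenic")]),
               c(5000, 2000, 2000, 6000, 0, 5000, 30000))
  expect_equal(sum(idx$sizes), sum(sizes))
  # classification at hand-picked summits
  p <- make_peaks_df("chr1", c(6999, 10500, 19000, 13000, 21000, 40000),
                     c(7001, 10502, 19002, 13002, 21002, 40002),
                     summit = c(7000, 10501, 19001, 13001, 21001, 40001))
  expect_equal(classify_peaks(p, idx),
               c("promoter", "utr5", "utr3", "exon", "downstream", "intergenic"))
})

test_that("strand mirroring swaps promoter and downstream", {
  m <- make_models(gene_row("g1", "chr1", 10000, 20000, "-",
                            cds_start = 12000, cds_end = 18000))
  idx <- build_feature_index(m, c(chr1 = 50000L))
  expect_equal(unname(idx$sizes[c("promoter", "downstream")]), c(5000, 5000))
  p <- make_peaks_df("chr1", c(21000, 6000), c(21002, 6002),
                     summit = c(21001, 6001))
  expect_equal(classify_peaks(p, idx), c("promoter", "downstream"))
})

test_that("summit precedence resolves overlapping categories", {
  # summit inside gene A's intron and within 5 kb upstream of gene B's TSS
  m <- make_models(
    gene_row("gA", "chr1", 1000, 20000, "+", cds_start = 1000, cds_end = 20000,
             exon_starts = c(1000, 15000), exon_ends = c(2000, 20000)),
    gene_row("gB", "chr1", 12000, 30000, "+", cds_start = 13000,
             cds_end = 29000)
  )
  idx <- build_feature_index(m, c(chr1 = 60000L))
  summit <- 9000L  # intron of gA, 3 kb upstream of gB's TSS
  expect_equal(oracle_category_at(summit, "chr1", m), "promoter")
  p <- make_peaks_df("chr1", summit - 1L, summit + 1L, summit = summit)
  expect_equal(classify_peaks(p, idx), "promoter")
})

test_that("summary has the documented densities and partition identities", {
  m <- make_models(gene_row("g1", "chr1", 50000, 140000, "+"))
  idx <- build_feature_index(m, c(chr1 = 1000000L))
  expect_equal(unname(idx$sizes[["intergenic"]]), 900000)
  start <- seq(500000, 950000, by = 50000)
  p <- make_peaks_df("chr1", start, start + 200L)
  s <- annotation_summary(p, idx)
  expect_equal(s$count[s$category == "intergenic"], 10L)
  expect_equal(s$density_per_100kb[s$category == "intergenic"], 10 / 9,
               tolerance = 1e-12)
  expect_equal(sum(s$count), nrow(p))
  expect_equal(sum(s$fraction), 1)
  # permuting peak order leaves the summary bit-identical
  expect_identical(annotation_summary(p[sample(nrow(p)), ], idx), s)
})

test_that("empty peak sets yield a zero summary with a flag", {
  m <- make_models(gene_row("g1", "chr1", 10000, 20000, "+"))
  idx <- build_feature_index(m, c(chr1 = 50000L))
  s <- annotation_summary(make_peaks_df("chr1", integer(0), integer(0)), idx)
  expect_true(attr(s, "empty"))
  expect_equal(sum(s$count), 0L)
  expect_equal(sum(s$fraction), 0)
})

test_that("peaks on unknown chromosomes are intergenic with a warning", {
  m <- make_models(gene_row("g1", "chr1", 10000, 20000, "+"))
  idx <- build_feature_index(m, c(chr1 = 50000L))
  p <- make_peaks_df("chrUn", 100, 300)
  expect_warning(cls <- classify_peaks(p, idx), "absent")
  expect_equal(cls, "intergenic")
})

test_that("category sizes always partition the genome exactly", {
  set.seed(31)
  for (rep in 1:10) {
    m <- random_models(sample(2:8, 1), 80000)
    sizes <- c(chrA = 80000L, chrB = 10000L)
    idx <- build_feature_index(m, sizes)
    expect_identical(sum(idx$sizes), as.numeric(sum(sizes)))
  }
})

test_that("TSS distances bin correctly at the boundaries", {
  m <- make_models(gene_row("g1", "chr1", 10000, 20000, "+"))
  p <- make_peaks_df("chr1", c(9990, 9740), c(10010, 9760),
                     summit = c(10000, 9750))
  d <- nearest_tss_distance(p, m)
  expect_equal(d, c(0, -250))
  h <- tss_distance_histogram(p, m)
  expect_equal(h$bin_start, c(-300, 0))
  expect_equal(h$count, c(1L, 1L))
  expect_error(tss_distance_histogram(p, m[0, ]), "no gene models")
})

test_that("nearest-TSS histogram matches the exhaustive scan", {
  set.seed(77)
  for (rep in 1:5) {
    m <- random_models(6, 60000)
    start <- sample(0:59000, 40)
    p <- make_peaks_df("chrA", start, start + 400L)
    d <- nearest_tss_distance(p, m)
    # O(peaks x genes) oracle with the same deterministic tie-break
    tss <- gene_tss(m)
    ord <- order(tss, match(m$strand, c("+", "-")))
    tss_o <- tss[ord]; strand_o <- m$strand[ord]
    d_oracle <- vapply(p$summit, function(s) {
      best <- which.min(abs(s - tss_o))
      if (strand_o[best] == "+") s - tss_o[best] else tss_o[best] - s
    }, 0)
    expect_equal(d, d_oracle)
    h <- tss_distance_histogram(p, m)
    expect_equal(sum(h$count), nrow(p))
  }
})

test_that("non-coding genes contribute no UTR intervals", {
  m <- make_models(gene_row("g1", "chr1", 10000, 20000, "+",
                            cds_start = 10000, cds_end = 10000))
  idx <- build_feature_index(m, c(chr1 = 50000L))
  expect_equal(unname(idx$sizes[c("utr5", "utr3")]), c(0, 0))
  expect_equal(unname(idx$sizes[["exon"]]), 10000)
})
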