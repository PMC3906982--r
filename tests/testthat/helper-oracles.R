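# Fixture builders and independent brute-force oracles used across the
# suite.  The oracles deliberately avoid the package's interval machinery:
# they enumerate base pairs, gene pairs or string offsets directly.

make_models <- function(...) {
  rows <- list(...)
  df <- data.frame(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, function(r) as.integer(r$start), 0L),
    end = vapply(rows, function(r) as.integer(r$end), 0L),
    strand = vapply(rows, `[[`, "", "strand"),
    cds_start = vapply(rows, function(r) as.integer(r$cds_start), 0L),
    cds_end = vapply(rows, function(r) as.integer(r$cds_end), 0L),
    stringsAsFactors = FALSE
  )
  df$exon_starts <- I(lapply(rows, function(r) as.integer(r$exon_starts)))
  df$exon_ends <- I(lapply(rows, function(r) as.integer(r$exon_ends)))
  df
}

# a simple gene: optionally coding, single exon spanning the locus
gene_row <- function(gene_id, chrom, start, end, strand = "+",
                     cds_start = start, cds_end = end,
                     exon_starts = start, exon_ends = end) {
  list(gene_id = gene_id, chrom = chrom, start = start, end = end,
       strand = strand, cds_start = cds_start, cds_end = cds_end,
       exon_starts = exon_starts, exon_ends = exon_ends)
}

make_peaks_df <- function(chrom, start, end, summit = NULL,
                          name = NULL, score = 1, fdr = NA_real_,
                          tags = NA_integer_) {
  n <- length(start)
  if (is.null(summit)) summit <- start + (end - start) %/% 2L
  if (is.null(name)) name <- sprintf("p%d", seq_len(n))
  data.frame(name = name, chrom = rep_len(chrom, n),
             start = as.integer(start), end = as.integer(end),
             summit = as.integer(summit), score = rep_len(score, n),
             fdr = rep_len(fdr, n), tags = rep_len(tags, n),
             stringsAsFactors = FALSE)
}

# random gene models on one small chromosome; genes may overlap each other
random_models <- function(n_genes, chrom_len, chrom = "chrA") {
  rows <- lapply(seq_len(n_genes), function(i) {
    len <- sample(500:5000, 1)
    start <- sample(0:(chrom_len - len), 1)
    end <- start + len
    n_ex <- sample(1:3, 1)
    cuts <- sort(sample(seq(start + 50, end - 50, by = 25),
                        2 * n_ex - 2, replace = FALSE))
    bounds <- c(start, cuts, end)
    es <- bounds[seq(1, 2 * n_ex - 1, by = 2)]
    ee <- bounds[seq(2, 2 * n_ex, by = 2)]
    coding <- stats::runif(1) < 0.8 && len > 400
    if (coding) {
      cs <- start + sample.int(len %/% 3, 1)
      ce <- end - sample.int(len %/% 3, 1)
    } else {
      cs <- ce <- start
    }
    gene_row(sprintf("g%02d", i), chrom, start, end,
             strand = sample(c("+", "-"), 1),
             cds_start = cs, cds_end = ce,
             exon_starts = es, exon_ends = ee)
  })
  do.call(make_models, rows)
}

# -- per-bp brute-force genomic category oracle ------------------------------
# Enumerates, gene by gene, every category the base `pos` belongs to and
# applies the precedence list.
oracle_category_at <- function(pos, chrom, models, promoter_bp = 5000,
                               downstream_bp = 5000) {
  cats <- character(0)
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    if (g$chrom != chrom) next
    tss <- if (g$strand == "+") g$start else g$end - 1L
    prom <- if (g$strand == "+") {
      c(tss - promoter_bp, tss)
    } else {
      c(tss + 1L, tss + 1L + promoter_bp)
    }
    if (pos >= prom[1] && pos < prom[2]) cats <- c(cats, "promoter")
    down <- if (g$strand == "+") {
      c(g$end, g$end + downstream_bp)
    } else {
      c(g$start - downstream_bp, g$start)
    }
    if (pos >= down[1] && pos < down[2]) cats <- c(cats, "downstream")
    es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
    in_exon <- any(pos >= es & pos < ee)
    in_body <- pos >= g$start && pos < g$end
    coding <- g$cds_start < g$cds_end
    if (coding && in_exon) {
      u5 <- if (g$strand == "+") c(g$start, g$cds_start) else c(g$cds_end, g$end)
      u3 <- if (g$strand == "+") c(g$cds_end, g$end) else c(g$start, g$cds_start)
      if (pos >= u5[1] && pos < u5[2]) cats <- c(cats, "utr5")
      if (pos >= u3[1] && pos < u3[2]) cats <- c(cats, "utr3")
    }
    if (in_exon) cats <- c(cats, "exon")
    if (in_body && !in_exon) cats <- c(cats, "intron")
  }
  for (cat in c("promoter", "utr5", "utr3", "exon", "intron", "downstream")) {
    if (cat %in% cats) return(cat)
  }
  "intergenic"
}

# -- all-pairs binding oracle ------------------------------------------------
oracle_binding <- function(peaks, models, flank = 5000) {
  out <- list()
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    ws <- max(g$start - flank, 0); we <- g$end + flank
    for (j in seq_len(nrow(peaks))) {
      p <- peaks[j, ]
      if (p$chrom == g$chrom && p$start < we && p$end > ws) {
        out[[g$gene_id]] <- c(out[[g$gene_id]], p$name)
      }
    }
  }
  out
}

# -- character-by-character IUPAC consensus oracle ---------------------------
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = character(0)  # N in subject never matches
)

oracle_scan_one_strand <- function(seq_chars, pat_chars) {
  k <- length(pat_chars)
  L <- length(seq_chars)
  hits <- integer(0)
  if (L < k) return(hits)
  for (off in 0:(L - k)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!(seq_chars[off + j] %in% IUPAC_SETS[[pat_chars[j]]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

revcomp_chars <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[chars]))
}

oracle_scan <- function(seqs, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  k <- length(pat)
  res <- list()
  for (id in names(seqs)) {
    ch <- strsplit(seqs[[id]], "")[[1]]
    L <- length(ch)
    for (off in oracle_scan_one_strand(ch, pat)) {
      res[[length(res) + 1]] <- data.frame(seq_id = id, offset = off,
                                           strand = "+",
                                           stringsAsFactors = FALSE)
    }
    for (off in oracle_scan_one_strand(revcomp_chars(ch), pat)) {
      res[[length(res) + 1]] <- data.frame(seq_id = id, offset = L - off - k,
                                           strand = "-",
                                           stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0) {
    return(data.frame(seq_id = character(0), offset = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

hit_key <- function(df) {
  sort(paste(df$seq_id, df$offset, df$strand, sep = ":"))
}

# -- naive window counting oracle --------------------------------------------
oracle_window_counts <- function(pos, chrom_len, w) {
  n_win <- ceiling(chrom_len / w)
  counts <- integer(n_win)
  for (k in seq_len(n_win)) {
    lo <- (k - 1) * w; hi <- k * w
    for (p in pos) if (p >= lo && p < hi) counts[k] <- counts[k] + 1L
  }
  counts
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
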