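# Genomic-feature classification of peaks and nearest-TSS distance profiling.
#
# Every peak is assigned exactly one of seven categories by its SUMMIT
# position, with the precedence
#   promoter > utr5 > utr3 > exon > intron > downstream > intergenic,
# and category sizes are computed from a per-bp partition of the genome under
# the same precedence, so sizes always sum to the genome length.

ANNOTATION_CATEGORIES <- c("promoter", "utr5", "utr3", "exon", "intron",
                           "downstream", "intergenic")

#' UTR intervals of coding gene models
#'
#' The 5'/3' UTR of a gene is its exonic sequence between the transcript
#' bound and the CDS bound on the corresponding side, in gene orientation;
#' each gene's exons are clipped against its own CDS bounds.  Non-coding
#' genes (`cds_start == cds_end`) contribute no UTR intervals.
#'
#' @param models gene-model table
#' @return list with GRanges elements `utr5` and `utr3`
#' @keywords internal
utr_intervals <- function(models) {
  acc <- list(utr5 = list(chrom = character(), s = integer(), e = integer()),
              utr3 = list(chrom = character(), s = integer(), e = integer()))
  add <- function(acc, side, chrom, rs, re, es, ee) {
    s <- pmax(es, rs); e <- pmin(ee, re)
    keep <- s < e
    if (any(keep)) {
      acc[[side]]$chrom <- c(acc[[side]]$chrom, rep(chrom, sum(keep)))
      acc[[side]]$s <- c(acc[[side]]$s, s[keep])
      acc[[side]]$e <- c(acc[[side]]$e, e[keep])
    }
    acc
  }
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    if (g$cds_start >= g$cds_end) next
    es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
    if (g$strand == "+") {
      acc <- add(acc, "utr5", g$chrom, g$start, g$cds_start, es, ee)
      acc <- add(acc, "utr3", g$chrom, g$cds_end, g$end, es, ee)
    } else {
      acc <- add(acc, "utr5", g$chrom, g$cds_end, g$end, es, ee)
      acc <- add(acc, "utr3", g$chrom, g$start, g$cds_start, es, ee)
    }
  }
  mk <- function(a) {
    if (length(a$s) == 0) GenomicRanges::GRanges() else gr0(a$chrom, a$s, a$e)
  }
  list(utr5 = mk(acc$utr5), utr3 = mk(acc$utr3))
}

#' Build the genomic feature index for peak classification
#'
#' Constructs per-category interval sets from gene models, in gene
#' orientation:
#' * promoter: `[TSS - promoter_bp, TSS)` upstream of the TSS;
#' * utr5 / utr3: exonic sequence between transcript and CDS bounds (5' /
#'   3' side); non-coding genes (`cds_start == cds_end`) contribute none;
#' * exon: all exons (effectively CDS exons after UTR precedence);
#' * intron: gene body minus exons;
#' * downstream: `downstream_bp` past the gene end;
#' * intergenic: the rest of the genome, i.e. outside the +/- flank extended
#'   gene loci.
#'
#' Raw category unions may overlap across categories (and across genes); the
#' precedence above resolves overlaps both when classifying a summit and in
#' the per-bp size partition, whose sizes sum exactly to the genome length.
#'
#' @param models gene-model table
#' @param chrom_sizes named integer vector of chromosome lengths
#' @param promoter_bp promoter extent upstream of the TSS (default 5000)
#' @param downstream_bp downstream extent past the gene end (default 5000)
#' @return list of class `feature_index` with `categories` (named list of
#'   GRanges, raw unions), `sizes` (named numeric, per-bp partitioned
#'   category sizes in bp), `chrom_sizes`
#' @export
build_feature_index <- function(models, chrom_sizes, promoter_bp = 5000,
                                downstream_bp = 5000) {
  validate_gene_models(models)
  stopifnot(promoter_bp > 0, downstream_bp > 0)
  empty <- GenomicRanges::GRanges()
  cat_list <- stats::setNames(
    rep(list(empty), length(ANNOTATION_CATEGORIES)), ANNOTATION_CATEGORIES)
  if (nrow(models) > 0) {
    tss <- gene_tss(models)
    plus <- models$strand == "+"
    # promoter [TSS - P, TSS) in gene orientation
    prom_s <- ifelse(plus, tss - promoter_bp, tss + 1L)
    prom_e <- ifelse(plus, tss, tss + 1L + promoter_bp)
    # downstream: flank past the gene end in gene orientation
    down_s <- ifelse(plus, models$end, models$start - downstream_bp)
    down_e <- ifelse(plus, models$end + downstream_bp, models$start)
    clip <- function(s, e, chrom) {
      len <- chrom_sizes[chrom]
      s <- pmax(s, 0); e <- pmin(e, len)
      keep <- !is.na(len) & s < e
      gr0(chrom[keep], s[keep], e[keep])
    }
    cat_list$promoter <- clip(prom_s, prom_e, models$chrom)
    cat_list$downstream <- clip(down_s, down_e, models$chrom)

    ex_chrom <- rep(models$chrom, lengths(models$exon_starts))
    ex_s <- unlist(models$exon_starts); ex_e <- unlist(models$exon_ends)
    exons_gr <- gr0(ex_chrom, ex_s, ex_e)
    cat_list$exon <- exons_gr
    body_gr <- gr0(models$chrom, models$start, models$end)
    cat_list$intron <- GenomicRanges::setdiff(
      GenomicRanges::reduce(body_gr), GenomicRanges::reduce(exons_gr))

    utrs <- utr_intervals(models)
    cat_list$utr5 <- utrs$utr5
    cat_list$utr3 <- utrs$utr3
  }
  genome_gr <- gr0(names(chrom_sizes), rep(0L, length(chrom_sizes)),
                   unname(chrom_sizes))
  # per-bp partition under precedence: each category takes the genome bp not
  # already claimed by a higher-precedence category; intergenic is the rest.
  sizes <- stats::setNames(numeric(length(ANNOTATION_CATEGORIES)),
                           ANNOTATION_CATEGORIES)
  claimed <- GenomicRanges::GRanges()
  for (cat in setdiff(ANNOTATION_CATEGORIES, "intergenic")) {
    part <- GenomicRanges::setdiff(
      GenomicRanges::intersect(GenomicRanges::reduce(cat_list[[cat]]),
                               genome_gr),
      claimed)
    sizes[[cat]] <- sum(GenomicRanges::width(part))
    claimed <- GenomicRanges::reduce(GenomicRanges::union(claimed, part))
  }
  sizes[["intergenic"]] <-
    sum(GenomicRanges::width(GenomicRanges::setdiff(genome_gr, claimed)))
  structure(list(categories = cat_list, sizes = sizes,
                 chrom_sizes = chrom_sizes),
            class = "feature_index")
}

#' Classify peaks into genomic feature categories by summit position
#'
#' Each peak receives exactly one category: the highest-precedence category
#' whose interval set contains the summit base.  Peaks on chromosomes absent
#' from the index are classified intergenic with a warning.
#'
#' @param peaks peak table
#' @param index a `feature_index`
#' @return character vector of categories, one per peak
#' @export
classify_peaks <- function(peaks, index) {
  stopifnot(inherits(index, "feature_index"))
  n <- nrow(peaks)
  out <- rep("intergenic", n)
  known <- peaks$chrom %in% names(index$chrom_sizes)
  if (any(!known)) {
    warning(sum(!known), " peak(s) on chromosomes absent from the index; ",
            "classified intergenic")
  }
  if (!any(known)) return(out)
  summit_gr <- gr0(peaks$chrom[known], peaks$summit[known],
                   peaks$summit[known] + 1L)
  assigned <- rep(FALSE, length(summit_gr))
  res <- rep("intergenic", length(summit_gr))
  for (cat in setdiff(ANNOTATION_CATEGORIES, "intergenic")) {
    hit <- IRanges::overlapsAny(summit_gr, index$categories[[cat]])
    take <- hit & !assigned
    res[take] <- cat
    assigned <- assigned | hit
  }
  out[known] <- res
  out
}

#' Summarize the genomic distribution of peaks
#'
#' Per-category peak counts, fractions of all peaks, partitioned category
#' sizes in bp, and size-normalized densities (peaks per 100 kb of
#' category).
#'
#' @param peaks peak table
#' @param index a `feature_index`
#' @return `data.frame` with columns `category`, `count`, `fraction`,
#'   `size_bp`, `density_per_100kb`.  With zero peaks all fractions are
#'   reported as 0 and the attribute `empty` is set to `TRUE`.
#' @export
annotation_summary <- function(peaks, index) {
  cats <- classify_peaks(peaks, index)
  counts <- vapply(ANNOTATION_CATEGORIES, function(cat) sum(cats == cat), 0L)
  total <- sum(counts)
  fraction <- if (total > 0) counts / total else rep(0, length(counts))
  sizes <- index$sizes[ANNOTATION_CATEGORIES]
  density <- ifelse(sizes > 0, counts / (sizes / 1e5), 0)
  out <- data.frame(
    category = ANNOTATION_CATEGORIES, count = unname(counts),
    fraction = unname(fraction), size_bp = unname(sizes),
    density_per_100kb = unname(density),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "empty") <- total == 0
  out
}

#' Nearest-TSS signed distances for peak summits
#'
#' For each peak, the signed distance from its summit to the nearest TSS by
#' absolute distance (same chromosome only).  The sign follows the
#' orientation of the nearest TSS's gene: negative means the summit lies
#' upstream of that TSS.  Equidistant TSSs are broken toward the TSS with the
#' smaller coordinate, then toward the `+` strand.
#'
#' @param peaks peak table
#' @param models gene-model table (>= 1 gene)
#' @return numeric vector of signed distances, `NA` for peaks on
#'   chromosomes with no TSS
#' @export
nearest_tss_distance <- function(peaks, models) {
  if (nrow(models) == 0) stop("no gene models supplied", call. = FALSE)
  tss_tab <- data.frame(chrom = models$chrom, tss = gene_tss(models),
                        strand = models$strand, stringsAsFactors = FALSE)
  # deterministic tie-break: smaller coordinate first, then + strand
  tss_tab <- tss_tab[order(tss_tab$chrom, tss_tab$tss,
                           match(tss_tab$strand, c("+", "-"))), ]
  out <- rep(NA_real_, nrow(peaks))
  for (chr in unique(peaks$chrom)) {
    tt <- tss_tab[tss_tab$chrom == chr, , drop = FALSE]
    idx <- which(peaks$chrom == chr)
    if (nrow(tt) == 0) next
    pos <- peaks$summit[idx]
    # sorted-TSS nearest search: candidate neighbours around the insertion
    # point, ties resolved by the table's deterministic ordering
    iv <- findInterval(pos, tt$tss)
    for (j in seq_along(idx)) {
      cand <- unique(pmin(pmax(c(iv[j], iv[j] + 1L), 1L), nrow(tt)))
      d <- abs(pos[j] - tt$tss[cand])
      best <- cand[which.min(d)]
      out[idx[j]] <- if (tt$strand[best] == "+") {
        pos[j] - tt$tss[best]
      } else {
        tt$tss[best] - pos[j]
      }
    }
  }
  out
}

#' Histogram of summit-to-nearest-TSS distances
#'
#' Signed distances from [nearest_tss_distance()] binned at `bin_width`
#' (default 100 bp); bin `[k*w, (k+1)*w)` by floor division.  Peaks with no
#' defined nearest TSS are excluded, so the histogram mass equals the number
#' of peaks with one.
#'
#' @param peaks peak table
#' @param models gene-model table
#' @param bin_width bin width in bp
#' @return `data.frame` with `bin_start`, `bin_end`, `count`
#' @export
tss_distance_histogram <- function(peaks, models, bin_width = 100) {
  d <- nearest_tss_distance(peaks, models)
  d <- d[!is.na(d)]
  if (length(d) == 0) {
    return(data.frame(bin_start = numeric(0), bin_end = numeric(0),
                      count = integer(0)))
  }
  bin <- floor(d / bin_width) * bin_width
  tab <- table(bin)
  starts <- as.numeric(names(tab))
  data.frame(bin_start = starts, bin_end = starts + bin_width,
             count = as.integer(tab), row.names = NULL)
}
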