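# Readers/writers for the standard formats the pipeline touches, and the
# canonical in-memory genomic data model.
#
# Coordinate convention: all coordinates are 0-based half-open (BED native),
# both on disk and in memory.  Conversion to the 1-based closed convention of
# IRanges/GenomicRanges happens only inside helper functions, never at module
# boundaries.

VALID_STRANDS <- c("+", "-")

#' Convert 0-based half-open coordinates to a GRanges
#'
#' Internal bridge between the package's BED-native coordinates and the
#' 1-based closed convention used by GenomicRanges.
#'
#' @param chrom character vector of chromosome names
#' @param start,end 0-based half-open bounds (`start < end`)
#' @param strand strand vector (`+`, `-` or `*`)
#' @keywords internal
gr0 <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end), strand = strand)
}

stop_parse <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

split_fields <- function(line) strsplit(trimws(line), "[ \t]+")[[1]]

#' Read gene models from BED12 or refFlat-like files
#'
#' Parses pre-collapsed gene loci (one record per gene) into the package's
#' gene-model table.  BED12 blocks become exons; refFlat-like input is the
#' UCSC tab-separated layout (geneName, name, chrom, strand, txStart, txEnd,
#' cdsStart, cdsEnd, exonCount, exonStarts, exonEnds).  Both dialects are
#' 0-based half-open.
#'
#' The transcription start site (TSS) of a gene is `start` on the `+` strand
#' and `end - 1` on the `-` strand; see [gene_tss()].
#'
#' @param path file path
#' @param format `"bed12"` or `"refflat"`
#' @return a `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `cds_start`, `cds_end` and list columns `exon_starts`,
#'   `exon_ends` (0-based half-open exon bounds, sorted, non-overlapping).
#'   Non-coding genes have `cds_start == cds_end`.
#' @export
read_gene_models <- function(path, format = c("bed12", "refflat")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- split_fields(lines[i])
    if (format == "bed12") {
      if (length(f) < 12) stop_parse(path, i, "expected 12 BED12 fields")
      n_blocks <- as.integer(f[10])
      sizes <- as.integer(strsplit(f[11], ",")[[1]])
      offs <- as.integer(strsplit(f[12], ",")[[1]])
      if (any(is.na(sizes)) || any(is.na(offs)) ||
          length(sizes) != n_blocks || length(offs) != n_blocks) {
        stop_parse(path, i, "malformed block fields")
      }
      start <- as.integer(f[2])
      recs[[i]] <- list(
        gene_id = f[4], chrom = f[1], start = start, end = as.integer(f[3]),
        strand = f[6], cds_start = as.integer(f[7]), cds_end = as.integer(f[8]),
        exon_starts = start + offs, exon_ends = start + offs + sizes
      )
    } else {
      if (length(f) < 11) stop_parse(path, i, "expected 11 refFlat fields")
      ex_s <- as.integer(strsplit(f[10], ",")[[1]])
      ex_e <- as.integer(strsplit(f[11], ",")[[1]])
      recs[[i]] <- list(
        gene_id = f[1], chrom = f[3], start = as.integer(f[5]),
        end = as.integer(f[6]), strand = f[4],
        cds_start = as.integer(f[7]), cds_end = as.integer(f[8]),
        exon_starts = ex_s, exon_ends = ex_e
      )
    }
    if (anyNA(unlist(recs[[i]][c("start", "end", "cds_start", "cds_end")]))) {
      stop_parse(path, i, "non-numeric coordinate")
    }
  }
  models <- data.frame(
    gene_id = vapply(recs, `[[`, "", "gene_id"),
    chrom = vapply(recs, `[[`, "", "chrom"),
    start = vapply(recs, `[[`, 0L, "start"),
    end = vapply(recs, `[[`, 0L, "end"),
    strand = vapply(recs, `[[`, "", "strand"),
    cds_start = vapply(recs, `[[`, 0L, "cds_start"),
    cds_end = vapply(recs, `[[`, 0L, "cds_end"),
    stringsAsFactors = FALSE
  )
  models$exon_starts <- I(lapply(recs, `[[`, "exon_starts"))
  models$exon_ends <- I(lapply(recs, `[[`, "exon_ends"))
  validate_gene_models(models)
  models
}

#' Validate a gene-model table
#'
#' Checks the structural invariants every gene model must satisfy:
#' `0 <= start < end`, a declared strand, CDS bounds inside the transcript,
#' and exons sorted, non-overlapping and inside the transcript.
#'
#' @param models gene-model `data.frame` as returned by [read_gene_models()]
#' @return the input, invisibly, if valid; otherwise an error
#' @export
validate_gene_models <- function(models) {
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    id <- g$gene_id
    if (is.na(g$start) || g$start < 0 || g$start >= g$end) {
      stop(sprintf("gene '%s': invalid interval [%s, %s)", id, g$start, g$end),
           call. = FALSE)
    }
    if (!g$strand %in% VALID_STRANDS) {
      stop(sprintf("gene '%s': strand must be '+' or '-'", id), call. = FALSE)
    }
    if (g$cds_start > g$cds_end || g$cds_start < g$start || g$cds_end > g$end) {
      stop(sprintf("gene '%s': CDS bounds outside transcript", id), call. = FALSE)
    }
    es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
    if (length(es) == 0) stop(sprintf("gene '%s': no exons", id), call. = FALSE)
    if (any(es >= ee)) stop(sprintf("gene '%s': empty exon", id), call. = FALSE)
    if (es[1] < g$start || ee[length(ee)] > g$end) {
      stop(sprintf("gene '%s': exon outside gene bounds", id), call. = FALSE)
    }
    if (length(es) > 1 && any(es[-1] < ee[-length(ee)])) {
      stop(sprintf("gene '%s': exons unsorted or overlapping", id), call. = FALSE)
    }
  }
  if (anyDuplicated(models$gene_id)) {
    stop("duplicated gene_id in gene models", call. = FALSE)
  }
  invisible(models)
}

#' Transcription start sites of gene models
#'
#' @param models gene-model table
#' @return integer vector of 0-based TSS positions, one per gene:
#'   `start` for `+` strand genes, `end - 1` for `-` strand genes.
#' @export
gene_tss <- function(models) {
  ifelse(models$strand == "+", models$start, models$end - 1L)
}

#' Write gene models as BED12
#'
#' @param models gene-model table
#' @param path output file
#' @export
write_gene_models <- function(models, path) {
  lines <- vapply(seq_len(nrow(models)), function(i) {
    g <- models[i, ]
    es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
    paste(g$chrom, g$start, g$end, g$gene_id, 0L, g$strand,
          g$cds_start, g$cds_end, 0L, length(es),
          paste0(paste(ee - es, collapse = ","), ","),
          paste0(paste(es - g$start, collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read ChIP-seq peaks from a BED-like file
#'
#' Columns: chrom, start, end, name, score, and optionally summit offset
#' (relative to `start`, MACS style), FDR (fraction in \[0,1\]) and tag count.
#' When the summit column is absent the summit defaults to the floor of the
#' interval midpoint.  Peaks are strandless.
#'
#' @param path file path
#' @param fdr_max optional FDR threshold; peaks with `fdr < fdr_max` are kept
#'   (peaks lacking an FDR field are kept unconditionally)
#' @return `data.frame` with columns `name`, `chrom`, `start`, `end`,
#'   `summit` (absolute 0-based position), `score`, `fdr` (NA when absent),
#'   `tags` (NA when absent)
#' @export
read_peaks <- function(path, fdr_max = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  out <- data.frame(
    name = character(n), chrom = character(n), start = integer(n),
    end = integer(n), summit = integer(n), score = numeric(n),
    fdr = rep(NA_real_, n), tags = rep(NA_integer_, n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    f <- split_fields(lines[i])
    if (length(f) < 5) stop_parse(path, i, "expected at least 5 peak fields")
    start <- as.integer(f[2]); end <- as.integer(f[3])
    if (is.na(start) || is.na(end)) stop_parse(path, i, "non-numeric coordinate")
    if (start < 0 || start >= end) {
      stop_parse(path, i, sprintf("invalid interval [%d, %d)", start, end))
    }
    summit <- if (length(f) >= 6 && nzchar(f[6]) && f[6] != ".") {
      start + as.integer(f[6])
    } else {
      start + (end - start) %/% 2L
    }
    if (summit < start || summit >= end) {
      stop_parse(path, i, "summit outside peak interval")
    }
    fdr <- if (length(f) >= 7) as.numeric(f[7]) else NA_real_
    if (!is.na(fdr) && (fdr < 0 || fdr > 1)) {
      stop_parse(path, i, "fdr outside [0, 1]")
    }
    tags <- if (length(f) >= 8) as.integer(f[8]) else NA_integer_
    if (!is.na(tags) && tags < 0) stop_parse(path, i, "negative tag count")
    out$name[i] <- f[4]; out$chrom[i] <- f[1]
    out$start[i] <- start; out$end[i] <- end; out$summit[i] <- summit
    out$score[i] <- as.numeric(f[5]); out$fdr[i] <- fdr; out$tags[i] <- tags
  }
  if (!is.null(fdr_max)) out <- filter_peaks_fdr(out, fdr_max)
  out
}

#' Filter peaks at an FDR threshold
#'
#' Keeps peaks whose `fdr` is strictly below `fdr_max`; peaks with no FDR
#' field (NA) are kept.
#'
#' @param peaks peak table
#' @param fdr_max threshold fraction in \[0,1\]
#' @export
filter_peaks_fdr <- function(peaks, fdr_max) {
  keep <- is.na(peaks$fdr) | peaks$fdr < fdr_max
  peaks[keep, , drop = FALSE]
}

#' Write peaks in the BED-like layout read_peaks() consumes
#'
#' Round-trips coordinates bit-exactly (summit is written as an offset from
#' `start`).
#'
#' @param peaks peak table
#' @param path output file
#' @export
write_peaks <- function(peaks, path) {
  fmt_na <- function(x) ifelse(is.na(x), ".", as.character(x))
  lines <- paste(peaks$chrom, peaks$start, peaks$end, peaks$name, peaks$score,
                 peaks$summit - peaks$start, fmt_na(peaks$fdr),
                 fmt_na(peaks$tags), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix with condition labels
#'
#' The file is a TSV with a header of sample identifiers and one row per
#' gene (first column = gene id).  `condition_map` assigns each sample to one
#' of exactly two conditions; per-gene ANOVA requires at least two replicates
#' per condition.
#'
#' @param path TSV file path
#' @param condition_map named character vector, `sample id -> condition`
#' @return an `expression_table` (see [expression_table()])
#' @export
read_expression <- function(path, condition_map) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- gene_ids
  samples <- colnames(values)
  missing <- setdiff(samples, names(condition_map))
  if (length(missing) > 0) {
    stop("samples missing from condition map: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  expression_table(values, condition_map[samples])
}

#' Construct and validate an expression table
#'
#' @param values non-negative numeric matrix, genes x samples, with row and
#'   column names
#' @param conditions named character vector or factor mapping each column of
#'   `values` to one of exactly two condition labels
#' @return list of class `expression_table` with elements `values` and
#'   `conditions` (factor over samples)
#' @export
expression_table <- function(values, conditions) {
  if (is.null(rownames(values))) stop("values must have gene ids as rownames")
  if (anyDuplicated(rownames(values))) {
    stop("duplicated gene id in expression matrix", call. = FALSE)
  }
  if (any(values < 0)) stop("negative intensity in expression matrix", call. = FALSE)
  conditions <- factor(unname(conditions[colnames(values)]))
  if (nlevels(conditions) != 2) {
    stop("exactly two conditions are required", call. = FALSE)
  }
  if (any(table(conditions) < 2)) {
    stop("at least 2 replicate samples per condition are required (ANOVA)",
         call. = FALSE)
  }
  structure(list(values = values, conditions = conditions),
            class = "expression_table")
}

#' Write an expression table as TSV
#' @param table an `expression_table`
#' @param path output file
#' @export
write_expression <- function(table, path) {
  df <- data.frame(gene_id = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FASTA file into a DNAStringSet
#'
#' Sequences are uppercased on read; duplicate record names and non-IUPAC
#' characters are errors.
#'
#' @param path FASTA file
#' @return a [Biostrings::DNAStringSet] with unique names
#' @export
read_fasta <- function(path) {
  # read as raw strings first: the DNAStringSet constructor below then
  # rejects non-IUPAC characters instead of silently dropping them
  seqs <- Biostrings::readBStringSet(path)
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence names in FASTA: ", path, call. = FALSE)
  }
  Biostrings::DNAStringSet(toupper(as.character(seqs)))
}

#' Write a DNAStringSet (or named character vector) as FASTA
#' @param records sequences with names
#' @param path output file
#' @export
write_fasta <- function(records, path) {
  if (!methods::is(records, "DNAStringSet")) {
    records <- Biostrings::DNAStringSet(records)
  }
  Biostrings::writeXStringSet(records, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#' Sets are intersected with the universe when one is given; sets that become
#' empty are dropped.
#'
#' @param path GMT file
#' @param universe optional character vector of gene ids the analysis is
#'   restricted to
#' @return list with elements `sets` (named list of character vectors) and
#'   `universe` (the supplied universe, or the union of all members)
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 3) stop_parse(path, i, "GMT line needs name, description, members")
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  gene_set_collection(sets, universe)
}

#' Construct and validate a gene-set collection
#'
#' @param sets named list of character vectors of gene ids
#' @param universe optional universe of gene ids; defaults to the union of
#'   all set members
#' @return list with `sets` (each intersected with the universe, empty sets
#'   dropped) and `universe`
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (is.null(universe)) universe <- unique(unlist(sets))
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(s) intersect(s, universe))
  sets <- sets[vapply(sets, length, 0L) > 0]
  list(sets = sets, universe = universe)
}

#' Write a gene-set collection as GMT
#' @param collection list as returned by [gene_set_collection()]
#' @param path output file
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a chromosome sizes file (chrom \\t length)
#' @param path two-column TSV
#' @return named integer vector of chromosome lengths
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(as.integer(tab[[2]]), tab[[1]])
}

#' Write a chromosome sizes file
#' @param sizes named integer vector
#' @param path output file
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(paste(names(sizes), sizes, sep = "\t"), path)
  invisible(path)
}

#' Read tag positions (read 5' ends) from a BED-like file
#'
#' Only the chrom and start columns are used: each line is one sequenced tag
#' whose 5' end is at `start`.
#'
#' @param path BED file of read 5' ends
#' @return `data.frame` with columns `chrom`, `pos`
#' @export
read_tags <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  chrom <- character(length(lines)); pos <- integer(length(lines))
  for (i in seq_along(lines)) {
    f <- split_fields(lines[i])
    if (length(f) < 2) stop_parse(path, i, "expected at least chrom and position")
    p <- as.integer(f[2])
    if (is.na(p) || p < 0) stop_parse(path, i, "invalid tag position")
    chrom[i] <- f[1]; pos[i] <- p
  }
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Write tag positions as 1-bp BED intervals
#' @param tags `data.frame` with `chrom`, `pos`
#' @param path output file
#' @export
write_tags <- function(tags, path) {
  writeLines(paste(tags$chrom, tags$pos, tags$pos + 1L, sep = "\t"), path)
  invisible(path)
}
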