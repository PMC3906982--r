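# Summit-flank extraction and IUPAC consensus scanning for the AT-rich
# Abd-B-type binding site (consensus WTTTAT, i.e. T/ATTTAT).  PWM scoring and
# de novo motif discovery are deliberately out of scope: the flank FASTA this
# module emits is what discovery tools consume.

IUPAC_LETTERS <- names(Biostrings::IUPAC_CODE_MAP)

#' Extract fixed-width sequences around peak summits
#'
#' One record per peak covering `[summit - flank, summit + flank)` (200 bp at
#' the 100 bp default), truncated at chromosome edges with a warning.
#' Records are named after the peaks and are ready for external motif
#' discovery.
#'
#' @param peaks peak table
#' @param genome a [Biostrings::DNAStringSet] keyed by chromosome
#' @param flank bases on each side of the summit (default 100)
#' @return a `DNAStringSet` of flank sequences
#' @export
extract_summit_flanks <- function(peaks, genome, flank = 100) {
  stopifnot(flank >= 1)
  bad <- setdiff(unique(peaks$chrom), names(genome))
  if (length(bad) > 0) {
    stop("summit on unknown chromosome(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  s <- peaks$summit - flank
  e <- peaks$summit + flank
  s_cl <- pmax(s, 0)
  e_cl <- pmin(e, lens[peaks$chrom])
  n_trunc <- sum(s_cl != s | e_cl != e)
  if (n_trunc > 0) {
    warning(n_trunc, " flank record(s) truncated at chromosome edges")
  }
  out <- Biostrings::DNAStringSet(vapply(seq_len(nrow(peaks)), function(i) {
    as.character(Biostrings::subseq(genome[[peaks$chrom[i]]],
                                    start = s_cl[i] + 1, end = e_cl[i]))
  }, ""))
  names(out) <- peaks$name
  out
}

validate_iupac <- function(pattern) {
  letters <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(letters, IUPAC_LETTERS)
  if (length(bad) > 0) {
    stop("invalid IUPAC symbol(s) in pattern: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  paste(letters, collapse = "")
}

#' Scan sequences for an IUPAC consensus motif on both strands
#'
#' Reports every match of the degenerate `pattern` (default `WTTTAT`, the
#' Abd-B-type consensus) on either strand.  Minus-strand matches are found by
#' scanning the reverse complement and mapping offsets back to plus-strand
#' coordinates.  Overlapping matches are all reported; an `N` in a subject
#' sequence never matches any pattern letter.
#'
#' @param sequences `DNAStringSet` or named character vector (A/C/G/T/N)
#' @param pattern IUPAC consensus string
#' @return `data.frame` with `seq_id`, `offset` (0-based start of the match
#'   in plus-strand coordinates), `strand`, `match` (the matching substring
#'   as read on the reported strand)
#' @export
scan_consensus <- function(sequences, pattern = "WTTTAT") {
  pattern <- validate_iupac(pattern)
  if (!methods::is(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  k <- nchar(pattern)
  res <- list()
  for (i in seq_along(sequences)) {
    subj <- sequences[[i]]
    L <- length(subj)
    if (L < k) next
    id <- names(sequences)[i]
    # fixed = "subject": pattern ambiguity codes are degenerate, subject
    # letters (including N) are literal, so N never matches
    fwd <- Biostrings::matchPattern(pattern, subj, fixed = "subject")
    if (length(fwd) > 0) {
      res[[length(res) + 1]] <- data.frame(
        seq_id = id, offset = BiocGenerics::start(fwd) - 1L, strand = "+",
        match = as.character(fwd), stringsAsFactors = FALSE)
    }
    rc <- Biostrings::reverseComplement(subj)
    rev <- Biostrings::matchPattern(pattern, rc, fixed = "subject")
    if (length(rev) > 0) {
      # offset j (0-based) on the reverse complement maps to plus-strand
      # start L - j - k
      res[[length(res) + 1]] <- data.frame(
        seq_id = id, offset = L - (BiocGenerics::start(rev) - 1L) - k,
        strand = "-", match = as.character(rev), stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0) {
    return(data.frame(seq_id = character(0), offset = integer(0),
                      strand = character(0), match = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(match(out$seq_id, names(sequences)), out$offset, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Mononucleotide shuffle of sequences
#'
#' Seeded Fisher-Yates permutation of each sequence's letters, preserving
#' its length and nucleotide composition exactly.  Used as the default
#' enrichment background.
#'
#' @param sequences `DNAStringSet` or character vector
#' @param seed integer RNG seed
#' @return a `DNAStringSet` of shuffled sequences
#' @export
shuffle_sequences <- function(sequences, seed = 1) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  set.seed(seed)
  out <- vapply(sequences, function(s) {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  }, "")
  Biostrings::DNAStringSet(out)
}

#' Consensus-motif enrichment of foreground vs background sequences
#'
#' Compares the fraction of sequences carrying at least one consensus hit
#' (either strand) between a foreground set and a background set (supplied,
#' or generated by per-sequence mononucleotide shuffling).  Reports the rate
#' ratio and a one-sided binomial p-value for the foreground hit count at
#' the background rate.
#'
#' @param foreground `DNAStringSet` (nonempty)
#' @param background optional `DNAStringSet`; default is a seeded shuffle of
#'   the foreground
#' @param pattern IUPAC consensus (default `WTTTAT`)
#' @param seed RNG seed for the shuffle background
#' @return list with `fg_rate`, `bg_rate`, `fold` (`Inf` flagged via
#'   `fold_infinite` when the background rate is 0 with foreground hits;
#'   `NA` with `fold_defined = FALSE` when the pattern hits neither set),
#'   `p_value`, and the underlying counts
#' @export
motif_enrichment <- function(foreground, background = NULL,
                             pattern = "WTTTAT", seed = 1) {
  if (length(foreground) == 0) stop("empty foreground", call. = FALSE)
  if (is.null(background)) background <- shuffle_sequences(foreground, seed)
  hit_count <- function(seqs) {
    hits <- scan_consensus(seqs, pattern)
    length(unique(hits$seq_id))
  }
  k_fg <- hit_count(foreground); n_fg <- length(foreground)
  k_bg <- hit_count(background); n_bg <- length(background)
  fg_rate <- k_fg / n_fg
  bg_rate <- k_bg / n_bg
  fold_defined <- !(k_fg == 0 && k_bg == 0)
  fold_infinite <- bg_rate == 0 && k_fg > 0
  fold <- if (!fold_defined) NA_real_
          else if (fold_infinite) Inf
          else fg_rate / bg_rate
  p <- if (k_fg == 0) {
    1
  } else if (bg_rate == 0) {
    # below any representable binomial tail at rate 0
    .Machine$double.xmin
  } else {
    stats::binom.test(k_fg, n_fg, p = bg_rate,
                      alternative = "greater")$p.value
  }
  list(fg_rate = fg_rate, bg_rate = bg_rate, fold = fold,
       fold_defined = fold_defined, fold_infinite = fold_infinite,
       p_value = p, k_fg = k_fg, n_fg = n_fg, k_bg = k_bg, n_bg = n_bg,
       pattern = pattern)
}
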