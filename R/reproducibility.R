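# Inter-replicate reproducibility: Pearson correlation of tag densities in
# 200 bp non-overlapping windows tiling the genome.

#' Windowed tag densities over a genome
#'
#' Counts, per chromosome, the tags whose 5' position falls in each
#' non-overlapping window `[k*w, (k+1)*w)`.  The last window of a chromosome
#' is kept even when shorter than `w`, so every tag is counted exactly once;
#' each chromosome has `ceiling(length / w)` windows.
#'
#' @param tags `data.frame` with `chrom`, `pos` (0-based read 5' ends)
#' @param chrom_sizes named integer vector of chromosome lengths
#' @param window_size window width in bp (default 200)
#' @return named list of integer count vectors, one per chromosome in
#'   `chrom_sizes` order
#' @export
window_tag_density <- function(tags, chrom_sizes, window_size = 200) {
  stopifnot(window_size >= 1)
  bad_chrom <- setdiff(unique(tags$chrom), names(chrom_sizes))
  if (length(bad_chrom) > 0) {
    stop("tags on unknown chromosome(s): ", paste(bad_chrom, collapse = ", "),
         call. = FALSE)
  }
  out <- vector("list", length(chrom_sizes))
  names(out) <- names(chrom_sizes)
  for (chr in names(chrom_sizes)) {
    len <- chrom_sizes[[chr]]
    n_win <- as.integer(ceiling(len / window_size))
    pos <- tags$pos[tags$chrom == chr]
    if (any(pos >= len)) {
      stop("tag position beyond end of ", chr, call. = FALSE)
    }
    out[[chr]] <- tabulate(pos %/% window_size + 1L, nbins = n_win)
  }
  out
}

#' Pearson correlation between two replicate window-density vectors
#'
#' Concatenates per-chromosome window counts (genome order must match) and
#' returns the standard Pearson correlation, flagged as highly correlated
#' when `R > 0.9`.  By default every genome window enters the computation,
#' including windows empty in both replicates; `nonzero_only = TRUE`
#' restricts to windows with at least one tag in either replicate.
#'
#' @param d1,d2 window-density lists from [window_tag_density()] (or plain
#'   numeric vectors of equal length)
#' @param nonzero_only drop windows that are zero in both replicates
#' @return list with `r`, `highly_correlated` (`r > 0.9`), `n_windows`, and
#'   `per_chrom` (`data.frame` of per-chromosome correlations, when list
#'   input was given; `NA` for zero-variance chromosomes)
#' @export
replicate_correlation <- function(d1, d2, nonzero_only = FALSE) {
  per_chrom <- NULL
  if (is.list(d1)) {
    stopifnot(is.list(d2), identical(names(d1), names(d2)))
    per_chrom <- data.frame(
      chrom = names(d1),
      r = vapply(names(d1), function(chr) {
        v1 <- d1[[chr]]; v2 <- d2[[chr]]
        if (nonzero_only) {
          keep <- v1 > 0 | v2 > 0
          v1 <- v1[keep]; v2 <- v2[keep]
        }
        if (length(v1) < 2 || stats::var(v1) == 0 || stats::var(v2) == 0) {
          NA_real_
        } else {
          stats::cor(v1, v2)
        }
      }, 0),
      row.names = NULL, stringsAsFactors = FALSE
    )
    d1 <- unlist(d1, use.names = FALSE)
    d2 <- unlist(d2, use.names = FALSE)
  }
  if (length(d1) != length(d2)) {
    stop("replicate density vectors have different lengths", call. = FALSE)
  }
  if (nonzero_only) {
    keep <- d1 > 0 | d2 > 0
    d1 <- d1[keep]; d2 <- d2[keep]
  }
  if (length(d1) < 2 || stats::var(d1) == 0 || stats::var(d2) == 0) {
    stop("replicate correlation undefined: zero variance in a density vector",
         call. = FALSE)
  }
  r <- stats::cor(d1, d2)
  list(r = r, highly_correlated = r > 0.9, n_windows = length(d1),
       per_chrom = per_chrom)
}
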