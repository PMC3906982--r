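# Gene-set over-representation analysis: hypergeometric upper-tail p-values
# with Benjamini-Hochberg FDR and the fold > 2 / FDR < 1% filter used to
# screen annotation categories.

#' Hypergeometric over-representation analysis
#'
#' For each gene set of size `K` in a universe of size `N`, tests the overlap
#' `k` with a study set of size `n` (both intersected with the universe)
#' against the hypergeometric null: `p = P(X >= k)` with
#' `X ~ Hypergeometric(N, K, n)`.  Fold enrichment is `(k/n) / (K/N)`.
#' `ease = TRUE` applies the conservative EASE-style variant that removes one
#' overlapping gene (`p = P(X >= k - 1)` evaluated at `k - 1`).
#'
#' @param study_set character vector of gene ids
#' @param collection a gene-set collection from [gene_set_collection()] /
#'   [read_gmt()]
#' @param ease use the k-1 penalized score (default `FALSE`)
#' @return `data.frame` with columns `set_name`, `k`, `n`, `K`, `N`, `fold`,
#'   `p_value`, `fdr` (BH-adjusted over the collection)
#' @export
hypergeom_ora <- function(study_set, collection, ease = FALSE) {
  universe <- collection$universe
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  study <- intersect(unique(study_set), universe)
  if (length(study) == 0) stop("empty study set (after universe intersection)",
                               call. = FALSE)
  N <- length(universe)
  n <- length(study)
  rows <- lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    K <- length(set)
    k <- length(intersect(study, set))
    kk <- if (ease) max(k - 1L, 0L) else k
    p <- stats::phyper(kk - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, n = n, K = K, N = N,
               fold = (k / n) / (K / N), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) == 0) {
    data.frame(set_name = character(0), k = integer(0), n = integer(0),
               K = integer(0), N = integer(0), fold = numeric(0),
               p_value = numeric(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  rownames(out) <- NULL
  out$fdr <- bh_fdr(out$p_value)
  out
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up FDR adjustment with monotonicity enforcement, as implemented by
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\]
#' @return adjusted values, same length and order
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Filter ORA results at fold and FDR thresholds
#'
#' Keeps results with `fold > fold_min` (strict) and `fdr < fdr_max`
#' (strict), ordered by ascending FDR then descending fold.
#'
#' @param results output of [hypergeom_ora()]
#' @param fold_min minimum fold enrichment, exclusive (default 2.0)
#' @param fdr_max maximum FDR, exclusive (default 0.01)
#' @return filtered, reordered `data.frame`
#' @export
filter_enriched <- function(results, fold_min = 2.0, fdr_max = 0.01) {
  keep <- results$fold > fold_min & results$fdr < fdr_max
  out <- results[keep, , drop = FALSE]
  out <- out[order(out$fdr, -out$fold), , drop = FALSE]
  rownames(out) <- NULL
  out
}
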