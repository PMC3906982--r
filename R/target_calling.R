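# Binding-gene assignment and direct-target calling: a gene is bound when at
# least one peak lies within the gene locus extended by a flank (5 kb by
# default) on each side, and a direct target when it is both bound and
# responsive.

#' Map peaks to the genes they bind
#'
#' A gene is bound by a peak when the peak shares at least one bp with the
#' gene locus (transcript span) extended by `flank` bp on each side, under
#' half-open semantics.  This follows the reading "within -5 ~ +5 kb of the
#' gene locus", not TSS +/- 5 kb.  One peak may bind several genes.
#' `mode = "summit"` is a stricter sensitivity-analysis variant requiring the
#' summit base itself to fall inside the extended locus.
#'
#' @param peaks peak table
#' @param models gene-model table
#' @param flank extension in bp on each side of the gene locus (default 5000)
#' @param mode `"peak"` (any overlap of the peak interval, default) or
#'   `"summit"` (summit containment)
#' @return named list, `gene_id -> character vector of peak names`, with one
#'   entry per bound gene
#' @export
binding_genes <- function(peaks, models, flank = 5000,
                          mode = c("peak", "summit")) {
  mode <- match.arg(mode)
  stopifnot(flank >= 0)
  if (nrow(peaks) == 0 || nrow(models) == 0) {
    return(stats::setNames(list(), character(0)))
  }
  win <- gr0(models$chrom, pmax(models$start - flank, 0), models$end + flank)
  q <- if (mode == "peak") {
    gr0(peaks$chrom, peaks$start, peaks$end)
  } else {
    gr0(peaks$chrom, peaks$summit, peaks$summit + 1L)
  }
  hits <- GenomicRanges::findOverlaps(q, win)
  out <- list()
  for (k in seq_along(hits)) {
    g <- models$gene_id[S4Vectors::subjectHits(hits)[k]]
    p <- peaks$name[S4Vectors::queryHits(hits)[k]]
    out[[g]] <- c(out[[g]], p)
  }
  out
}

#' Call direct target genes
#'
#' Combines the binding map with the responsive-gene table: a gene is a
#' direct target iff it is bound and responsive; its direction is carried
#' over from the expression result.  Genes appearing in only one input are
#' retained with the missing-side flags false/none.
#'
#' @param binding_map output of [binding_genes()]
#' @param de_results output of [call_responsive()]
#' @return `data.frame` with columns `gene_id`, `bound`, `n_peaks`,
#'   `peak_ids` (comma-collapsed), `direction`, `direct_target`
#' @export
call_direct_targets <- function(binding_map, de_results) {
  gene_ids <- union(de_results$gene_id, names(binding_map))
  bound <- gene_ids %in% names(binding_map)
  dir_map <- stats::setNames(de_results$direction, de_results$gene_id)
  direction <- unname(dir_map[gene_ids])
  direction[is.na(direction)] <- "none"
  peak_ids <- vapply(gene_ids, function(g) {
    p <- binding_map[[g]]
    if (is.null(p)) "" else paste(p, collapse = ",")
  }, "")
  n_peaks <- vapply(gene_ids, function(g) length(binding_map[[g]]), 0L)
  data.frame(
    gene_id = gene_ids, bound = bound, n_peaks = unname(n_peaks),
    peak_ids = unname(peak_ids), direction = direction,
    direct_target = bound & direction != "none",
    row.names = NULL, stringsAsFactors = FALSE
  )
}

round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Summarize the direct-target bookkeeping
#'
#' The headline accounting of the analysis: responsive counts (up/down),
#' bound genes, direct targets (up/down) and the share of responsive genes
#' that are direct targets, as a percentage rounded half-away-from-zero to
#' one decimal.  For each optional gene set, the analogous within-set share
#' `100 * |targets in set| / |responsive in set|` is reported.
#'
#' @param target_calls output of [call_direct_targets()]
#' @param gene_sets optional named list of character vectors of gene ids
#' @return list with `n_responsive`, `n_up`, `n_down`, `n_bound`,
#'   `n_targets`, `n_targets_up`, `n_targets_down`,
#'   `pct_targets_of_responsive` (`NA` with `pct_defined = FALSE` when there
#'   are no responsive genes) and, per gene set, a record with the overlap
#'   counts and percentage
#' @export
summarize_targets <- function(target_calls, gene_sets = NULL) {
  responsive <- target_calls$direction != "none"
  targ <- target_calls$direct_target
  out <- list(
    n_responsive = sum(responsive),
    n_up = sum(target_calls$direction == "up"),
    n_down = sum(target_calls$direction == "down"),
    n_bound = sum(target_calls$bound),
    n_targets = sum(targ),
    n_targets_up = sum(targ & target_calls$direction == "up"),
    n_targets_down = sum(targ & target_calls$direction == "down")
  )
  out$pct_defined <- out$n_responsive > 0
  out$pct_targets_of_responsive <- if (out$pct_defined) {
    round_half_up(100 * out$n_targets / out$n_responsive, 1)
  } else {
    NA_real_
  }
  if (!is.null(gene_sets)) {
    out$gene_sets <- lapply(gene_sets, function(set) {
      n_resp_set <- sum(responsive & target_calls$gene_id %in% set)
      n_targ_set <- sum(targ & target_calls$gene_id %in% set)
      list(n_targets_in_set = n_targ_set, n_responsive_in_set = n_resp_set,
           pct = if (n_resp_set > 0) {
             round_half_up(100 * n_targ_set / n_resp_set, 1)
           } else {
             NA_real_
           })
    })
  }
  out
}

#' Write a target-call table as TSV
#' @param target_calls output of [call_direct_targets()]
#' @param path output file
#' @export
write_target_calls <- function(target_calls, path) {
  utils::write.table(target_calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
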