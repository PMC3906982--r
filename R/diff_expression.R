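# Responsive-gene calling: per-gene one-way ANOVA on log2 intensities plus a
# signed fold change on linear-scale condition means, thresholded at
# |FC| >= 1.5 and P < 0.01 by default.

#' Signed fold change between two condition means
#'
#' Uses the signed-ratio ("Partek-style") convention: the returned value is
#' `+(induced/control)` when the induced mean is at least the control mean and
#' `-(control/induced)` otherwise, so its magnitude is always `>= 1` and its
#' sign carries the direction of change.  A gene with no change has fold
#' `+1`.
#'
#' @param mean_control,mean_induced positive linear-scale condition means
#' @return signed ratio with `|value| >= 1`
#' @examples
#' signed_fold_change(10, 15)  # +1.5
#' signed_fold_change(15, 10)  # -1.5
#' @export
signed_fold_change <- function(mean_control, mean_induced) {
  if (any(mean_control <= 0) || any(mean_induced <= 0)) {
    stop("condition means must be positive", call. = FALSE)
  }
  ifelse(mean_induced >= mean_control,
         mean_induced / mean_control,
         -mean_control / mean_induced)
}

#' One-way ANOVA p-value for one gene across two conditions
#'
#' Computed on log2-transformed intensities via `stats::oneway.test` with the
#' classical equal-variance assumption; with two groups this is equivalent to
#' the pooled two-sample t-test (F = t^2).  Degenerate zero-variance inputs
#' (possible on noiseless synthetic data) resolve to p = 1 when the group
#' means are equal and p = 0 when they differ.
#'
#' @param control,induced numeric vectors of linear-scale intensities,
#'   `>= 2` values each
#' @return two-sided p-value in \[0, 1\]
#' @export
gene_anova_p <- function(control, induced) {
  if (length(control) < 2 || length(induced) < 2) {
    stop("at least 2 replicates per condition are required", call. = FALSE)
  }
  x <- log2(control); y <- log2(induced)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  vals <- c(x, y)
  grp <- factor(rep(c("a", "b"), c(length(x), length(y))))
  stats::oneway.test(vals ~ grp, var.equal = TRUE)$p.value
}

#' Call responsive genes from an expression table
#'
#' One result row per gene: the signed fold change of linear-scale condition
#' means, the per-gene ANOVA p-value on log2 intensities, and the responsive
#' call `responsive <=> |fold_change| >= fc_threshold AND p_value <
#' p_threshold`, with `direction` following the fold-change sign.
#'
#' @param table an `expression_table`
#' @param control the condition label treated as baseline; defaults to the
#'   first factor level
#' @param fc_threshold minimum fold-change magnitude (default 1.5)
#' @param p_threshold maximum raw p-value, strict (default 0.01); no
#'   multiple-testing correction is applied at this stage
#' @return `data.frame` with columns `gene_id`, `mean_control`,
#'   `mean_induced`, `fold_change`, `p_value`, `responsive`, `direction`
#' @export
call_responsive <- function(table, control = NULL, fc_threshold = 1.5,
                            p_threshold = 0.01) {
  stopifnot(inherits(table, "expression_table"))
  if (is.null(control)) control <- levels(table$conditions)[1]
  if (!control %in% levels(table$conditions)) {
    stop("unknown control condition: ", control, call. = FALSE)
  }
  is_ctrl <- table$conditions == control
  v <- table$values
  mean_ctrl <- rowMeans(v[, is_ctrl, drop = FALSE])
  mean_ind <- rowMeans(v[, !is_ctrl, drop = FALSE])
  fc <- signed_fold_change(mean_ctrl, mean_ind)
  p <- vapply(seq_len(nrow(v)), function(i) {
    gene_anova_p(v[i, is_ctrl], v[i, !is_ctrl])
  }, 0)
  responsive <- abs(fc) >= fc_threshold & p < p_threshold
  direction <- ifelse(!responsive, "none", ifelse(fc > 0, "up", "down"))
  data.frame(
    gene_id = rownames(v), mean_control = mean_ctrl, mean_induced = mean_ind,
    fold_change = fc, p_value = p, responsive = responsive,
    direction = direction, row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Summarize a responsive-gene table
#' @param de_results output of [call_responsive()]
#' @return list with `n_responsive`, `n_up`, `n_down`
#' @export
summarize_de <- function(de_results) {
  list(
    n_responsive = sum(de_results$responsive),
    n_up = sum(de_results$direction == "up"),
    n_down = sum(de_results$direction == "down")
  )
}

#' Write a differential-expression result table as TSV
#' @param de_results output of [call_responsive()]
#' @param path output file
#' @export
write_de_results <- function(de_results, path) {
  utils::write.table(de_results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
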