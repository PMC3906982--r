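# End-to-end orchestration: synthetic (or file-based) inputs through peak
# filtering, responsive-gene calling, annotation, reproducibility, target
# calling, motif enrichment and ORA, into one self-validating report.

#' Default pipeline configuration
#'
#' Every analysis threshold is a named parameter defaulting to the study
#' values: peak FDR < 1%, fold-change magnitude >= 1.5 with P < 0.01,
#' binding flank 5 kb, promoter/downstream extents 5 kb, 200 bp correlation
#' windows, 100 bp TSS histogram bins, 100 bp motif flanks with consensus
#' `WTTTAT`, ORA filter fold > 2 with FDR < 1%.  Data come either from the
#' `synthetic` block (default) or from a `paths` block naming input files
#' (`genome`, `genes`, `peaks_rep1`, `peaks_rep2`, `tags_rep1`, `tags_rep2`,
#' `chrom_sizes`, `expression`, `conditions`, `gene_sets`).
#'
#' @param ... overrides merged into the defaults (named sub-lists merge
#'   recursively one level down)
#' @return configuration list
#' @export
default_config <- function(...) {
  cfg <- list(
    synthetic = synthetic_config(),
    paths = NULL,
    thresholds = list(
      fc = 1.5, p = 0.01, peak_fdr = 0.01, flank = 5000,
      promoter_bp = 5000, downstream_bp = 5000, window_size = 200,
      tss_bin = 100, motif_flank = 100, motif_pattern = "WTTTAT",
      ora_fold = 2.0, ora_fdr = 0.01
    ),
    nonzero_windows_only = FALSE
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], overrides[[nm]])
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()].
#'
#' @param path YAML file
#' @return configuration list
#' @export
config_from_yaml <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

load_pipeline_inputs <- function(config, seed) {
  if (!is.null(config$paths)) {
    p <- config$paths
    cond <- utils::read.table(p$conditions, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    condition_map <- stats::setNames(cond$condition, cond$sample)
    models <- read_gene_models(p$genes, format = p$genes_format %||% "bed12")
    list(
      genome = read_fasta(p$genome), models = models,
      chrom_sizes = read_chrom_sizes(p$chrom_sizes),
      peaks_rep1 = read_peaks(p$peaks_rep1),
      peaks_rep2 = read_peaks(p$peaks_rep2),
      tags_rep1 = read_tags(p$tags_rep1),
      tags_rep2 = read_tags(p$tags_rep2),
      expression = read_expression(p$expression, condition_map),
      gene_sets = if (!is.null(p$gene_sets)) read_gmt(p$gene_sets) else NULL,
      truth = NULL
    )
  } else {
    simulate_dataset(config$synthetic, seed = seed)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full direct-target pipeline
#'
#' Stages, in order: peak FDR filter (replicate 1 peaks drive all
#' peak-based stages), responsive-gene calling, feature classification and
#' nearest-TSS profiling, replicate window-density correlation, binding and
#' direct-target calling, summit-flank motif enrichment, and gene-set ORA
#' of the direct targets against the expression universe.  The assembled
#' report is checked with [validate_report()] before it is returned; when
#' `outdir` is given every table is written there, the report JSON last.
#'
#' @param config from [default_config()]
#' @param seed integer seed governing all randomness (synthetic data and the
#'   motif shuffle background)
#' @param outdir optional output directory
#' @return a `pipeline_report` list
#' @export
run_pipeline <- function(config = default_config(), seed = 1, outdir = NULL) {
  th <- config$thresholds
  data <- load_pipeline_inputs(config, seed)
  peaks <- filter_peaks_fdr(data$peaks_rep1, th$peak_fdr)

  de <- call_responsive(data$expression, control = "control",
                        fc_threshold = th$fc, p_threshold = th$p)
  de_sum <- summarize_de(de)

  index <- build_feature_index(data$models, data$chrom_sizes,
                               promoter_bp = th$promoter_bp,
                               downstream_bp = th$downstream_bp)
  annot <- annotation_summary(peaks, index)
  tss_hist <- tss_distance_histogram(peaks, data$models,
                                     bin_width = th$tss_bin)

  dens1 <- window_tag_density(data$tags_rep1, data$chrom_sizes,
                              window_size = th$window_size)
  dens2 <- window_tag_density(data$tags_rep2, data$chrom_sizes,
                              window_size = th$window_size)
  repro <- replicate_correlation(dens1, dens2,
                                 nonzero_only = config$nonzero_windows_only)

  binding <- binding_genes(peaks, data$models, flank = th$flank)
  targets <- call_direct_targets(binding, de)
  target_sum <- summarize_targets(
    targets, gene_sets = if (!is.null(data$gene_sets)) data$gene_sets$sets)

  flanks <- extract_summit_flanks(peaks, data$genome, flank = th$motif_flank)
  motif <- motif_enrichment(flanks, pattern = th$motif_pattern,
                            seed = seed + 17L)

  ora <- NULL
  ora_filtered <- NULL
  target_ids <- targets$gene_id[targets$direct_target]
  if (!is.null(data$gene_sets) && length(target_ids) > 0) {
    universe <- rownames(data$expression$values)
    coll <- gene_set_collection(data$gene_sets$sets, universe)
    ora <- hypergeom_ora(target_ids, coll)
    ora_filtered <- filter_enriched(ora, fold_min = th$ora_fold,
                                    fdr_max = th$ora_fdr)
  }

  report <- structure(list(
    seed = seed,
    thresholds = th,
    n_peaks_input = nrow(data$peaks_rep1),
    n_peaks_used = nrow(peaks),
    de = de_sum,
    targets = target_sum,
    annotation = annot,
    tss_histogram_mass = sum(tss_hist$count),
    replicate_r = repro$r,
    replicate_highly_correlated = repro$highly_correlated,
    motif = motif[c("fg_rate", "bg_rate", "fold", "fold_defined",
                    "fold_infinite", "p_value", "pattern")],
    ora_top = if (!is.null(ora) && nrow(ora) > 0) {
      o <- ora[order(ora$p_value, -ora$fold), ]
      as.list(o[1, c("set_name", "k", "n", "K", "N", "fold", "p_value", "fdr")])
    },
    n_ora_enriched = if (!is.null(ora_filtered)) nrow(ora_filtered)
  ), class = "pipeline_report")

  val <- validate_report(report)
  if (!val$pass) {
    stop("pipeline report failed self-validation: ",
         paste(val$violations, collapse = "; "), call. = FALSE)
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_de_results(de, file.path(outdir, "de_results.tsv"))
    utils::write.table(annot, file.path(outdir, "annotation_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tss_hist, file.path(outdir, "tss_histogram.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_target_calls(targets, file.path(outdir, "target_calls.tsv"))
    write_fasta(flanks, file.path(outdir, "summit_flanks.fa"))
    if (!is.null(ora)) {
      utils::write.table(ora, file.path(outdir, "ora_results.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns",
                         force = TRUE)
  }
  report
}

#' Validate the internal identities of a pipeline report
#'
#' Checks every bookkeeping identity the analysis guarantees: up + down =
#' responsive (expression level), targets_up + targets_down = targets,
#' targets <= bound and targets <= responsive, annotation fractions sum to 1
#' (when peaks exist) with counts summing to the peaks used, and the
#' reported percentage of responsive genes that are targets matching its
#' counts.  Failures are returned, not raised.
#'
#' @param report a `pipeline_report` (or an equivalently shaped list, e.g.
#'   hand-entered summary counts)
#' @return list with `pass` (logical) and `violations` (character vector)
#' @export
validate_report <- function(report) {
  v <- character(0)
  de <- report$de; tg <- report$targets
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  if (!is.null(de)) {
    chk(de$n_up + de$n_down == de$n_responsive,
        "de: up + down != responsive")
  }
  if (!is.null(tg)) {
    chk(tg$n_up + tg$n_down == tg$n_responsive,
        "targets: up + down != responsive")
    chk(tg$n_targets_up + tg$n_targets_down == tg$n_targets,
        "targets: targets_up + targets_down != targets")
    chk(tg$n_targets <= tg$n_bound, "targets: targets > bound")
    chk(tg$n_targets <= tg$n_responsive, "targets: targets > responsive")
    if (isTRUE(tg$pct_defined) || (is.null(tg$pct_defined) &&
                                   tg$n_responsive > 0)) {
      expected <- round_half_up(100 * tg$n_targets / tg$n_responsive, 1)
      chk(isTRUE(all.equal(tg$pct_targets_of_responsive, expected)),
          "targets: percentage inconsistent with counts")
    }
  }
  if (!is.null(de) && !is.null(tg)) {
    chk(de$n_responsive == tg$n_responsive,
        "responsive counts disagree between de and target summaries")
  }
  if (!is.null(report$annotation)) {
    a <- report$annotation
    chk(sum(a$count) == report$n_peaks_used %||% sum(a$count),
        "annotation: counts do not sum to peaks used")
    if (sum(a$count) > 0) {
      chk(abs(sum(a$fraction) - 1) < 1e-9,
          "annotation: fractions do not sum to 1")
    }
  }
  list(pass = length(v) == 0, violations = v)
}
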