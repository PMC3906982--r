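# Ground-truthed synthetic data: a small multi-chromosome genome with gene
# models, two replicate ChIP peak/tag sets with tunable inter-replicate
# correlation and planted consensus motifs, a 3-vs-3 expression matrix with
# planted signed fold changes, and gene-set collections -- everything the
# downstream pipeline consumes, with the truth recorded alongside.
#
# Each generator draws from its own RNG stream, seeded from the master seed
# by a fixed offset, so adding one generator never perturbs another's draws.

SEED_OFFSET_GENOME <- 101L
SEED_OFFSET_CHIP <- 202L
SEED_OFFSET_EXPRESSION <- 303L
SEED_OFFSET_GENESETS <- 404L

#' Default configuration of the synthetic dataset
#'
#' Returns the nested configuration list the generators consume; any element
#' can be overridden via `...` (named sub-lists are merged into the
#' defaults).  The defaults describe a 3 x 500 kb genome with 60 genes, 40%
#' of genes bound, an inter-replicate window correlation target of 0.93, a
#' planted Abd-B-type consensus under every true summit, and a 3-vs-3
#' expression design in which 30% of genes (bound or not, independently)
#' carry planted fold changes of magnitude >= 1.5 over 10% multiplicative
#' noise, 40% of them upward.
#'
#' @param ... named overrides, e.g. `chip = list(rho = 1, summit_jitter_sd = 0)`
#' @return nested configuration list with blocks `genome`, `chip`,
#'   `expression`, `gene_sets`
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    genome = list(
      n_chroms = 3L, chrom_len = 500000L, genes_per_chrom = 20L,
      gene_len_min = 2000L, gene_len_max = 8000L,
      gap_min = 12000L, gap_max = 14000L, first_gene_offset = 6000L,
      max_exons = 4L, noncoding_prob = 0.1
    ),
    chip = list(
      frac_genes_bound = 0.4, promoter_site_prob = 0.6,
      n_intergenic_sites = 6L, rho = 0.93,
      tags_per_site_mean = 200, tags_per_site_shape = 4,
      background_rate = 0.2, window_size = 200L,
      summit_jitter_sd = 10, motif_prob = 1.0, peak_halfwidth = 150L,
      n_noise_peaks = 3L
    ),
    expression = list(
      n_reps = 3L, frac_bound_responsive = 0.3, frac_unbound_responsive = 0.3,
      up_frac = 0.4, fc_min = 1.5, fc_extra_rate = 2,
      baseline_meanlog = log(500), baseline_sdlog = 0.8, noise_cv = 0.1
    ),
    gene_sets = list(n_random_sets = 5L, random_set_min = 8L,
                     random_set_max = 16L, planted_extra = 4L)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], overrides[[nm]])
  }
  cfg
}

#' Generate a toy genome with gene models
#'
#' Places `genes_per_chrom` genes per chromosome on random strands with
#' inter-gene gaps of at least `gap_min` bp (default 12 kb, so that the
#' +/- 5 kb extended loci of neighbouring genes never overlap), random exon
#' structures and CDS bounds; a fraction of genes is non-coding
#' (`cds_start == cds_end`).  Chromosome sequence is uniform random ACGT.
#' Fully deterministic given the seed.
#'
#' @param config `genome` block of [synthetic_config()]
#' @param seed master seed (the genome stream uses a fixed offset from it)
#' @return list with `genome` ([Biostrings::DNAStringSet]), `models`
#'   (gene-model table), `chrom_sizes`
#' @export
generate_genome <- function(config = synthetic_config()$genome, seed = 1) {
  g <- config
  worst <- g$first_gene_offset +
    g$genes_per_chrom * (g$gene_len_max + g$gap_max)
  if (g$genes_per_chrom > 0 && worst > g$chrom_len) {
    stop(sprintf(paste0("infeasible packing: %d genes of up to %d bp with ",
                        "gaps up to %d bp cannot fit in %d bp"),
                 g$genes_per_chrom, g$gene_len_max, g$gap_max, g$chrom_len),
         call. = FALSE)
  }
  if (g$gap_min < 12000) {
    stop("gap_min below 12 kb: +/- 5 kb extended loci could overlap",
         call. = FALSE)
  }
  set.seed(seed + SEED_OFFSET_GENOME)
  chroms <- paste0("chr", seq_len(g$n_chroms))
  chrom_sizes <- stats::setNames(rep(g$chrom_len, g$n_chroms), chroms)
  seqs <- vapply(chroms, function(chr) {
    paste(sample(c("A", "C", "G", "T"), g$chrom_len, replace = TRUE),
          collapse = "")
  }, "")
  recs <- list()
  for (chr in chroms) {
    pos <- g$first_gene_offset
    for (j in seq_len(g$genes_per_chrom)) {
      len <- sample(g$gene_len_min:g$gene_len_max, 1)
      start <- pos
      end <- start + len
      strand <- sample(c("+", "-"), 1)
      n_ex <- sample(seq_len(g$max_exons), 1)
      # alternate exon/intron segments spanning the gene exactly
      n_seg <- 2L * n_ex - 1L
      w <- stats::rexp(n_seg) + 0.3
      seg <- diff(round(c(0, cumsum(w)) / sum(w) * len))
      seg[seg < 1] <- 1
      seg[n_seg] <- len - sum(seg[-n_seg])
      if (seg[n_seg] < 1) { n_ex <- 1L; seg <- len }
      bounds <- start + c(0, cumsum(seg))
      ex_idx <- seq(1, 2 * n_ex - 1, by = 2)
      exon_starts <- bounds[ex_idx]
      exon_ends <- bounds[ex_idx + 1]
      if (stats::runif(1) < g$noncoding_prob || len < 600) {
        cds_start <- cds_end <- start
      } else {
        trim <- round(len * stats::runif(2, 0.05, 0.2))
        cds_start <- start + trim[1]
        cds_end <- end - trim[2]
      }
      recs[[length(recs) + 1]] <- list(
        gene_id = sprintf("gene_%03d", length(recs) + 1L), chrom = chr,
        start = start, end = end, strand = strand,
        cds_start = cds_start, cds_end = cds_end,
        exon_starts = as.integer(exon_starts), exon_ends = as.integer(exon_ends)
      )
      pos <- end + sample(g$gap_min:g$gap_max, 1)
    }
  }
  models <- data.frame(
    gene_id = vapply(recs, `[[`, "", "gene_id"),
    chrom = vapply(recs, `[[`, "", "chrom"),
    start = vapply(recs, function(r) as.integer(r$start), 0L),
    end = vapply(recs, function(r) as.integer(r$end), 0L),
    strand = vapply(recs, `[[`, "", "strand"),
    cds_start = vapply(recs, function(r) as.integer(r$cds_start), 0L),
    cds_end = vapply(recs, function(r) as.integer(r$cds_end), 0L),
    stringsAsFactors = FALSE
  )
  models$exon_starts <- I(lapply(recs, `[[`, "exon_starts"))
  models$exon_ends <- I(lapply(recs, `[[`, "exon_ends"))
  if (nrow(models) > 0) validate_gene_models(models)
  list(genome = Biostrings::DNAStringSet(seqs), models = models,
       chrom_sizes = chrom_sizes)
}

# Solve the latent-intensity mixing weight so that the expected Pearson
# correlation of Poisson counts X_r ~ Pois(w*mu + (1-w)*nu_r), nu_r an
# independent permutation of mu, equals rho:
#   rho = w^2 v / (m + v (w^2 + (1-w)^2)),   m = mean(mu), v = var(mu).
solve_mixture_weight <- function(rho, m, v) {
  if (rho >= v / (m + v)) {
    if (rho > v / (m + v) + 1e-9) {
      warning("target correlation ", rho, " exceeds the achievable maximum ",
              round(v / (m + v), 4), " for this intensity profile; using the ",
              "fully shared mixture")
    }
    return(1)
  }
  a <- v * (2 * rho - 1)
  b <- -2 * rho * v
  c0 <- rho * (m + v)
  if (abs(a) < 1e-12) return(sqrt(c0 / (2 * rho * v)))
  disc <- b^2 - 4 * a * c0
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  roots <- roots[roots >= 0 & roots <= 1]
  if (length(roots) == 0) return(1)
  max(roots)
}

#' Generate replicate ChIP peak and tag data with known truth
#'
#' Chooses a fraction of genes as bound and places one true binding site per
#' bound gene (in the promoter or the gene body) plus extra intergenic
#' sites.  Per-window tag intensities are a flat background plus a smoothing
#' kernel around each site; replicate counts are Poisson draws from a shared
#' latent intensity mixed with replicate-specific noise, with the mixing
#' weight solved analytically so the realized 200-bp-window Pearson
#' correlation approaches `rho` (at `rho = 1` with zero summit jitter the
#' two replicates are identical copies).  The consensus motif `WTTTAT` is
#' written into the genome sequence under each flagged summit.  Noise peaks
#' carry FDR above 1% so the standard peak filter removes them.
#'
#' @param gm output of [generate_genome()]
#' @param config `chip` block of [synthetic_config()]
#' @param seed master seed (fixed stream offset)
#' @return list with `peaks_rep1`, `peaks_rep2`, `tags_rep1`, `tags_rep2`,
#'   `genome` (motif-planted copy), `truth` (bound genes, true sites, motif
#'   flags, target rho)
#' @export
generate_chip <- function(gm, config = synthetic_config()$chip, seed = 1) {
  cc <- config
  if (cc$rho < 0 || cc$rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
  set.seed(seed + SEED_OFFSET_CHIP)
  models <- gm$models
  chrom_sizes <- gm$chrom_sizes
  genome_chr <- stats::setNames(as.character(gm$genome), names(gm$genome))

  n_bound <- round(cc$frac_genes_bound * nrow(models))
  bound_genes <- sort(sample(models$gene_id, n_bound))
  tss <- gene_tss(models)
  site_chrom <- character(0); site_pos <- integer(0); site_gene <- character(0)
  for (g in bound_genes) {
    i <- match(g, models$gene_id)
    if (stats::runif(1) < cc$promoter_site_prob) {
      off <- round(stats::runif(1, 200, 2000))
      pos <- if (models$strand[i] == "+") tss[i] - off else tss[i] + off
    } else {
      pos <- round(stats::runif(1, models$start[i] + 200, models$end[i] - 200))
    }
    site_chrom <- c(site_chrom, models$chrom[i])
    site_pos <- c(site_pos, as.integer(pos))
    site_gene <- c(site_gene, g)
  }
  # intergenic sites: centres of gaps left between the +/- 5 kb extended loci
  if (cc$n_intergenic_sites > 0) {
    centres_chrom <- character(0); centres_pos <- integer(0)
    for (chr in names(chrom_sizes)) {
      m <- models[models$chrom == chr, , drop = FALSE]
      s <- pmax(m$start - 5000L, 0L); e <- pmin(m$end + 5000L, chrom_sizes[[chr]])
      o <- order(s)
      gap_s <- c(0L, e[o]); gap_e <- c(s[o], chrom_sizes[[chr]])
      keep <- gap_e - gap_s >= 3000L
      mid <- as.integer((gap_s[keep] + gap_e[keep]) %/% 2L)
      centres_chrom <- c(centres_chrom, rep(chr, sum(keep)))
      centres_pos <- c(centres_pos, mid)
    }
    take <- sample(seq_along(centres_pos),
                   min(cc$n_intergenic_sites, length(centres_pos)))
    site_chrom <- c(site_chrom, centres_chrom[take])
    site_pos <- c(site_pos, centres_pos[take])
    site_gene <- c(site_gene, rep(NA_character_, length(take)))
  }
  n_sites <- length(site_pos)
  motif_planted <- stats::runif(n_sites) < cc$motif_prob
  for (j in which(motif_planted)) {
    w_letter <- sample(c("A", "T"), 1)
    motif <- paste0(w_letter, "TTTAT")
    p <- site_pos[j]
    if (p >= 3 && p + 3 <= chrom_sizes[[site_chrom[j]]]) {
      substr(genome_chr[[site_chrom[j]]], p - 2, p + 3) <- motif
    }
  }

  w <- cc$window_size
  kernel <- c(0.1, 0.2, 0.4, 0.2, 0.1)
  lambda <- lapply(names(chrom_sizes), function(chr) {
    rep(cc$background_rate, ceiling(chrom_sizes[[chr]] / w))
  })
  names(lambda) <- names(chrom_sizes)
  site_total <- stats::rgamma(n_sites, shape = cc$tags_per_site_shape,
                              scale = cc$tags_per_site_mean / cc$tags_per_site_shape)
  for (j in seq_len(n_sites)) {
    chr <- site_chrom[j]
    ctr <- site_pos[j] %/% w + 1L
    idx <- ctr + (-2:2)
    ok <- idx >= 1 & idx <= length(lambda[[chr]])
    lambda[[chr]][idx[ok]] <- lambda[[chr]][idx[ok]] + site_total[j] * kernel[ok]
  }
  mu <- unlist(lambda, use.names = FALSE)
  n_win <- length(mu)
  if (cc$rho == 1) {
    counts <- stats::rpois(n_win, mu)
    counts1 <- counts; counts2 <- counts
  } else {
    m <- mean(mu); v <- stats::var(mu)
    wmix <- solve_mixture_weight(cc$rho, m, v)
    lam1 <- wmix * mu + (1 - wmix) * mu[sample.int(n_win)]
    lam2 <- wmix * mu + (1 - wmix) * mu[sample.int(n_win)]
    counts1 <- stats::rpois(n_win, lam1)
    counts2 <- stats::rpois(n_win, lam2)
  }
  win_chrom <- rep(names(lambda), vapply(lambda, length, 0L))
  win_start <- unlist(lapply(lambda, function(l) (seq_along(l) - 1L) * w),
                      use.names = FALSE)
  place_tags <- function(counts) {
    nz <- which(counts > 0)
    chrom <- rep(win_chrom[nz], counts[nz])
    len_here <- pmin(win_start[nz] + w,
                     chrom_sizes[win_chrom[nz]]) - win_start[nz]
    pos <- unlist(lapply(seq_along(nz), function(k) {
      win_start[nz[k]] +
        sample.int(len_here[k], counts[nz[k]], replace = TRUE) - 1L
    }), use.names = FALSE)
    if (length(pos) == 0) {
      return(data.frame(chrom = character(0), pos = integer(0),
                        stringsAsFactors = FALSE))
    }
    o <- order(chrom, pos)
    data.frame(chrom = chrom[o], pos = as.integer(pos[o]),
               stringsAsFactors = FALSE)
  }
  tags_rep1 <- place_tags(counts1)
  tags_rep2 <- if (cc$rho == 1) tags_rep1 else place_tags(counts2)

  site_tag_count <- function(counts) {
    vapply(seq_len(n_sites), function(j) {
      chr <- site_chrom[j]
      base <- match(chr, names(lambda))
      off <- if (base > 1) {
        sum(vapply(lambda[seq_len(base - 1)], length, 0L))
      } else 0L
      ctr <- site_pos[j] %/% w + 1L
      idx <- ctr + (-2:2)
      idx <- idx[idx >= 1 & idx <= length(lambda[[chr]])]
      sum(counts[off + idx])
    }, 0L)
  }
  make_peaks <- function(rep_id, counts) {
    jit <- if (cc$summit_jitter_sd == 0) {
      rep(0L, n_sites)
    } else {
      as.integer(pmax(pmin(round(stats::rnorm(n_sites, 0, cc$summit_jitter_sd)),
                           50), -50))
    }
    summit <- site_pos + jit
    start <- pmax(summit - cc$peak_halfwidth, 0L)
    end <- pmin(summit + cc$peak_halfwidth, chrom_sizes[site_chrom])
    df <- data.frame(
      name = sprintf("r%d_p%03d", rep_id, seq_len(n_sites)),
      chrom = site_chrom, start = as.integer(start), end = as.integer(end),
      summit = as.integer(summit), score = round(site_total, 1),
      fdr = stats::runif(n_sites, 0, 0.0099),
      tags = site_tag_count(counts),
      stringsAsFactors = FALSE
    )
    if (cc$n_noise_peaks > 0) {
      chr <- sample(names(chrom_sizes), cc$n_noise_peaks, replace = TRUE)
      smt <- vapply(chr, function(ch) {
        as.integer(round(stats::runif(1, cc$peak_halfwidth,
                                      chrom_sizes[[ch]] - cc$peak_halfwidth)))
      }, 0L)
      noise <- data.frame(
        name = sprintf("r%d_noise%02d", rep_id, seq_len(cc$n_noise_peaks)),
        chrom = chr, start = smt - cc$peak_halfwidth,
        end = smt + cc$peak_halfwidth, summit = smt,
        score = round(stats::runif(cc$n_noise_peaks, 1, 5), 1),
        fdr = stats::runif(cc$n_noise_peaks, 0.02, 0.2),
        tags = 0L, stringsAsFactors = FALSE
      )
      df <- rbind(df, noise)
    }
    rownames(df) <- NULL
    df
  }
  peaks_rep1 <- make_peaks(1L, counts1)
  peaks_rep2 <- make_peaks(2L, counts2)
  if (cc$rho == 1 && cc$summit_jitter_sd == 0 && cc$n_noise_peaks == 0) {
    peaks_rep2[, -1] <- peaks_rep1[, -1]  # identical replicate geometry
  }
  truth <- list(
    bound_genes = bound_genes,
    true_sites = data.frame(chrom = site_chrom, summit = site_pos,
                            gene_id = site_gene, motif_planted = motif_planted,
                            stringsAsFactors = FALSE),
    inter_replicate_rho = cc$rho
  )
  list(peaks_rep1 = peaks_rep1, peaks_rep2 = peaks_rep2,
       tags_rep1 = tags_rep1, tags_rep2 = tags_rep2,
       genome = Biostrings::DNAStringSet(genome_chr), truth = truth)
}

#' Generate a two-condition expression matrix with planted fold changes
#'
#' Baselines are log-normal; a configurable fraction of bound genes and of
#' unbound genes independently carry planted signed fold changes of
#' magnitude `fc_min + Exp(fc_extra_rate)` (so `|FC| >= 1.5` by default),
#' applied to the induced-condition mean; samples are the condition mean
#' times multiplicative log-normal noise of coefficient of variation
#' `noise_cv` (zero noise reproduces the planted folds exactly).
#'
#' @param models gene-model table
#' @param bound_genes character vector of bound gene ids (from the ChIP
#'   truth); responsiveness is drawn independently inside and outside it
#' @param config `expression` block of [synthetic_config()]
#' @param seed master seed (fixed stream offset)
#' @return list with `table` (an `expression_table`, conditions `control` /
#'   `induced`) and `responsive_genes` (`data.frame` of planted gene_id,
#'   direction, fold_change)
#' @export
generate_expression <- function(models, bound_genes = character(0),
                                config = synthetic_config()$expression,
                                seed = 1) {
  ec <- config
  if (ec$noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  set.seed(seed + SEED_OFFSET_EXPRESSION)
  gene_ids <- models$gene_id
  n <- length(gene_ids)
  is_bound <- gene_ids %in% bound_genes
  resp <- (is_bound & stats::runif(n) < ec$frac_bound_responsive) |
    (!is_bound & stats::runif(n) < ec$frac_unbound_responsive)
  up <- resp & stats::runif(n) < ec$up_frac
  fc_mag <- ec$fc_min + stats::rexp(n, ec$fc_extra_rate)
  fc <- rep(1, n)
  fc[resp & up] <- fc_mag[resp & up]
  fc[resp & !up] <- -fc_mag[resp & !up]
  baseline <- stats::rlnorm(n, ec$baseline_meanlog, ec$baseline_sdlog)
  mean_ctrl <- baseline
  mean_ind <- ifelse(fc >= 1, baseline * fc, baseline / abs(fc))
  sdlog <- sqrt(log(1 + ec$noise_cv^2))
  n_samp <- 2L * ec$n_reps
  noise <- if (sdlog == 0) {
    matrix(1, n, n_samp)
  } else {
    matrix(stats::rlnorm(n * n_samp, -sdlog^2 / 2, sdlog), n, n_samp)
  }
  values <- cbind(matrix(rep(mean_ctrl, ec$n_reps), n, ec$n_reps),
                  matrix(rep(mean_ind, ec$n_reps), n, ec$n_reps)) * noise
  samples <- c(paste0("ctrl_", seq_len(ec$n_reps)),
               paste0("ind_", seq_len(ec$n_reps)))
  colnames(values) <- samples
  rownames(values) <- gene_ids
  conditions <- stats::setNames(rep(c("control", "induced"), each = ec$n_reps),
                                samples)
  responsive <- data.frame(
    gene_id = gene_ids[resp],
    direction = ifelse(up[resp], "up", "down"),
    fold_change = fc[resp],
    stringsAsFactors = FALSE
  )
  list(table = expression_table(values, conditions),
       responsive_genes = responsive)
}

#' Generate gene-set collections with one planted enriched set
#'
#' The planted set consists of the (truth) responsive genes plus a few
#' others, so over-representation analysis of a responsive or direct-target
#' study list should rank it first; the remaining sets are uniform random
#' draws from the gene universe.
#'
#' @param models gene-model table (defines the universe)
#' @param responsive_genes `data.frame` from [generate_expression()]
#' @param config `gene_sets` block of [synthetic_config()]
#' @param seed master seed (fixed stream offset)
#' @return a gene-set collection (see [gene_set_collection()]) whose first
#'   set is named `planted_process`
#' @export
generate_gene_sets <- function(models, responsive_genes,
                               config = synthetic_config()$gene_sets,
                               seed = 1) {
  gc_ <- config
  set.seed(seed + SEED_OFFSET_GENESETS)
  universe <- models$gene_id
  others <- setdiff(universe, responsive_genes$gene_id)
  planted <- c(responsive_genes$gene_id,
               sample(others, min(gc_$planted_extra, length(others))))
  sets <- list(planted_process = planted)
  for (i in seq_len(gc_$n_random_sets)) {
    sz <- min(sample(gc_$random_set_min:gc_$random_set_max, 1),
              length(universe))
    sets[[sprintf("random_set_%02d", i)]] <- sample(universe, sz)
  }
  gene_set_collection(sets, universe)
}

#' Generate the complete synthetic dataset
#'
#' Runs the genome, ChIP, expression and gene-set generators in order and
#' assembles the ground truth.  When `outdir` is given, every artifact is
#' also written in the plain-text formats the readers consume (FASTA,
#' BED12, BED peaks and tags, TSV expression, GMT, JSON truth).
#'
#' @param config full [synthetic_config()]
#' @param seed master seed
#' @param outdir optional output directory (created if needed)
#' @return list with `genome`, `models`, `chrom_sizes`, `peaks_rep1/2`,
#'   `tags_rep1/2`, `expression` (an `expression_table`), `gene_sets`, and
#'   `truth` (bound genes, responsive genes, their intersection
#'   `direct_targets`, true sites, motif flags, target rho)
#' @export
simulate_dataset <- function(config = synthetic_config(), seed = 1,
                             outdir = NULL) {
  gm <- generate_genome(config$genome, seed)
  chip <- generate_chip(gm, config$chip, seed)
  expr <- generate_expression(gm$models, chip$truth$bound_genes,
                              config$expression, seed)
  sets <- generate_gene_sets(gm$models, expr$responsive_genes,
                             config$gene_sets, seed)
  truth <- chip$truth
  truth$responsive_genes <- expr$responsive_genes
  truth$direct_targets <- sort(intersect(truth$bound_genes,
                                         expr$responsive_genes$gene_id))
  ds <- list(
    genome = chip$genome, models = gm$models, chrom_sizes = gm$chrom_sizes,
    peaks_rep1 = chip$peaks_rep1, peaks_rep2 = chip$peaks_rep2,
    tags_rep1 = chip$tags_rep1, tags_rep2 = chip$tags_rep2,
    expression = expr$table, gene_sets = sets, truth = truth, seed = seed
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(ds$genome, file.path(outdir, "genome.fa"))
    write_gene_models(ds$models, file.path(outdir, "genes.bed12"))
    write_chrom_sizes(ds$chrom_sizes, file.path(outdir, "chrom.sizes"))
    write_peaks(ds$peaks_rep1, file.path(outdir, "peaks_rep1.bed"))
    write_peaks(ds$peaks_rep2, file.path(outdir, "peaks_rep2.bed"))
    write_tags(ds$tags_rep1, file.path(outdir, "tags_rep1.bed"))
    write_tags(ds$tags_rep2, file.path(outdir, "tags_rep2.bed"))
    write_expression(ds$expression, file.path(outdir, "expression.tsv"))
    utils::write.table(
      data.frame(sample = colnames(ds$expression$values),
                 condition = as.character(ds$expression$conditions)),
      file.path(outdir, "conditions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_gmt(ds$gene_sets, file.path(outdir, "gene_sets.gmt"))
    jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  ds
}
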