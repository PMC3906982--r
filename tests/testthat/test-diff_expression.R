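# Signed fold change, per-gene ANOVA, and the responsive call.

test_that("signed fold change follows the magnitude >= 1 convention", {
  expect_equal(signed_fold_change(10, 15), 1.5)
  expect_equal(signed_fold_change(15, 10), -1.5)
  expect_equal(signed_fold_change(10, 10), 1.0)
  expect_error(signed_fold_change(0, 5), "positive")
})

test_that("a hair-below-threshold fold is not responsive", {
  # ratio 1.003 downward: clearly significant but below the 1.5 cutoff
  vals <- cbind(matrix(rep(1003, 6), 2, 3), matrix(rep(1000, 6), 2, 3))
  dimnames(vals) <- list(c("gA", "gB"), paste0("s", 1:6))
  et <- expression_table(vals, setNames(rep(c("control", "induced"), each = 3),
                                        paste0("s", 1:6)))
  de <- call_responsive(et)
  expect_equal(round(de$fold_change[1], 3), -1.003)
  expect_false(any(de$responsive))
})

test_that("two-group ANOVA p equals the pooled t-test closed form", {
  # intensities whose log2 values are (1,2,3) vs (4,5,6)
  p <- gene_anova_p(2^c(1, 2, 3), 2^c(4, 5, 6))
  expect_equal(p, 0.0213116411287567, tolerance = 1e-12)
  # label swap leaves p unchanged
  expect_equal(gene_anova_p(2^c(4, 5, 6), 2^c(1, 2, 3)), p)
})

test_that("ANOVA p orders group assignments exactly as the permutation test", {
  # within one dataset, treat each of the 20 assignments of the six values
  # to groups of three as the observed split: the parametric p must order
  # the splits exactly as the exact permutation p built from independently
  # computed pooled t statistics
  set.seed(404)
  splits <- utils::combn(6, 3)
  for (rep in 1:5) {
    vals <- 2^rnorm(6, 8, 1)
    tstat <- apply(splits, 2, function(idx) {
      x <- log2(vals[idx]); y <- log2(vals[-idx])
      sp <- sqrt((var(x) + var(y)) / 2)
      abs(mean(x) - mean(y)) / (sp * sqrt(2 / 3))
    })
    perm_p <- vapply(tstat, function(t0) mean(tstat >= t0 - 1e-12), 0)
    pa <- apply(splits, 2, function(idx) gene_anova_p(vals[idx], vals[-idx]))
    # whenever one split has the smaller permutation p it must also have
    # the smaller parametric p (ties in the discrete permutation p allowed)
    expect_true(all(!(outer(perm_p, perm_p, "<") & outer(pa, pa, ">="))))
  }
})

test_that("degenerate zero-variance groups resolve to p in {0, 1}", {
  expect_equal(gene_anova_p(c(16, 16, 16), c(16, 16, 16)), 1)
  expect_equal(gene_anova_p(c(16, 16, 16), c(32, 32, 32)), 0)
})

test_that("noiseless planted folds are recovered exactly by the call", {
  n_up <- 10; n_flat <- 90
  means <- c(rep(100, n_up + n_flat))
  ind <- c(rep(200, n_up), rep(100, n_flat))
  vals <- cbind(matrix(rep(means, 3), ncol = 3),
                matrix(rep(ind, 3), ncol = 3))
  dimnames(vals) <- list(sprintf("g%03d", 1:(n_up + n_flat)), paste0("s", 1:6))
  et <- expression_table(vals, setNames(rep(c("control", "induced"), each = 3),
                                        paste0("s", 1:6)))
  de <- call_responsive(et)
  expect_equal(sum(de$responsive), n_up)
  expect_true(all(de$direction[de$responsive] == "up"))
  # a planted 1.4-fold stays below the 1.5 cutoff; exactly 1.5 is included
  vals14 <- vals; vals14[1:n_up, 4:6] <- 140
  de14 <- call_responsive(expression_table(vals14, setNames(
    rep(c("control", "induced"), each = 3), paste0("s", 1:6))))
  expect_equal(sum(de14$responsive), 0)
  vals15 <- vals; vals15[1:n_up, 4:6] <- 150
  de15 <- call_responsive(expression_table(vals15, setNames(
    rep(c("control", "induced"), each = 3), paste0("s", 1:6))))
  expect_equal(sum(de15$responsive), n_up)
})

test_that("partition, threshold monotonicity and label antisymmetry hold", {
  set.seed(99)
  for (rep in 1:5) {
    vals <- matrix(2^rnorm(60 * 6, 8, 1), 60, 6,
                   dimnames = list(sprintf("g%02d", 1:60), paste0("s", 1:6)))
    cmap <- setNames(rep(c("control", "induced"), each = 3), paste0("s", 1:6))
    et <- expression_table(vals, cmap)
    de <- call_responsive(et, fc_threshold = 1.2, p_threshold = 0.2)
    s <- summarize_de(de)
    expect_equal(s$n_up + s$n_down, s$n_responsive)
    stricter <- call_responsive(et, fc_threshold = 1.5, p_threshold = 0.2)
    expect_lte(sum(stricter$responsive), s$n_responsive)
    lower_p <- call_responsive(et, fc_threshold = 1.2, p_threshold = 0.05)
    expect_lte(sum(lower_p$responsive), s$n_responsive)
    # swapping condition labels negates folds, preserves p
    swapped <- call_responsive(et, control = "induced",
                               fc_threshold = 1.2, p_threshold = 0.2)
    expect_equal(swapped$fold_change, -de$fold_change)
    expect_equal(swapped$p_value, de$p_value)
  }
})

test_that("responsive calls recover planted effects with high accuracy", {
  # noise CV 0.1, |FC| = 2, n = 3 per group: sensitivity and specificity
  # both above 0.9 pooled over 20 seeds
  tp <- fp <- fn <- tn <- 0
  for (s in 1:20) {
    set.seed(7000 + s)
    n <- 50
    planted <- rep(c(TRUE, FALSE), c(10, 40))
    base <- rlnorm(n, log(500), 0.5)
    ind_mean <- ifelse(planted, base * 2, base)
    sdlog <- sqrt(log(1 + 0.1^2))
    vals <- cbind(
      matrix(rlnorm(3 * n, log(rep(base, 3)) - sdlog^2 / 2, sdlog), n, 3),
      matrix(rlnorm(3 * n, log(rep(ind_mean, 3)) - sdlog^2 / 2, sdlog), n, 3))
    dimnames(vals) <- list(sprintf("g%02d", 1:n), paste0("s", 1:6))
    et <- expression_table(vals, setNames(
      rep(c("control", "induced"), each = 3), paste0("s", 1:6)))
    de <- call_responsive(et)
    tp <- tp + sum(de$responsive & planted)
    fn <- fn + sum(!de$responsive & planted)
    fp <- fp + sum(de$responsive & !planted)
    tn <- tn + sum(!de$responsive & !planted)
  }
  expect_gt(tp / (tp + fn), 0.9)  # sensitivity
  expect_gt(tn / (tn + fp), 0.9)  # specificity
})
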