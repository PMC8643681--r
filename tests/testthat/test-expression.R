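small_design <- function(...) {
  synthetic_expression_design(n_genes = 300, seed = 42, ...)
}

test_that("synthetic counts are seeded, labelled, and class-structured", {
  sim1 <- generate_synthetic_counts(small_design())
  sim2 <- generate_synthetic_counts(small_design())
  expect_identical(sim1, sim2)
  expect_equal(dim(sim1$counts), c(300L, 12L))
  expect_equal(as.vector(table(sim1$samples$strain)[c("Ag", "Y119F",
                                                      "gyrAB")]),
               rep(4L, 3))
  expect_equal(as.vector(table(sim1$truth$class)[c("burden_responsive",
                                                   "null",
                                                   "supercoiling_responsive")]),
               c(30L, 240L, 30L))
})

test_that("planted group means are recovered within sampling error", {
  design <- synthetic_expression_design(n_genes = 400, dispersion = 0.1,
                                        n_replicates = 4, seed = 8)
  sim <- generate_synthetic_counts(design)
  ag <- sim$counts[, sim$samples$strain == "Ag"]
  mu <- sim$truth$baseline_mean
  se <- sqrt((mu + design$dispersion * mu^2) / 4)
  z <- (rowMeans(ag) - mu) / se
  expect_gt(mean(abs(z) < 3), 0.95)
  # supercoiling-responsive genes shift only in gyrAB
  sc <- sim$truth$class == "supercoiling_responsive" & mu > 100
  gy <- rowMeans(sim$counts[, sim$samples$strain == "gyrAB"])
  yf <- rowMeans(sim$counts[, sim$samples$strain == "Y119F"])
  l2_gy <- log2(gy[sc] / rowMeans(ag)[sc])
  expect_gt(min(abs(l2_gy)), 1) # planted |log2FC| = 2
  expect_lt(max(abs(log2(yf[sc] / rowMeans(ag)[sc]))), 1)
})

test_that("zero effect size collapses all classes onto the null", {
  sim <- generate_synthetic_counts(small_design(effect_size_log2 = 0))
  tab <- simple_de_test(sim$counts, sim$samples, "Ag", "gyrAB")
  expect_lt(max(abs(tab$log2_fold_change), na.rm = TRUE), 1.5)
  expect_gt(min(tab$p_adjusted, na.rm = TRUE), 1e-4)
})

test_that("size factors match the DESeq2 median-of-ratios oracle", {
  design <- synthetic_expression_design(
    n_genes = 200, seed = 5,
    library_sizes = rep(c(1, 1.6, 0.7, 1.2), 3))
  sim <- generate_synthetic_counts(design)
  sf <- topogel:::size_factors_mor(sim$counts)
  oracle <- DESeq2::estimateSizeFactorsForMatrix(sim$counts)
  expect_equal(unname(sf), unname(oracle), tolerance = 1e-8)
})

test_that("a planted fold change is detected at high expression", {
  set.seed(9)
  g <- 200
  mu <- rep(500, g)
  counts <- cbind(
    matrix(rnbinom(g * 4, size = 10, mu = mu), ncol = 4),
    matrix(rnbinom(g * 4, size = 10, mu = c(mu[1] * 4, mu[-1])), ncol = 4))
  # gene 1 is 4-fold up in strain B
  colnames(counts) <- paste0(rep(c("A", "B"), each = 4), "_", 1:4)
  rownames(counts) <- sprintf("g%03d", seq_len(g))
  samples <- data.frame(sample = colnames(counts),
                        strain = rep(c("A", "B"), each = 4))
  tab <- simple_de_test(counts, samples, "A", "B")
  expect_equal(tab$log2_fold_change[1], 2, tolerance = 0.25)
  expect_lt(tab$p_adjusted[1], 0.05)
})

test_that("degenerate tables are handled: one gene, all-zero rows", {
  counts <- matrix(c(5L, 8L, 50L, 60L, 0L, 0L, 0L, 0L), nrow = 2,
                   byrow = TRUE,
                   dimnames = list(c("g1", "gz"),
                                   c("A_1", "A_2", "B_1", "B_2")))
  samples <- data.frame(sample = colnames(counts),
                        strain = rep(c("A", "B"), each = 2))
  tab <- simple_de_test(counts, samples, "A", "B")
  expect_true(tab$filtered[2])
  expect_true(is.na(tab$log2_fold_change[2]))
  # BH at m = 1 is the identity
  expect_equal(tab$p_adjusted[1], tab$p_value[1])
})

test_that("DEG filtering uses strict two-sided thresholds", {
  records <- data.frame(
    gene_id = paste0("g", 1:5),
    log2_fold_change = c(2.0, log2(1.25), -0.9, 0.1, -2.5),
    p_adjusted = c(0.001, 0.001, 0.02, 0.001, 0.05))
  # g2 sits exactly on the fold-change boundary, g5 on the padj boundary
  expect_equal(filter_degs(records), c("g1", "g3"))
  expect_equal(filter_degs(records, fc_threshold = 1e-9,
                           padj_threshold = 0.9999),
               c("g1", "g2", "g3", "g4", "g5"))
})

test_that("DEG filtering is monotone in both thresholds", {
  set.seed(12)
  records <- data.frame(gene_id = paste0("g", 1:200),
                        log2_fold_change = rnorm(200, sd = 1),
                        p_adjusted = runif(200))
  prev <- character(0)
  for (padj in c(0.01, 0.05, 0.2, 0.5)) {
    cur <- filter_degs(records, fc_threshold = 1.25, padj_threshold = padj)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  prev <- character(0)
  for (fc in c(2, 1.5, 1.25, 1.05)) {
    cur <- filter_degs(records, fc_threshold = fc)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("triple contrasts recover the planted SRG class", {
  sim <- generate_synthetic_counts(small_design())
  tables <- list(
    gyrAB_vs_Ag = simple_de_test(sim$counts, sim$samples, "Ag", "gyrAB"),
    Y119F_vs_Ag = simple_de_test(sim$counts, sim$samples, "Ag", "Y119F"),
    gyrAB_vs_Y119F = simple_de_test(sim$counts, sim$samples, "Y119F",
                                    "gyrAB"))
  res <- build_contrasts(tables)
  expect_s3_class(res, "contrast_result")
  expect_identical(res$srg_set, res$deg_sets$gyrAB_vs_Y119F)
  truth_sc <- sim$truth$gene_id[sim$truth$class == "supercoiling_responsive"]
  sens <- mean(truth_sc %in% res$srg_set)
  expect_gt(sens, 0.8)
  # burden genes cancel in the active-vs-dead comparison
  truth_b <- sim$truth$gene_id[sim$truth$class == "burden_responsive"]
  expect_gt(mean(truth_b %in% res$deg_sets$Y119F_vs_Ag), 0.8)
  expect_lt(mean(truth_b %in% res$srg_set), 0.2)
})

test_that("contrast set algebra handles edge cases", {
  empty <- data.frame(gene_id = character(0),
                      log2_fold_change = numeric(0),
                      p_adjusted = numeric(0))
  res <- build_contrasts(list(gyrAB_vs_Ag = empty, Y119F_vs_Ag = empty,
                              gyrAB_vs_Y119F = empty))
  expect_equal(lengths(res$deg_sets), c(gyrAB_vs_Ag = 0L, Y119F_vs_Ag = 0L,
                                        gyrAB_vs_Y119F = 0L))
  expect_equal(unname(res$overlap_counts), rep(0L, 4))

  one <- data.frame(gene_id = c("a", "b"),
                    log2_fold_change = c(2, -2),
                    p_adjusted = c(0.001, 0.001))
  res2 <- build_contrasts(list(gyrAB_vs_Ag = one, Y119F_vs_Ag = one,
                               gyrAB_vs_Y119F = one))
  expect_true(all(res2$overlap_counts == 2))

  other <- data.frame(gene_id = c("a", "c"),
                      log2_fold_change = c(2, -2),
                      p_adjusted = c(0.001, 0.001))
  expect_error(build_contrasts(list(gyrAB_vs_Ag = one, Y119F_vs_Ag = other,
                                    gyrAB_vs_Y119F = one)),
               "mismatched ids")
})

test_that("FPKM follows its definitional scaling laws", {
  expect_equal(fpkm(100, 1000, 1e6), 100)
  expect_equal(fpkm(0, 1000, 1e6), 0)
  counts <- c(10, 250, 3000)
  len <- c(500, 1500, 2400)
  expect_equal(fpkm(counts, len, 2e7), fpkm(counts, len, 1e7) / 2)
  expect_error(fpkm(10, 0, 1e6), "positive")
})

test_that("Z-score rows have mean zero and unit population SD", {
  expect_equal(zscore_rows(matrix(c(1, 2, 3), nrow = 1))[1, ],
               c(-1, 0, 1) * sqrt(3 / 2))
  set.seed(3)
  m <- matrix(rlnorm(60, 3, 1), nrow = 6)
  z <- zscore_rows(m)
  expect_true(all(abs(rowMeans(z)) <= 1e-12))
  expect_equal(sqrt(rowMeans((z - rowMeans(z))^2)), rep(1, 6))

  expect_warning(zc <- zscore_rows(rbind(m[1, ], rep(4, 10))), "constant")
  expect_equal(zc[2, ], rep(0, 10))
  expect_error(zscore_rows(matrix(1:3, ncol = 1)), "2 samples")
})

test_that("top-N anti-correlation counts sign-flipped genes", {
  set.seed(6)
  records <- data.frame(gene_id = paste0("g", 1:100),
                        log2_fold_change = sort(rnorm(100, sd = 2),
                                                decreasing = TRUE))
  flipped <- data.frame(gene_id = records$gene_id,
                        log2_fold_change = -records$log2_fold_change)
  expect_equal(top_n_anticorrelation(records, flipped,
                                     n = 30)$n_anticorrelated, 30)
  expect_equal(top_n_anticorrelation(records, records,
                                     n = 30)$n_anticorrelated, 0)
  # planted 26-of-30 sign flips
  ref <- flipped
  keep_pos <- paste0("g", c(2, 9, 17, 25))
  ref$log2_fold_change[ref$gene_id %in% keep_pos] <- 1
  out <- top_n_anticorrelation(records, ref, n = 30)
  expect_equal(out$n_anticorrelated, 26)
  expect_equal(out$n_evaluated, 30)
  # absent genes drop from numerator and denominator
  miss <- ref[!(ref$gene_id %in% paste0("g", 1:5)), ]
  out2 <- top_n_anticorrelation(records, miss, n = 30)
  expect_equal(out2$n_evaluated, 25)
  expect_equal(sort(out2$excluded), sort(paste0("g", 1:5)))
})
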