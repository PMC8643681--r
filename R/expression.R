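# Three-strain transcriptome logic: synthetic negative-binomial counts with
# planted gene classes, a simple internal differential-expression statistic,
# threshold filtering, triple-contrast set algebra for supercoiling-
# responsive gene (SRG) calling, and FPKM / Z-score transforms.

STRAINS <- c("Ag", "Y119F", "gyrAB")

#' Design of a synthetic three-strain expression experiment
#'
#' The generator emulates a three-strain comparison: a baseline strain
#' (`Ag`, empty vector), a strain bearing a catalytically dead enzyme
#' (`Y119F`, expression-burden effects only) and the active-enzyme strain
#' (`gyrAB`, burden plus supercoiling response). Three planted gene classes
#' drive the contrasts: supercoiling-responsive genes shift only in
#' `gyrAB`, burden-responsive genes shift equally in `Y119F` and `gyrAB`,
#' and null genes shift nowhere.
#'
#' @param n_genes Number of genes.
#' @param class_fractions Named fractions `supercoiling_responsive`,
#'   `burden_responsive`, `null`, summing to 1.
#' @param effect_size_log2 Absolute log2 fold change planted in responsive
#'   classes (direction drawn +/- with equal probability per gene).
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param n_replicates Biological replicates per strain (>= 2; default 4).
#' @param library_sizes Optional per-sample scaling factors (length
#'   `3 * n_replicates`); default all 1.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   gene means.
#' @param seed Integer seed.
#'
#' @return An object of class `synthetic_expression_design`.
#' @export
synthetic_expression_design <- function(n_genes = 1000,
                                        class_fractions = c(
                                          supercoiling_responsive = 0.1,
                                          burden_responsive = 0.1,
                                          null = 0.8),
                                        effect_size_log2 = 2,
                                        dispersion = 0.1,
                                        n_replicates = 4,
                                        library_sizes = NULL,
                                        baseline_meanlog = log(200),
                                        baseline_sdlog = 1,
                                        seed = 1L) {
  stopifnot(n_genes >= 1, n_genes == round(n_genes))
  req <- c("supercoiling_responsive", "burden_responsive", "null")
  if (!all(req %in% names(class_fractions)) ||
      any(class_fractions < 0) ||
      abs(sum(class_fractions) - 1) > 1e-8) {
    stop("'class_fractions' must be named fractions for ",
         paste(req, collapse = ", "), " summing to 1", call. = FALSE)
  }
  stopifnot(n_replicates >= 2, n_replicates == round(n_replicates))
  scalar_number(effect_size_log2, "effect_size_log2")
  scalar_number(dispersion, "dispersion", lower = 0, strict_lower = TRUE)
  n_samples <- 3L * as.integer(n_replicates)
  if (is.null(library_sizes)) library_sizes <- rep(1, n_samples)
  stopifnot(length(library_sizes) == n_samples, all(library_sizes > 0))
  structure(
    list(n_genes = as.integer(n_genes),
         class_fractions = class_fractions[req],
         effect_size_log2 = effect_size_log2,
         dispersion = dispersion,
         n_replicates = as.integer(n_replicates),
         library_sizes = library_sizes,
         baseline_meanlog = baseline_meanlog,
         baseline_sdlog = baseline_sdlog,
         seed = as.integer(seed)),
    class = "synthetic_expression_design"
  )
}

#' Generate a synthetic three-strain count matrix
#'
#' Draws negative-binomial counts for the three strains under the planted
#' class structure of a [synthetic_expression_design()], with ground-truth
#' labels. Deterministic given the design's seed.
#'
#' @param design A [synthetic_expression_design()].
#' @return A list with `counts` (genes x samples integer matrix), `samples`
#'   (data frame `sample`, `strain`) and `truth` (data frame `gene_id`,
#'   `class`, `direction`, `baseline_mean`).
#' @examples
#' sim <- generate_synthetic_counts(synthetic_expression_design(
#'   n_genes = 100, seed = 7))
#' table(sim$truth$class)
#' @export
generate_synthetic_counts <- function(design) {
  if (!inherits(design, "synthetic_expression_design")) {
    stop("expected a 'synthetic_expression_design' object", call. = FALSE)
  }
  g <- design$n_genes
  reps <- design$n_replicates
  n_per <- c(supercoiling_responsive = round(
               g * design$class_fractions[["supercoiling_responsive"]]),
             burden_responsive = round(
               g * design$class_fractions[["burden_responsive"]]))
  n_per <- c(n_per, null = g - sum(n_per))
  strain <- rep(STRAINS, each = reps)
  sample_id <- paste(strain, rep(seq_len(reps), times = 3), sep = "_")

  with_seed(design$seed, {
    cls <- sample(rep(names(n_per), times = n_per))
    mu0 <- stats::rlnorm(g, design$baseline_meanlog, design$baseline_sdlog)
    dir <- ifelse(cls == "null", 0, sample(c(-1, 1), g, replace = TRUE))
    fc <- 2^(dir * design$effect_size_log2)
    mu <- cbind(Ag = mu0,
                Y119F = ifelse(cls == "burden_responsive", mu0 * fc, mu0),
                gyrAB = ifelse(cls == "null", mu0, mu0 * fc))
    counts <- matrix(0L, nrow = g, ncol = length(sample_id),
                     dimnames = list(sprintf("gene_%04d", seq_len(g)),
                                     sample_id))
    for (j in seq_along(sample_id)) {
      counts[, j] <- stats::rnbinom(g, size = 1 / design$dispersion,
                                    mu = mu[, strain[j]] *
                                      design$library_sizes[j])
    }
    list(counts = counts,
         samples = data.frame(sample = sample_id, strain = strain),
         truth = data.frame(gene_id = rownames(counts), class = cls,
                            direction = dir, baseline_mean = mu0))
  })
}

# Median-of-ratios size factors (reference = per-gene geometric mean over
# all-positive genes).
size_factors_mor <- function(counts) {
  log_geo <- rowMeans(log(counts))
  ok <- is.finite(log_geo)
  if (!any(ok)) stop("no gene has positive counts in every sample",
                     call. = FALSE)
  apply(counts, 2, function(cnt) {
    exp(stats::median((log(cnt) - log_geo)[ok & cnt > 0]))
  })
}

#' Simple per-gene differential-expression statistic
#'
#' Deliberately simple internal statistic so the downstream set logic is
#' testable end-to-end: median-of-ratios normalization, log2 fold change of
#' normalized group means (0.5 pseudocount), and a two-sided
#' variance-moderated t statistic on `log2(normalized count + 1)` with
#' Benjamini-Hochberg adjustment. The per-gene pooled variance is shrunk
#' toward the across-gene median with `prior_df` prior degrees of freedom
#' (empirical-Bayes moderation in the style of limma), which restores power
#' at the small replicate numbers typical of these designs. It is not a
#' substitute for a full DE model on real data.
#'
#' @param counts Genes x samples count matrix.
#' @param samples Data frame with columns `sample`, `strain` matching
#'   `colnames(counts)`.
#' @param strain_a Reference strain (denominator of the fold change).
#' @param strain_b Test strain (numerator).
#' @param prior_df Prior degrees of freedom of the variance moderation
#'   (default 10).
#' @return A data frame of per-gene records: `gene_id`,
#'   `log2_fold_change`, `p_value`, `p_adjusted`, `mean_expression`
#'   (mean normalized count over both groups) and `filtered` (all-zero
#'   rows, excluded from testing).
#' @export
simple_de_test <- function(counts, samples, strain_a, strain_b,
                           prior_df = 10) {
  stopifnot(is.matrix(counts), is.data.frame(samples),
            all(c("sample", "strain") %in% names(samples)),
            identical(colnames(counts), samples$sample))
  for (s in c(strain_a, strain_b)) {
    if (sum(samples$strain == s) < 2L) {
      stop(sprintf("strain '%s' needs >= 2 replicates", s), call. = FALSE)
    }
  }
  sel <- samples$strain %in% c(strain_a, strain_b)
  sub <- counts[, sel, drop = FALSE]
  grp <- samples$strain[sel]
  sf <- size_factors_mor(sub)
  norm <- sweep(sub, 2, sf, "/")
  a <- norm[, grp == strain_a, drop = FALSE]
  b <- norm[, grp == strain_b, drop = FALSE]

  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  filtered <- rowSums(sub) == 0
  l2fc <- ifelse(filtered, NA_real_,
                 log2((mean_b + 0.5) / (mean_a + 0.5)))
  la <- log2(a + 1)
  lb <- log2(b + 1)
  na <- ncol(a)
  nb <- ncol(b)
  df_resid <- na + nb - 2
  pooled_var <- (apply(la, 1, stats::var) * (na - 1) +
                   apply(lb, 1, stats::var) * (nb - 1)) / df_resid
  prior_var <- stats::median(pooled_var[!filtered])
  mod_var <- (prior_df * prior_var + df_resid * pooled_var) /
    (prior_df + df_resid)
  tstat <- (rowMeans(lb) - rowMeans(la)) /
    sqrt(mod_var * (1 / na + 1 / nb))
  pval <- 2 * stats::pt(-abs(tstat), df = prior_df + df_resid)
  pval[filtered | !is.finite(pval)] <- NA_real_
  padj <- rep(NA_real_, length(pval))
  tested <- !is.na(pval)
  padj[tested] <- stats::p.adjust(pval[tested], method = "BH")
  data.frame(gene_id = rownames(counts),
             log2_fold_change = l2fc,
             p_value = pval,
             p_adjusted = padj,
             mean_expression = (mean_a + mean_b) / 2,
             filtered = filtered,
             row.names = NULL)
}

#' Filter differentially expressed genes by threshold
#'
#' Strict two-sided thresholds: a gene qualifies when
#' `p_adjusted < padj_threshold` and `|fold change| > fc_threshold`,
#' i.e. `|log2_fold_change| > log2(fc_threshold)`. Boundary genes are
#' excluded; untested genes (`NA`) never qualify.
#'
#' @param records Data frame of DE records with columns `gene_id`,
#'   `log2_fold_change`, `p_adjusted` (as from [simple_de_test()] or
#'   [read_de_table()]).
#' @param fc_threshold Fold-change threshold (> 1 scale; default 1.25).
#' @param padj_threshold Adjusted p-value threshold (default 0.05).
#' @return Character vector of qualifying gene ids.
#' @export
filter_degs <- function(records, fc_threshold = 1.25, padj_threshold = 0.05) {
  stopifnot(is.data.frame(records),
            all(c("gene_id", "log2_fold_change", "p_adjusted") %in%
                  names(records)))
  scalar_number(fc_threshold, "fc_threshold", lower = 0, strict_lower = TRUE)
  scalar_number(padj_threshold, "padj_threshold", lower = 0,
                strict_lower = TRUE)
  hit <- !is.na(records$p_adjusted) & !is.na(records$log2_fold_change) &
    records$p_adjusted < padj_threshold &
    abs(records$log2_fold_change) > log2(fc_threshold)
  records$gene_id[hit]
}

#' Triple-contrast set algebra and SRG calling
#'
#' Applies [filter_degs()] to the three pairwise strain comparisons and
#' assembles the supercoiling-responsive gene (SRG) set: the DEGs of the
#' active-versus-dead enzyme comparison (`gyrAB_vs_Y119F`), in which burden
#' effects cancel. All pairwise and triple overlaps are reported.
#'
#' @param tables Named list of three DE record tables with names
#'   `gyrAB_vs_Ag`, `Y119F_vs_Ag`, `gyrAB_vs_Y119F`; all tables must share
#'   one gene universe.
#' @param fc_threshold,padj_threshold Passed to [filter_degs()].
#' @return An object of class `contrast_result`: `deg_sets` (named list of
#'   gene-id vectors), `srg_set`, and `overlap_counts` (named integer
#'   vector of pairwise and triple intersection sizes).
#' @export
build_contrasts <- function(tables, fc_threshold = 1.25,
                            padj_threshold = 0.05) {
  req <- c("gyrAB_vs_Ag", "Y119F_vs_Ag", "gyrAB_vs_Y119F")
  if (!is.list(tables) || !all(req %in% names(tables))) {
    stop("'tables' must be a named list with elements ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  tables <- tables[req]
  universes <- lapply(tables, function(t) sort(t$gene_id))
  for (k in 2:3) {
    if (!identical(universes[[1]], universes[[k]])) {
      miss <- c(setdiff(universes[[1]], universes[[k]]),
                setdiff(universes[[k]], universes[[1]]))
      stop("gene universes differ between comparisons; mismatched ids: ",
           paste(utils::head(miss, 10), collapse = ", "), call. = FALSE)
    }
  }
  deg_sets <- lapply(tables, filter_degs, fc_threshold = fc_threshold,
                     padj_threshold = padj_threshold)
  ov <- c(
    "gyrAB_vs_Ag&Y119F_vs_Ag" =
      length(intersect(deg_sets$gyrAB_vs_Ag, deg_sets$Y119F_vs_Ag)),
    "gyrAB_vs_Ag&gyrAB_vs_Y119F" =
      length(intersect(deg_sets$gyrAB_vs_Ag, deg_sets$gyrAB_vs_Y119F)),
    "Y119F_vs_Ag&gyrAB_vs_Y119F" =
      length(intersect(deg_sets$Y119F_vs_Ag, deg_sets$gyrAB_vs_Y119F)),
    "all_three" = length(Reduce(intersect, deg_sets))
  )
  structure(list(deg_sets = deg_sets,
                 srg_set = deg_sets$gyrAB_vs_Y119F,
                 overlap_counts = ov),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("<contrast_result>\n")
  for (nm in names(x$deg_sets)) {
    cat(sprintf("  %-18s %d DEGs\n", nm, length(x$deg_sets[[nm]])))
  }
  cat(sprintf("  SRG set: %d genes\n", length(x$srg_set)))
  cat("  overlaps:", paste(names(x$overlap_counts), x$overlap_counts,
                           sep = " = ", collapse = "; "), "\n")
  invisible(x)
}

#' Fragments per kilobase of transcript per million mapped fragments
#'
#' `FPKM = counts * 1e9 / (gene_length_bp * total_mapped)`.
#'
#' @param counts Per-gene fragment counts (non-negative).
#' @param gene_length_bp Gene lengths in bp (> 0).
#' @param total_mapped Total mapped fragments in the library (> 0),
#'   supplied by the caller.
#' @return Per-gene FPKM values.
#' @examples
#' fpkm(100, 1000, 1e6) # 100
#' @export
fpkm <- function(counts, gene_length_bp, total_mapped) {
  stopifnot(is.numeric(counts), is.numeric(gene_length_bp),
            all(counts >= 0))
  if (any(gene_length_bp <= 0)) {
    stop("'gene_length_bp' must be positive", call. = FALSE)
  }
  scalar_number(total_mapped, "total_mapped", lower = 0, strict_lower = TRUE)
  counts * 1e9 / (gene_length_bp * total_mapped)
}

#' Z-score scaling of expression rows
#'
#' Centres each row (gene) to mean 0 and scales to standard deviation 1
#' using the population (n denominator) convention. Constant rows are
#' returned as all-zero with a warning.
#'
#' @param mat Numeric genes x samples matrix with >= 2 columns.
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (ncol(mat) < 2L) {
    stop("Z-score scaling needs at least 2 samples per row", call. = FALSE)
  }
  m <- rowMeans(mat)
  s <- sqrt(rowMeans((mat - m)^2))
  const <- s == 0
  if (any(const)) {
    warning(sum(const), " constant row(s) mapped to zeros", call. = FALSE)
    s[const] <- 1
  }
  out <- (mat - m) / s
  out[const, ] <- 0
  out
}

#' Count anti-correlated genes among the top-N upregulated set
#'
#' Takes the `n` genes of `records` with the largest log2 fold change and
#' counts how many have a negative log2 fold change in `reference`
#' (sign-opposition definition of anti-correlation). Genes absent from the
#' reference are excluded from numerator and denominator and reported.
#'
#' @param records DE records with `gene_id`, `log2_fold_change`.
#' @param reference Data frame with `gene_id`, `log2_fold_change` from the
#'   comparison dataset.
#' @param n Number of top upregulated genes to consider (default 30).
#' @return A list: `n_anticorrelated`, `n_evaluated`, `genes` (data frame
#'   with both fold changes and the anti-correlation flag), `excluded`
#'   (gene ids missing from the reference).
#' @export
top_n_anticorrelation <- function(records, reference, n = 30) {
  stopifnot(is.data.frame(records), is.data.frame(reference),
            all(c("gene_id", "log2_fold_change") %in% names(records)),
            all(c("gene_id", "log2_fold_change") %in% names(reference)),
            n >= 1)
  ord <- order(records$log2_fold_change, decreasing = TRUE)
  top <- utils::head(records[ord, c("gene_id", "log2_fold_change")], n)
  idx <- match(top$gene_id, reference$gene_id)
  excluded <- top$gene_id[is.na(idx)]
  kept <- !is.na(idx)
  genes <- data.frame(
    gene_id = top$gene_id[kept],
    log2_fold_change = top$log2_fold_change[kept],
    reference_log2_fold_change = reference$log2_fold_change[idx[kept]])
  genes$anticorrelated <- genes$reference_log2_fold_change < 0
  list(n_anticorrelated = sum(genes$anticorrelated),
       n_evaluated = nrow(genes),
       genes = genes,
       excluded = excluded)
}
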