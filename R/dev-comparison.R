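#' Rank-sum differential expression between two groups of cells
#'
#' Two-sided Wilcoxon rank-sum test on log-normalized expression, with
#' exact enumeration for small untied samples and the tie-corrected normal
#' approximation otherwise. The reported average log2 fold change is
#' computed on the normalized (de-logged) scale with a pseudocount:
#' `log2(mean(expm1(a)) + pc) - log2(mean(expm1(b)) + pc)`. Group `a` is
#' the older stage, so positive values indicate higher expression in the
#' older stage.
#'
#' @param cells_a Log-normalized expression in the older-stage cells.
#' @param cells_b Log-normalized expression in the younger-stage cells.
#' @param pseudocount Pseudocount `pc` on the normalized scale.
#' @param exact_max Largest group size for which the exact distribution is
#'   enumerated (ties force the normal approximation regardless).
#' @return Named numeric vector `c(avg_log2fc, p)`.
#' @export
wilcoxon_de <- function(cells_a, cells_b, pseudocount = 1, exact_max = 25) {
  if (length(cells_a) == 0 || length(cells_b) == 0) {
    stop2("both groups must contain at least one cell")
  }
  lfc <- log2(mean(expm1(cells_a)) + pseudocount) -
    log2(mean(expm1(cells_b)) + pseudocount)
  all_vals <- c(cells_a, cells_b)
  if (stats::sd(all_vals) == 0) {
    return(c(avg_log2fc = lfc, p = 1))
  }
  use_exact <- length(cells_a) <= exact_max &&
    length(cells_b) <= exact_max && !any(duplicated(all_vals))
  p <- suppressWarnings(
    stats::wilcox.test(cells_a, cells_b, exact = use_exact,
                       correct = TRUE)$p.value)
  c(avg_log2fc = lfc, p = p)
}

#' Differential-expression records for one neuron class across two stages
#'
#' Pipeline helper: merges the two stages' raw counts for one neuron
#' class, size-factor normalizes and log-transforms them jointly
#' (merge-then-normalize), runs [wilcoxon_de()] per gene, and assembles
#' the per-gene record with detection statistics and
#' Benjamini-Hochberg-adjusted p-values across genes within the class.
#'
#' @param counts_older,counts_younger Cell-by-gene raw count matrices for
#'   the class at each stage (shared gene columns).
#' @param neuron_class Class label stored in the records.
#' @param pseudocount Passed to [wilcoxon_de()].
#' @return data.frame with columns `gene`, `neuron_class`, `avg_log2fc`
#'   (positive = higher in the older stage), `p`, `p_adj`, `pct_older`,
#'   `pct_younger`, `n_detect_older`, `n_detect_younger`.
#' @export
de_records <- function(counts_older, counts_younger, neuron_class = "NA",
                       pseudocount = 1) {
  stopifnot(ncol(counts_older) == ncol(counts_younger))
  merged <- rbind(counts_older, counts_younger)
  norm <- log1p(size_factor_normalize(merged))
  ia <- seq_len(nrow(counts_older))
  ib <- nrow(counts_older) + seq_len(nrow(counts_younger))
  res <- t(vapply(seq_len(ncol(merged)), function(g) {
    wilcoxon_de(norm[ia, g], norm[ib, g], pseudocount = pseudocount)
  }, numeric(2)))
  data.frame(
    gene = colnames(merged),
    neuron_class = neuron_class,
    avg_log2fc = res[, 1],
    p = res[, 2],
    p_adj = stats::p.adjust(res[, 2], method = "BH"),
    pct_older = colMeans(counts_older > 0),
    pct_younger = colMeans(counts_younger > 0),
    n_detect_older = colSums(counts_older > 0),
    n_detect_younger = colSums(counts_younger > 0),
    row.names = NULL)
}

#' Filter differential-expression records by the four retention criteria
#'
#' Keeps records with adjusted p below 0.05, absolute average log2 fold
#' change of at least 1, detection in strictly more than 10% of the cells
#' of the higher-expressing stage, and detection in strictly more than 5
#' cells of the higher-expressing stage; records whose gene is on the
#' exclusion list are dropped.
#'
#' @param records data.frame of DE records (see [de_records()]).
#' @param exclusion Character vector of genes to drop (e.g. genes whose
#'   loci are overexpressed in reporter strains).
#' @param alpha Adjusted-p cutoff.
#' @param min_lfc Absolute log2 fold-change cutoff (inclusive).
#' @param min_pct Detection-fraction cutoff in the higher-expressing stage
#'   (strict).
#' @param min_cells Detected-cell cutoff in the higher-expressing stage
#'   (strict).
#' @return The retained subset of `records`.
#' @export
filter_de <- function(records, exclusion = character(), alpha = 0.05,
                      min_lfc = 1, min_pct = 0.10, min_cells = 5) {
  if (nrow(records) == 0) return(records)
  higher_pct <- ifelse(records$avg_log2fc >= 0,
                       records$pct_older, records$pct_younger)
  higher_n <- ifelse(records$avg_log2fc >= 0,
                     records$n_detect_older, records$n_detect_younger)
  keep <- records$p_adj < alpha &
    abs(records$avg_log2fc) >= min_lfc &
    higher_pct > min_pct &
    higher_n > min_cells &
    !(records$gene %in% exclusion)
  records[keep, , drop = FALSE]
}

#' Per-gene expression stability and Jaccard similarity across stages
#'
#' For each gene, stability is the fraction of classes expressing it at
#' the younger stage that still express it at the older stage:
#' `both / (both + only_young)`. The Jaccard index also penalizes gained
#' expression: `both / (both + only_young + only_old)`. Stability is
#' undefined (`NA`) when the gene is detected in no class at the younger
#' stage; Jaccard when it is detected at neither stage.
#'
#' @param bin_young,bin_old Gene-by-class binary matrices with identical
#'   class sets (restricted to classes present at both stages).
#' @return data.frame: `gene`, `stability`, `jaccard`, `n_both`,
#'   `n_only_young`, `n_only_old`.
#' @export
stability_jaccard <- function(bin_young, bin_old) {
  if (!identical(colnames(bin_young), colnames(bin_old))) {
    stop2("class sets must be identical (and identically ordered)")
  }
  genes <- intersect(rownames(bin_young), rownames(bin_old))
  y <- bin_young[genes, , drop = FALSE] > 0
  o <- bin_old[genes, , drop = FALSE] > 0
  both <- rowSums(y & o)
  only_y <- rowSums(y & !o)
  only_o <- rowSums(!y & o)
  data.frame(
    gene = genes,
    stability = ifelse(both + only_y > 0, both / (both + only_y), NA),
    jaccard = ifelse(both + only_y + only_o > 0,
                     both / (both + only_y + only_o), NA),
    n_both = both, n_only_young = only_y, n_only_old = only_o,
    row.names = NULL)
}

#' Fold enrichment of a query gene set in annotation categories
#'
#' `fold = (k/n) / (K/N)` where `k` of the `n` query genes and `K` of the
#' `N` background genes fall in the category. Significance is a one-sided
#' Fisher exact test for over-representation, Bonferroni-corrected across
#' the categories supplied in the call.
#'
#' @param k,n,K,N Integer vectors (recycled): query genes in category,
#'   query size, background genes in category, background size.
#' @return data.frame: `fold` (`NA` when `K = 0`), `p_fisher`, `p_bonf`.
#' @export
fold_enrichment <- function(k, n, K, N) {
  df <- data.frame(k = k, n = n, K = K, N = N)
  if (any(df$k > df$n | df$K > df$N | df$k > df$K | df$n > df$N)) {
    stop2("need k <= n, K <= N, k <= K, n <= N")
  }
  fold <- ifelse(df$K > 0, (df$k / df$n) / (df$K / df$N), NA)
  p <- vapply(seq_len(nrow(df)), function(i) {
    tab <- matrix(c(df$k[i], df$n[i] - df$k[i],
                    df$K[i] - df$k[i],
                    df$N[i] - df$n[i] - df$K[i] + df$k[i]), nrow = 2)
    stats::fisher.test(tab, alternative = "greater")$p.value
  }, numeric(1))
  data.frame(fold = fold, p_fisher = p,
             p_bonf = pmin(1, p * nrow(df)))
}

#' Genes broadly downregulated in early post-mitotic neurons
#'
#' Selects genes that are differentially expressed in strictly more than
#' `min_old` neuron classes in the older comparison (L1 vs L4) with at
#' least `frac` of those cases higher at the younger stage, and in
#' strictly more than `min_young` classes in the younger comparison
#' (embryo vs L1), again with at least `frac` higher at the younger stage.
#' Records must already have passed [filter_de()]. Records encode the
#' older stage as group `a`, so "higher at the younger stage" means a
#' negative `avg_log2fc`.
#'
#' @param de_old_pair Filtered records for the L1-vs-L4 comparison
#'   (older = L4).
#' @param de_young_pair Filtered records for the embryo-vs-L1 comparison
#'   (older = L1).
#' @param min_old,min_young Class-count cutoffs (strict `>`).
#' @param frac Minimum fraction of classes with higher expression at the
#'   younger stage (inclusive).
#' @return Character vector of selected genes.
#' @export
broad_downregulation <- function(de_old_pair, de_young_pair,
                                 min_old = 10, min_young = 40,
                                 frac = 0.75) {
  passes <- function(records, min_classes) {
    if (nrow(records) == 0) return(character())
    counts <- table(records$gene)
    down <- table(records$gene[records$avg_log2fc < 0])
    genes <- names(counts)[counts > min_classes]
    genes[vapply(genes, function(g) {
      d <- if (g %in% names(down)) down[[g]] else 0
      d / counts[[g]] >= frac
    }, logical(1))]
  }
  intersect(passes(de_old_pair, min_old),
            passes(de_young_pair, min_young))
}

#' Classify per-gene direction consistency across neuron classes
#'
#' Among genes differentially expressed in more than one class, a gene is
#' consistent when every class's fold change has the same sign, and mixed
#' otherwise. Single-class genes are excluded.
#'
#' @param records Filtered DE records.
#' @return data.frame: `gene`, `n_classes`, `direction` in
#'   `consistent_up` / `consistent_down` / `mixed`.
#' @export
direction_consistency <- function(records) {
  counts <- table(records$gene)
  multi <- names(counts)[counts > 1]
  dir <- vapply(multi, function(g) {
    s <- sign(records$avg_log2fc[records$gene == g])
    if (all(s > 0)) "consistent_up"
    else if (all(s < 0)) "consistent_down"
    else "mixed"
  }, character(1))
  data.frame(gene = multi, n_classes = as.integer(counts[multi]),
             direction = unname(dir), row.names = NULL)
}
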