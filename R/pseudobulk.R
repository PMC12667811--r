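#' Size-factor normalize single-cell UMI counts
#'
#' Each cell's size factor is its total UMI count divided by the geometric
#' mean of all cells' totals; counts are divided by the factor. The
#' geometric mean of the resulting factors is therefore 1.
#'
#' @param dataset A `single_cell_dataset`, or a bare cell-by-gene count
#'   matrix.
#' @return Cell-by-gene matrix of normalized counts.
#' @export
size_factor_normalize <- function(dataset) {
  counts <- if (inherits(dataset, "single_cell_dataset")) dataset$counts
            else dataset
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    bad <- rownames(counts)[totals == 0]
    stop2("cells with zero total UMI cannot be normalized: ",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  geo <- exp(mean(log(totals)))
  counts / (totals / geo)
}

#' Aggregate normalized single cells into a class-level pseudobulk profile
#'
#' For each neuron class the profile records (i) the detection proportion:
#' the fraction of cells in the class with at least one UMI for the gene,
#' and (ii) a TPM-scale value: the mean normalized expression across the
#' class's cells, rescaled so that each class column sums to 1,000,000.
#'
#' @param normalized Cell-by-gene matrix from [size_factor_normalize()].
#'   Entries are positive exactly where the raw count was at least 1, so
#'   detection is computed on raw detection status.
#' @param cell_class Per-cell class labels (length `nrow(normalized)`).
#' @return A list of class `pseudobulk_profile`: `proportion` and `tpm`
#'   (gene-by-class matrices) and `n_cells` (named per-class cell counts).
#' @export
aggregate_profiles <- function(normalized, cell_class) {
  stopifnot(nrow(normalized) == length(cell_class))
  classes <- unique(cell_class)
  if (any(table(cell_class) < 1)) stop2("every class needs >= 1 cell")
  genes <- colnames(normalized)
  prop <- tpm <- matrix(0, nrow = ncol(normalized), ncol = length(classes),
                        dimnames = list(genes, classes))
  n_cells <- integer(length(classes))
  names(n_cells) <- classes
  for (cl in classes) {
    rows <- which(cell_class == cl)
    n_cells[cl] <- length(rows)
    sub <- normalized[rows, , drop = FALSE]
    prop[, cl] <- colMeans(sub > 0)
    mu <- colMeans(sub)
    total <- sum(mu)
    tpm[, cl] <- if (total > 0) mu / total * 1e6 else 0
  }
  structure(list(proportion = prop, tpm = tpm, n_cells = n_cells),
            class = "pseudobulk_profile")
}

#' Prefilter genes before dynamic thresholding
#'
#' Genes detected above `ubiq_prop` in every class are retained as
#' ubiquitous and exempt from dynamic thresholding; genes detected below
#' `low_prop` in every class (and not ubiquitous) are removed as
#' unexpressed; the remainder proceed to thresholding. If a gene satisfies
#' both rules the ubiquitous rule wins and a warning is raised, since the
#' two bands are not expected to overlap in real data.
#'
#' @param profile A `pseudobulk_profile`.
#' @param ubiq_prop Ubiquitous rule: detection proportion strictly above
#'   this in every class.
#' @param low_prop Removal rule: detection proportion strictly below this
#'   in every class.
#' @return List of class `gene_prefilter` with character vectors
#'   `retained_ubiquitous`, `removed_low`, `to_threshold`.
#' @export
prefilter_genes <- function(profile, ubiq_prop = 0.01, low_prop = 0.02) {
  prop <- profile$proportion
  ubiq <- apply(prop, 1, function(x) all(x > ubiq_prop))
  low <- apply(prop, 1, function(x) all(x < low_prop))
  both <- ubiq & low
  if (any(both)) {
    warning(sum(both), " gene(s) satisfy both the ubiquitous and the ",
            "low-expression rule; keeping them as ubiquitous")
    low[both] <- FALSE
  }
  structure(list(retained_ubiquitous = rownames(prop)[ubiq],
                 removed_low = rownames(prop)[low & !ubiq],
                 to_threshold = rownames(prop)[!ubiq & !(low & !ubiq)]),
            class = "gene_prefilter")
}

## Binary expression calls implied by a dynamic-threshold fraction:
## detected at all, and detection proportion at or above the per-gene cutoff.
threshold_calls <- function(proportion, fraction) {
  cutoff <- fraction * apply(proportion, 1, max)
  (proportion > 0 & proportion >= cutoff) * 1L
}

#' Apply per-gene dynamic thresholds to a pseudobulk profile
#'
#' Each gene is considered individually: its cutoff is `fraction` times its
#' highest detection proportion across classes. TPM values are set to 0 in
#' classes where the detection proportion is strictly below the cutoff;
#' classes at or above the cutoff retain their continuous TPM. Ubiquitous
#' genes from the prefilter pass through unthresholded and removed genes
#' are zeroed everywhere.
#'
#' @param profile A `pseudobulk_profile`.
#' @param fraction Threshold fraction in `[0, 1]`.
#' @param prefilter Optional `gene_prefilter`; if `NULL` every gene is
#'   dynamically thresholded.
#' @return A list of class `thresholded_expression`: `tpm_thresholded`,
#'   `fraction`, `per_gene_cutoff` (named; `NA` for genes not dynamically
#'   thresholded), `retained_ubiquitous`, `removed_low`.
#' @export
dynamic_threshold <- function(profile, fraction, prefilter = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  prop <- profile$proportion
  genes <- rownames(prop)
  if (is.null(prefilter)) {
    prefilter <- list(retained_ubiquitous = character(),
                      removed_low = character(),
                      to_threshold = genes)
  }
  gene_set <- intersect(prefilter$to_threshold, genes)
  maxp <- apply(prop[gene_set, , drop = FALSE], 1, max)
  if (any(maxp == 0)) {
    stop2("gene(s) with maximum detection proportion 0 in the threshold ",
          "set (should have been prefiltered): ",
          paste(utils::head(gene_set[maxp == 0], 5), collapse = ", "))
  }
  cutoff <- stats::setNames(rep(NA_real_, length(genes)), genes)
  cutoff[gene_set] <- fraction * maxp
  tpm <- profile$tpm
  zero <- prop[gene_set, , drop = FALSE] <
    matrix(cutoff[gene_set], nrow = length(gene_set), ncol = ncol(prop))
  tpm[gene_set, ][zero] <- 0
  tpm[intersect(prefilter$removed_low, genes), ] <- 0
  structure(list(tpm_thresholded = tpm, fraction = fraction,
                 per_gene_cutoff = cutoff,
                 retained_ubiquitous = prefilter$retained_ubiquitous,
                 removed_low = prefilter$removed_low),
            class = "thresholded_expression")
}

#' Confusion rates of binary expression calls against a ground truth
#'
#' @param calls Gene-by-class binary matrix of calls.
#' @param truth Gene-by-class binary ground truth of identical shape.
#' @return Named numeric vector `c(tpr, fpr, fdr)` with
#'   `tpr = TP/(TP+FN)`, `fpr = FP/(FP+TN)` and `fdr = FP/(TP+FP)`, the
#'   latter defined as 0 when no positives are called.
#' @export
confusion_rates <- function(calls, truth) {
  if (!all(dim(calls) == dim(truth))) {
    stop2("calls and truth must have identical dimensions")
  }
  tp <- sum(calls == 1 & truth == 1)
  fp <- sum(calls == 1 & truth == 0)
  fn <- sum(calls == 0 & truth == 1)
  tn <- sum(calls == 0 & truth == 0)
  c(tpr = if (tp + fn > 0) tp / (tp + fn) else 0,
    fpr = if (fp + tn > 0) fp / (fp + tn) else 0,
    fdr = if (tp + fp > 0) fp / (tp + fp) else 0)
}

#' Default dynamic-threshold fraction grid
#'
#' 272 evenly spaced fractions on `[0, 1]` inclusive.
#' @return Numeric vector of length 272.
#' @export
default_fraction_grid <- function() seq(0, 1, length.out = 272)

#' Calibrate dynamic thresholds against a ground truth with BCa bootstraps
#'
#' For each candidate fraction, the thresholded detection calls on the
#' ground-truth genes are scored against the truth (TPR/FPR/FDR), and
#' confidence intervals are obtained from stratified bootstraps of the
#' ground-truth genes with the bias-corrected and accelerated (BCa)
#' percentile method. Strata are quartile bins of each gene's
#' positive-class fraction in the truth, so resamples preserve the mix of
#' broadly and narrowly expressed genes; bins with fewer than two genes
#' are merged with their neighbor.
#'
#' @param profile A `pseudobulk_profile` containing at least the truth
#'   genes.
#' @param truth Gene-by-class binary ground truth (classes must match the
#'   profile's).
#' @param fractions Numeric grid of threshold fractions.
#' @param n_boot Bootstrap replicates per fraction.
#' @param ci Confidence level.
#' @param seed Integer seed for the bootstrap resampling; point estimates
#'   do not depend on it.
#' @return data.frame of class `calibration_table` with one row per
#'   fraction: point rates and BCa interval bounds. When a rate is constant
#'   across bootstrap replicates its interval collapses to the point
#'   estimate.
#' @export
calibrate_thresholds <- function(profile, truth, fractions,
                                 n_boot = 5000, ci = 0.95, seed = 1L) {
  stopifnot(n_boot >= 2, length(fractions) >= 1)
  genes <- rownames(truth)
  if (!all(genes %in% rownames(profile$proportion))) {
    stop2("all ground-truth genes must be present in the profile")
  }
  if (!all(colnames(truth) == colnames(profile$proportion))) {
    stop2("truth and profile classes must match")
  }
  prop <- profile$proportion[genes, , drop = FALSE]

  pos_frac <- rowMeans(truth)
  strata <- make_strata(pos_frac)

  rows <- with_seed(seed, lapply(fractions, function(f) {
    calls <- threshold_calls(prop, f)
    point <- confusion_rates(calls, truth)
    stat <- function(d, idx) {
      confusion_rates(calls[idx, , drop = FALSE],
                      truth[idx, , drop = FALSE])
    }
    b <- boot::boot(seq_along(genes), stat, R = n_boot, strata = strata)
    cis <- vapply(1:3, function(k) bca_or_point(b, k, ci), numeric(2))
    data.frame(fraction = f,
               tpr = point["tpr"], fpr = point["fpr"], fdr = point["fdr"],
               tpr_ci_lo = cis[1, 1], tpr_ci_hi = cis[2, 1],
               fpr_ci_lo = cis[1, 2], fpr_ci_hi = cis[2, 2],
               fdr_ci_lo = cis[1, 3], fdr_ci_hi = cis[2, 3],
               row.names = NULL)
  }))
  out <- do.call(rbind, rows)
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  class(out) <- c("calibration_table", "data.frame")
  out
}

## Quartile bins of the positive-class fraction; merge bins of size < 2
## into the nearest nonempty neighbor.
make_strata <- function(pos_frac) {
  qs <- unique(stats::quantile(pos_frac, probs = c(0.25, 0.5, 0.75)))
  bins <- findInterval(pos_frac, qs, left.open = TRUE) + 1L
  repeat {
    counts <- table(bins)
    small <- names(counts)[counts < 2]
    if (length(small) == 0 || length(counts) == 1) break
    warning("bootstrap stratum with < 2 genes merged with its neighbor")
    s <- as.integer(small[1])
    others <- as.integer(names(counts)[names(counts) != small[1]])
    nearest <- others[which.min(abs(others - s))]
    bins[bins == s] <- nearest
  }
  factor(bins)
}

## BCa interval for statistic index k, collapsing to the point estimate
## when the bootstrap distribution is degenerate.
bca_or_point <- function(b, k, ci) {
  point <- b$t0[k]
  if (stats::var(b$t[, k]) < .Machine$double.eps) return(c(point, point))
  ## boot.ci warns when interval endpoints hit extreme order statistics at
  ## small R; the fallback endpoints are still valid for our use
  res <- tryCatch(suppressWarnings(
    boot::boot.ci(b, conf = ci, type = "bca", index = k)),
    error = function(e) NULL)
  if (is.null(res) || is.null(res$bca)) return(c(point, point))
  lim <- res$bca[1, 4:5]
  ## guard: BCa limits can numerically exclude the point in tiny samples
  c(min(lim[1], point), max(lim[2], point))
}

#' Select threshold fractions matching target rate triples
#'
#' For each target `(tpr, fpr, fdr)` triple, returns the grid fraction
#' whose point rates minimize the summed absolute deviation from the
#' target; ties break toward the smaller fraction.
#'
#' @param table A `calibration_table`.
#' @param target_rates data.frame (or coercible) with columns `tpr`,
#'   `fpr`, `fdr`, one row per target.
#' @return Numeric vector of selected fractions, one per target row.
#' @export
select_levels <- function(table, target_rates) {
  if (nrow(table) == 0) stop2("calibration table is empty")
  target_rates <- as.data.frame(target_rates)
  ord <- order(table$fraction)
  tab <- table[ord, ]
  vapply(seq_len(nrow(target_rates)), function(i) {
    dev <- abs(tab$tpr - target_rates$tpr[i]) +
      abs(tab$fpr - target_rates$fpr[i]) +
      abs(tab$fdr - target_rates$fdr[i])
    ## ties (to numerical precision) break toward the smaller fraction
    tab$fraction[which(dev <= min(dev) + 1e-9)[1]]
  }, numeric(1))
}
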