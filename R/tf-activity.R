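#' Transcription-factor activity from fold changes via a multivariate
#' linear model
#'
#' Regresses a neuron's per-gene log2 fold-change vector on all regulon
#' weight columns jointly (one column per transcription factor) plus an
#' intercept, by ordinary least squares. The activity score of a TF is the
#' t-statistic of its coefficient, with a two-sided p-value from the
#' residual-degrees-of-freedom t distribution. Collinear regulon columns
#' are dropped with a warning and the affected TFs reported as untested.
#'
#' @param logfc Named numeric vector of per-gene log2 fold changes; names
#'   must index rows of `regulons`.
#' @param regulons Gene-by-TF numeric weight matrix (0 = gene not in the
#'   TF's regulon).
#' @param neuron_class Label stored in the records.
#' @return data.frame: `tf`, `neuron_class`, `score`, `p`, `tested`. A
#'   zero-residual fit yields `score = 0, p = 1` for zero coefficients and
#'   an infinite score with `p = 0` otherwise.
#' @export
mlm_activity <- function(logfc, regulons, neuron_class = "NA") {
  regulons <- as.matrix(regulons)
  genes <- intersect(names(logfc), rownames(regulons))
  if (length(genes) == 0) stop2("logfc names must index regulon rows")
  X <- cbind(`(Intercept)` = 1, regulons[genes, , drop = FALSE])
  y <- logfc[genes]
  if (nrow(X) <= ncol(X)) {
    stop2("need more genes than TFs + 1 to fit the model")
  }
  qr_x <- qr(X)
  rank <- qr_x$rank
  kept <- qr_x$pivot[seq_len(rank)]
  dropped_tfs <- setdiff(colnames(X)[-kept], "(Intercept)")
  if (length(dropped_tfs) > 0) {
    warning("dropping collinear regulon column(s): ",
            paste(dropped_tfs, collapse = ", "))
  }
  Xk <- X[, kept, drop = FALSE]
  fit <- stats::lm.fit(Xk, y)
  df <- length(y) - rank
  rss <- sum(fit$residuals^2)
  coefs <- fit$coefficients
  ## unscaled coefficient variances from the R factor of the QR
  R <- qr.R(qr(Xk))
  XtX_inv <- chol2inv(R)
  se_unscaled <- sqrt(diag(XtX_inv))
  tol <- .Machine$double.eps^0.75 * max(1, sum(y^2))
  if (rss <= tol) {
    score <- ifelse(abs(coefs) < sqrt(.Machine$double.eps), 0,
                    sign(coefs) * Inf)
    p <- ifelse(score == 0, 1, 0)
  } else {
    sigma2 <- rss / df
    score <- coefs / (se_unscaled * sqrt(sigma2))
    p <- 2 * stats::pt(abs(score), df = df, lower.tail = FALSE)
  }
  tfs <- setdiff(colnames(X), "(Intercept)")
  out <- data.frame(tf = tfs, neuron_class = neuron_class,
                    score = NA_real_, p = NA_real_,
                    tested = !(tfs %in% dropped_tfs), row.names = NULL)
  tested_names <- setdiff(colnames(Xk), "(Intercept)")
  out$score[match(tested_names, out$tf)] <-
    score[match(tested_names, names(coefs))]
  out$p[match(tested_names, out$tf)] <-
    p[match(tested_names, names(coefs))]
  out
}

#' Filter TF activity records by significance and TF detection
#'
#' Keeps records whose Benjamini-Hochberg adjusted p (computed within each
#' neuron class across its tested TFs) is below `alpha` and whose TF
#' transcript was detected in that neuron at one or more of the compared
#' stages.
#'
#' @param records data.frame from [mlm_activity()] (possibly several
#'   neuron classes row-bound).
#' @param detection List of gene-by-class binary matrices, one per stage.
#' @param alpha Adjusted-p cutoff.
#' @return The significant subset, with columns `p_adj` and `detected`
#'   added.
#' @export
filter_activity <- function(records, detection, alpha = 0.05) {
  if (!is.list(detection)) detection <- list(detection)
  records$p_adj <- adjust_within(records$p, records$neuron_class)
  records$detected <- vapply(seq_len(nrow(records)), function(i) {
    tf <- records$tf[i]
    cl <- records$neuron_class[i]
    any(vapply(detection, function(d) {
      tf %in% rownames(d) && cl %in% colnames(d) && d[tf, cl] > 0
    }, logical(1)))
  }, logical(1))
  keep <- !is.na(records$p_adj) & records$p_adj < alpha & records$detected
  records[keep, , drop = FALSE]
}
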