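#' Per-cell maturation index from a 2-D embedding
#'
#' The maturation index of a cell is its Euclidean distance in embedding
#' space from a user-supplied baseline coordinate, chosen at the branch
#' point between the progenitor cluster and the post-mitotic cells. The
#' Manhattan distance is computed alongside for completeness but is not
#' used downstream.
#'
#' @param coords Cell-by-2 numeric matrix of embedding coordinates
#'   (rownames are cell ids).
#' @param baseline Length-2 numeric baseline coordinate.
#' @return List of class `maturation_result`: `index` (Euclidean distance,
#'   named per cell), `manhattan`, `baseline`.
#' @export
maturation_index <- function(coords, baseline) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, length(baseline) == 2)
  if (!all(is.finite(coords)) || !all(is.finite(baseline))) {
    stop2("coordinates must be finite")
  }
  dx <- coords[, 1] - baseline[1]
  dy <- coords[, 2] - baseline[2]
  structure(list(index = stats::setNames(sqrt(dx^2 + dy^2),
                                         rownames(coords)),
                 manhattan = stats::setNames(abs(dx) + abs(dy),
                                             rownames(coords)),
                 baseline = baseline),
            class = "maturation_result")
}

#' Correlate gene expression with the maturation index
#'
#' Pearson correlation of each gene's expression (log2 of normalized
#' expression plus one is the intended input scale) against the maturation
#' index within one post-mitotic cell class, with two-sided p-values and
#' Bonferroni correction across the genes tested. Genes with constant
#' expression have no defined correlation; they are reported with `NA` and
#' excluded from the Bonferroni denominator.
#'
#' @param expr Cell-by-gene expression matrix (cells must match
#'   `result$index`).
#' @param result A `maturation_result`.
#' @param alpha Significance level on the Bonferroni-adjusted p-value.
#' @return data.frame: `gene`, `r`, `p`, `p_bonf`, `significant`.
#' @export
correlate_with_maturation <- function(expr, result, alpha = 0.05) {
  stopifnot(inherits(result, "maturation_result"))
  expr <- as.matrix(expr)
  if (nrow(expr) < 3) stop2("need at least 3 cells to correlate")
  idx <- result$index
  if (nrow(expr) != length(idx)) stop2("expr rows must match indexed cells")
  n <- nrow(expr)
  sds <- apply(expr, 2, stats::sd)
  testable <- sds > 0 & stats::sd(idx) > 0
  r <- rep(NA_real_, ncol(expr))
  p <- rep(NA_real_, ncol(expr))
  r[testable] <- suppressWarnings(
    as.vector(stats::cor(expr[, testable, drop = FALSE], idx)))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p[testable] <- 2 * stats::pt(abs(tstat[testable]), df = n - 2,
                               lower.tail = FALSE)
  m <- sum(testable)
  p_bonf <- pmin(1, p * m)
  data.frame(gene = colnames(expr), r = r, p = p, p_bonf = p_bonf,
             significant = !is.na(p_bonf) & p_bonf < alpha,
             row.names = NULL)
}
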