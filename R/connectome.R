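#' Welch's unequal-variance two-sample t-test (closed form)
#'
#' Two-sided test with Welch-Satterthwaite degrees of freedom. When both
#' groups have zero variance the statistic is 0 with p 1 if the means are
#' equal, and infinite with p 0 otherwise; this keeps degenerate
#' expression patterns (e.g. a gene absent from both groups) well-defined.
#'
#' @param x,y Numeric vectors (each of length at least 2).
#' @return Named numeric vector `c(t, df, p)`.
#' @export
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop2("each group needs at least 2 observations")
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mx == my) return(c(t = 0, df = nx + ny - 2, p = 1))
    return(c(t = sign(mx - my) * Inf, df = nx + ny - 2, p = 0))
  }
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  c(t = t, df = df, p = 2 * stats::pt(abs(t), df = df, lower.tail = FALSE))
}

#' Collapse a cell-level adjacency matrix to neuron-class level
#'
#' Class-level entries are the sums of the member-cell entries of the
#' primary dataset (e.g. left/right homologs of a class are pooled). An
#' entry is retained only when the corresponding class-level entry is
#' nonzero in every confirmer dataset, suppressing connections not
#' reproduced across animals; with no confirmers this is pure summation.
#'
#' @param cell_matrices Named list of cell-by-cell nonnegative matrices,
#'   one per reconstruction dataset.
#' @param cell_to_class Named character vector mapping cell names to
#'   class names.
#' @param primary Name of the dataset whose counts are reported.
#' @param confirmers Names of datasets an edge must also appear in.
#' @return Class-by-class numeric matrix.
#' @export
collapse_connectome <- function(cell_matrices, cell_to_class, primary,
                                confirmers = character()) {
  collapse_one <- function(m) {
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      stop2("cell matrices must have dimnames")
    }
    bad <- setdiff(c(rownames(m), colnames(m)), names(cell_to_class))
    if (length(bad) > 0) {
      stop2("unmapped cell(s): ", paste(utils::head(bad, 5), collapse = ", "))
    }
    agg <- rowsum(m, cell_to_class[rownames(m)])
    t(rowsum(t(agg), cell_to_class[colnames(m)]))
  }
  out <- collapse_one(cell_matrices[[primary]])
  for (cf in confirmers) {
    conf <- collapse_one(cell_matrices[[cf]])
    shared_r <- intersect(rownames(out), rownames(conf))
    shared_c <- intersect(colnames(out), colnames(conf))
    mask <- matrix(0, nrow(out), ncol(out), dimnames = dimnames(out))
    mask[shared_r, shared_c] <-
      (conf[shared_r, shared_c, drop = FALSE] > 0) * 1
    out <- out * mask
  }
  out
}

#' Assemble a class-level connectome object
#'
#' Enforces the containment invariant that every synapse runs along a
#' membrane contact: synapse entries without a corresponding contact are
#' zeroed with a warning (this can happen when confirmer intersection
#' removes a contact but not the synapse).
#'
#' @param contact Class-by-class contact matrix (treated as undirected
#'   for grouping; symmetrized by elementwise max).
#' @param synapse Class-by-class directed synapse matrix (pre to post).
#' @param provenance Optional character vector of dataset ids.
#' @return List of class `class_connectome`.
#' @export
class_connectome <- function(contact, synapse, provenance = character()) {
  stopifnot(identical(dim(contact), dim(synapse)),
            identical(colnames(contact), colnames(synapse)))
  if (any(contact < 0) || any(synapse < 0)) stop2("negative entries")
  contact_sym <- pmax(contact, t(contact))
  orphan <- synapse > 0 & contact_sym == 0
  if (any(orphan)) {
    warning(sum(orphan), " synapse entr(ies) without membrane contact ",
            "set to 0")
    synapse[orphan] <- 0
  }
  structure(list(contact = contact_sym, synapse = synapse,
                 provenance = provenance),
            class = "class_connectome")
}

## Shared Welch/log2fc/BH machinery for contact and synaptic enrichment.
enrich_groups <- function(expr, genes, in_group, out_group, focal,
                          direction, pseudocount = 1e-5) {
  genes <- intersect(genes, rownames(expr))
  tested <- genes[rowSums(expr[genes, c(in_group, out_group),
                               drop = FALSE] > 0) > 0]
  ok <- length(in_group) >= 2 && length(out_group) >= 2
  rows <- lapply(tested, function(g) {
    xin <- expr[g, in_group]
    xout <- expr[g, out_group]
    w <- if (ok) welch_t(xin, xout) else c(t = NA, df = NA, p = NA)
    data.frame(gene = g, focal_neuron = focal, direction = direction,
               t_stat = w[["t"]], df = w[["df"]], p = w[["p"]],
               log2fc = log2((mean(xin) + pseudocount) /
                             (mean(xout) + pseudocount)),
               mean_in_group = mean(xin), mean_out_group = mean(xout),
               n_in_group = length(in_group),
               n_out_group = length(out_group),
               tested = ok, row.names = NULL)
  })
  out <- if (length(rows) > 0) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(gene = character(), focal_neuron = character(),
                      direction = character(), t_stat = numeric(),
                      df = numeric(), p = numeric(), log2fc = numeric(),
                      mean_in_group = numeric(),
                      mean_out_group = numeric(),
                      n_in_group = integer(), n_out_group = integer(),
                      tested = logical())
  }
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$has_expressed_partner <- rep(NA, nrow(out))
  out
}

#' Gene enrichment in classes contacting a focal neuron
#'
#' Splits all classes other than the focal neuron by whether they have
#' membrane contact with it, and Welch-tests each candidate gene's
#' per-class expression between the contacted and non-contacted groups.
#' Positive statistics indicate enrichment in contacted classes. Log2
#' fold changes use a 1e-5 pseudocount on the group means, and p-values
#' are Benjamini-Hochberg adjusted across the genes tested for this focal
#' neuron (genes expressed in no considered class are not tested).
#'
#' @param expr Thresholded gene-by-class TPM matrix.
#' @param connectome A `class_connectome`.
#' @param focal Focal class name.
#' @param cam_genes Candidate genes (cell-surface and secreted molecules).
#' @return data.frame of enrichment records (see [enrich_groups] fields).
#' @export
contact_enrichment <- function(expr, connectome, focal, cam_genes) {
  classes <- setdiff(colnames(connectome$contact), focal)
  contacted <- classes[connectome$contact[focal, classes] > 0]
  non_contacted <- setdiff(classes, contacted)
  enrich_groups(expr, cam_genes, contacted, non_contacted, focal,
                direction = "contact")
}

#' Gene enrichment in synaptic partners versus adjacent-only neighbors
#'
#' Among the classes contacting the focal neuron, compares each candidate
#' gene's expression in its synaptic partners (presynaptic inputs or
#' postsynaptic outputs, per `direction`) against the adjacent,
#' non-synaptic classes. The focal neuron is skipped entirely (empty
#' result, attribute `skipped = TRUE`) when it has fewer than
#' `min_partners` synaptic partners in the requested direction. Positive
#' statistics indicate enrichment in synaptic partners.
#'
#' @param expr Thresholded gene-by-class TPM matrix.
#' @param connectome A `class_connectome`.
#' @param focal Focal class name.
#' @param direction `"input"` (classes presynaptic to the focal neuron)
#'   or `"output"` (classes it synapses onto).
#' @param cam_genes Candidate genes.
#' @param min_partners Minimum synaptic partner count (default 3).
#' @return data.frame of enrichment records.
#' @export
synaptic_enrichment <- function(expr, connectome, focal,
                                direction = c("output", "input"),
                                cam_genes, min_partners = 3) {
  direction <- match.arg(direction)
  classes <- setdiff(colnames(connectome$contact), focal)
  contacted <- classes[connectome$contact[focal, classes] > 0]
  syn <- if (direction == "output") {
    classes[connectome$synapse[focal, classes] > 0]
  } else {
    classes[connectome$synapse[classes, focal] > 0]
  }
  syn <- intersect(syn, contacted)
  adjacent_only <- setdiff(contacted, syn)
  if (length(syn) < min_partners) {
    out <- enrich_groups(expr, character(), syn, adjacent_only, focal,
                         direction)
    attr(out, "skipped") <- TRUE
    return(out)
  }
  enrich_groups(expr, cam_genes, syn, adjacent_only, focal, direction)
}

#' Annotate enrichment records with expressed binding partners
#'
#' Marks each record according to whether any known protein-protein
#' interaction partner of its gene (including homophilic self-pairs) is
#' detected in the focal neuron.
#'
#' @param results Enrichment records from [contact_enrichment()] or
#'   [synaptic_enrichment()].
#' @param ppi data.frame of unordered interacting gene pairs, columns
#'   `gene_a`, `gene_b`.
#' @param expr_bin Gene-by-class binary expression matrix.
#' @return `results` with `has_expressed_partner` filled in.
#' @export
annotate_binding_partners <- function(results, ppi, expr_bin) {
  partners_of <- function(g) {
    unique(c(ppi$gene_b[ppi$gene_a == g], ppi$gene_a[ppi$gene_b == g]))
  }
  results$has_expressed_partner <-
    vapply(seq_len(nrow(results)), function(i) {
      p <- partners_of(results$gene[i])
      p <- p[p %in% rownames(expr_bin)]
      fc <- results$focal_neuron[i]
      length(p) > 0 && fc %in% colnames(expr_bin) &&
        any(expr_bin[p, fc] > 0)
    }, logical(1))
  results
}

#' Fractions of contacted classes that are synaptic partners
#'
#' For each class, among the classes it has membrane contact with, the
#' fraction that are synaptic partners at all, that receive its synaptic
#' output, and that provide it presynaptic input. Classes with no
#' contacts are undefined (`NA`) and excluded from the reported medians.
#'
#' @param connectome A `class_connectome`.
#' @return data.frame: `class`, `n_contacted`, `frac_any`, `frac_output`,
#'   `frac_input`; attribute `medians` holds the three medians.
#' @export
synapse_fraction_summary <- function(connectome) {
  classes <- colnames(connectome$contact)
  rows <- lapply(classes, function(cl) {
    others <- setdiff(classes, cl)
    contacted <- others[connectome$contact[cl, others] > 0]
    n <- length(contacted)
    if (n == 0) {
      return(data.frame(class = cl, n_contacted = 0L, frac_any = NA,
                        frac_output = NA, frac_input = NA))
    }
    out <- connectome$synapse[cl, contacted] > 0
    inp <- connectome$synapse[contacted, cl] > 0
    data.frame(class = cl, n_contacted = n,
               frac_any = mean(out | inp),
               frac_output = mean(out), frac_input = mean(inp))
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(res, "medians") <- c(
    frac_any = stats::median(res$frac_any, na.rm = TRUE),
    frac_output = stats::median(res$frac_output, na.rm = TRUE),
    frac_input = stats::median(res$frac_input, na.rm = TRUE))
  res
}
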