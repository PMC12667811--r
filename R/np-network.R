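#' Filter ligand-receptor interactions by potency and cross-stage expression
#'
#' Keeps neuropeptide-receptor pairs with in-vitro potency at or below
#' `max_ec50` (boundary inclusive) whose NPP and GPCR genes are each
#' detected in at least one neuron class at every supplied stage.
#'
#' @param table data.frame with columns `npp`, `gpcr`, `ec50_nM`.
#' @param expr_stages List of gene-by-class binary expression matrices,
#'   one per developmental stage.
#' @param max_ec50 Potency cutoff in nM (inclusive).
#' @return Retained subset of `table`.
#' @export
filter_interactions <- function(table, expr_stages, max_ec50 = 500) {
  stopifnot(all(c("npp", "gpcr", "ec50_nM") %in% colnames(table)))
  if (!is.list(expr_stages)) expr_stages <- list(expr_stages)
  expressed_everywhere <- function(gene) {
    all(vapply(expr_stages, function(e) {
      gene %in% rownames(e) && any(e[gene, ] > 0)
    }, logical(1)))
  }
  keep <- table$ec50_nM <= max_ec50 &
    vapply(table$npp, expressed_everywhere, logical(1)) &
    vapply(table$gpcr, expressed_everywhere, logical(1))
  table[keep, , drop = FALSE]
}

#' Build a class-level proximity (diffusion-range) matrix
#'
#' Short range allows signaling only within the same neuronal process
#' bundle; mid range allows it within the same anatomical area (head,
#' midbody, tail). The diagonal is always reachable.
#'
#' @param bundles Named character vector: process bundle per class.
#' @param regions Named character vector: region per class, values in
#'   `head` / `midbody` / `tail`.
#' @param range_mode `"short"` or `"mid"`.
#' @return List of class `proximity_matrix`: `reachable` (class-by-class
#'   binary), `range_mode`, `bundles`, `regions`.
#' @export
build_proximity <- function(bundles, regions, range_mode = c("mid", "short")) {
  range_mode <- match.arg(range_mode)
  classes <- names(bundles)
  if (is.null(classes) || is.null(names(regions))) {
    stop2("bundles and regions must be named by class")
  }
  if (!setequal(classes, names(regions))) {
    stop2("every class needs both a bundle and a region assignment")
  }
  regions <- regions[classes]
  if (anyNA(bundles) || anyNA(regions)) stop2("unassigned class")
  key <- if (range_mode == "short") bundles else regions
  reachable <- (outer(key, key, `==`)) * 1L
  diag(reachable) <- 1L
  dimnames(reachable) <- list(classes, classes)
  structure(list(reachable = reachable, range_mode = range_mode,
                 bundles = bundles, regions = regions),
            class = "proximity_matrix")
}

#' Build the binary signaling layer of one ligand-receptor pair
#'
#' The directed connection from class `i` to class `j` exists when `i`
#' expresses the neuropeptide precursor, `j` expresses the receptor, and
#' the two classes are within the proximity mask:
#' `A[i, j] = NPP[i] * GPCR[j] * reachable[i, j]`. Self-edges arise when
#' one class expresses both genes.
#'
#' @param expr_bin Gene-by-class binary expression matrix.
#' @param pair One-row data.frame (or list) with `npp`, `gpcr`, `ec50_nM`.
#' @param proximity A `proximity_matrix` over the same classes.
#' @return List of class `pair_layer`: `npp`, `gpcr`, `ec50_nM`,
#'   `adjacency` (class-by-class binary, sender rows).
#' @export
build_pair_network <- function(expr_bin, pair, proximity) {
  classes <- colnames(expr_bin)
  if (!all(c(pair$npp, pair$gpcr) %in% rownames(expr_bin))) {
    stop2("pair genes must be rows of the expression matrix")
  }
  if (!identical(classes, colnames(proximity$reachable))) {
    stop2("expression and proximity class sets must match")
  }
  adj <- outer(expr_bin[pair$npp, ] > 0, expr_bin[pair$gpcr, ] > 0) *
    proximity$reachable
  storage.mode(adj) <- "integer"
  structure(list(npp = pair$npp, gpcr = pair$gpcr,
                 ec50_nM = pair$ec50_nM, adjacency = adj),
            class = "pair_layer")
}

#' Aggregate pair layers into a weighted neuropeptide network
#'
#' The weighted adjacency is the elementwise sum of the layers' binary
#' adjacencies, so each weight counts the number of ligand-receptor pairs
#' connecting the two classes.
#'
#' @param layers List of `pair_layer` objects over a common class set.
#' @param stage Stage label.
#' @param classes Class set, required only when `layers` is empty (the
#'   result is then an all-zero network).
#' @return List of class `np_network`: `weighted`, `layers`, `stage`.
#' @export
aggregate_network <- function(layers, stage = "L1", classes = NULL) {
  if (length(layers) == 0) {
    if (is.null(classes)) stop2("classes must be given when layers is empty")
    weighted <- matrix(0L, length(classes), length(classes),
                       dimnames = list(classes, classes))
    return(structure(list(weighted = weighted, layers = layers,
                          stage = stage), class = "np_network"))
  }
  classes <- colnames(layers[[1]]$adjacency)
  for (l in layers) {
    if (!identical(colnames(l$adjacency), classes)) {
      stop2("layers must share one class set")
    }
  }
  weighted <- Reduce(`+`, lapply(layers, `[[`, "adjacency"))
  structure(list(weighted = weighted, layers = layers, stage = stage),
            class = "np_network")
}

#' Node degrees of a neuropeptide network
#'
#' Degrees are computed on the binarized directed network: in-degree is
#' the number of distinct sender classes, out-degree the number of
#' distinct receiver classes, and degree their sum.
#'
#' @param network An `np_network`.
#' @return data.frame: `class`, `in_degree`, `out_degree`, `degree`.
#' @export
np_degrees <- function(network) {
  b <- (network$weighted > 0) * 1L
  data.frame(class = colnames(b),
             in_degree = colSums(b),
             out_degree = rowSums(b),
             degree = colSums(b) + rowSums(b),
             row.names = NULL)
}

#' Classify the expression topology of a ligand-receptor pair
#'
#' Expression of each side is restricted when at most `cutoff` neurons
#' express it and broad otherwise; the four combinations define local
#' (both restricted), pervasive (both broad), broadcaster (restricted
#' ligand, broad receptor) and integrative (broad ligand, restricted
#' receptor) network topologies.
#'
#' @param expr_bin Gene-by-class binary expression matrix.
#' @param pair One-row data.frame or list with `npp` and `gpcr`.
#' @param cutoff Restricted/broad boundary (inclusive for restricted).
#' @param class_sizes Optional named vector of neurons per class; when
#'   supplied, expressing-neuron counts are summed class sizes, otherwise
#'   classes are counted directly.
#' @return Character scalar: `"local"`, `"pervasive"`, `"broadcaster"` or
#'   `"integrative"`.
#' @export
classify_topology <- function(expr_bin, pair, cutoff = 50,
                              class_sizes = NULL) {
  count_of <- function(gene) {
    on <- expr_bin[gene, ] > 0
    if (is.null(class_sizes)) sum(on)
    else sum(class_sizes[colnames(expr_bin)[on]])
  }
  npp_n <- count_of(pair$npp)
  gpcr_n <- count_of(pair$gpcr)
  npp_restricted <- npp_n <= cutoff
  gpcr_restricted <- gpcr_n <= cutoff
  if (npp_restricted && gpcr_restricted) "local"
  else if (!npp_restricted && !gpcr_restricted) "pervasive"
  else if (npp_restricted) "broadcaster"
  else "integrative"
}

#' Compare two stages' neuropeptide networks edge by edge
#'
#' Each ordered class pair in the union of the two binarized edge sets is
#' classified: `conserved_identical` (same ligand-receptor pair sets at
#' both stages), `conserved_shared` (at least one common pair, not all),
#' `conserved_different` (edge at both stages, no common pair), `a_only`
#' or `b_only`. The summary reports conserved fractions with per-stage
#' denominators (conserved edges over edges present in that stage).
#'
#' @param net_a,net_b `np_network` objects over identical class sets.
#' @return List of class `stage_comparison`: `edges` (data.frame `from`,
#'   `to`, `category`) and `summary` (named numeric: category counts,
#'   `conserved_frac_a`, `conserved_frac_b`).
#' @export
compare_stages <- function(net_a, net_b) {
  classes <- colnames(net_a$weighted)
  if (!identical(classes, colnames(net_b$weighted))) {
    stop2("networks must share an identical class set")
  }
  pair_sets <- function(net) {
    sets <- vector("list", length(classes)^2)
    dim(sets) <- c(length(classes), length(classes))
    for (l in net$layers) {
      idx <- which(l$adjacency > 0)
      key <- paste0(l$npp, "|", l$gpcr)
      for (i in idx) sets[[i]] <- c(sets[[i]], key)
    }
    sets
  }
  sa <- pair_sets(net_a)
  sb <- pair_sets(net_b)
  ea <- net_a$weighted > 0
  eb <- net_b$weighted > 0
  idx <- which(ea | eb)
  category <- vapply(idx, function(i) {
    if (ea[i] && eb[i]) {
      common <- intersect(sa[[i]], sb[[i]])
      if (setequal(sa[[i]], sb[[i]])) "conserved_identical"
      else if (length(common) > 0) "conserved_shared"
      else "conserved_different"
    } else if (ea[i]) "a_only" else "b_only"
  }, character(1))
  rowi <- ((idx - 1) %% length(classes)) + 1
  coli <- ((idx - 1) %/% length(classes)) + 1
  edges <- data.frame(from = classes[rowi], to = classes[coli],
                      category = category, row.names = NULL)
  conserved <- sum(startsWith(category, "conserved"))
  counts <- table(factor(category,
                         levels = c("conserved_identical",
                                    "conserved_shared",
                                    "conserved_different",
                                    "a_only", "b_only")))
  summary <- c(as.vector(counts),
               conserved_frac_a = if (sum(ea) > 0) conserved / sum(ea)
                                  else NA,
               conserved_frac_b = if (sum(eb) > 0) conserved / sum(eb)
                                  else NA)
  names(summary)[1:5] <- names(counts)
  structure(list(edges = edges, summary = summary),
            class = "stage_comparison")
}
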