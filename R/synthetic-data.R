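#' Simulation configuration for synthetic single-cell datasets
#'
#' Bundles the parameters of the count generator: the per-gene, per-class
#' detection probabilities, the negative-binomial expression model for
#' detected genes, and the log-normal library-size variation.
#'
#' @param n_classes Number of neuron classes.
#' @param cells_per_class Either a single integer (same for every class) or a
#'   vector of length `n_classes`.
#' @param n_genes Number of genes.
#' @param detection_prob Gene-by-class matrix of detection probabilities in
#'   `[0, 1]`. If `NULL`, probabilities are drawn uniformly at random (under
#'   `seed`) with a sparse-expression bias typical of low-UMI single-cell
#'   data.
#' @param nb_mean Mean UMI count per detected gene per cell, before
#'   library-size scaling.
#' @param nb_dispersion Negative-binomial dispersion (`size` parameter of
#'   [stats::rnbinom()]; smaller means more overdispersed).
#' @param libsize_sigma Standard deviation of the log-normal per-cell library
#'   scaling factor (0 disables library-size variation).
#' @param seed Integer seed controlling every random draw downstream.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_classes, cells_per_class, n_genes,
                       detection_prob = NULL,
                       nb_mean = 2, nb_dispersion = 1,
                       libsize_sigma = 0.3, seed = 1L) {
  stopifnot(n_classes >= 1, n_genes >= 1, nb_mean > 0, nb_dispersion > 0,
            libsize_sigma >= 0)
  if (length(cells_per_class) == 1L) {
    cells_per_class <- rep(as.integer(cells_per_class), n_classes)
  }
  if (length(cells_per_class) != n_classes) {
    stop2("cells_per_class must have length 1 or n_classes")
  }
  if (any(cells_per_class < 1)) stop2("cells_per_class must be positive")
  classes <- sprintf("class%02d", seq_len(n_classes))
  genes <- sprintf("gene%04d", seq_len(n_genes))
  if (is.null(detection_prob)) {
    detection_prob <- with_seed(seed, {
      ## beta(0.3, 1) biases mass toward low detection, the common case
      matrix(stats::rbeta(n_genes * n_classes, 0.3, 1),
             nrow = n_genes, ncol = n_classes)
    })
    dimnames(detection_prob) <- list(genes, classes)
  } else {
    if (!all(dim(detection_prob) == c(n_genes, n_classes))) {
      stop2("detection_prob must be n_genes x n_classes")
    }
    if (any(detection_prob < 0 | detection_prob > 1)) {
      stop2("detection probabilities must lie in [0, 1]")
    }
    if (is.null(rownames(detection_prob))) rownames(detection_prob) <- genes
    if (is.null(colnames(detection_prob))) colnames(detection_prob) <- classes
  }
  structure(
    list(n_classes = n_classes, cells_per_class = cells_per_class,
         n_genes = n_genes, detection_prob = detection_prob,
         nb_mean = nb_mean, nb_dispersion = nb_dispersion,
         libsize_sigma = libsize_sigma, seed = as.integer(seed),
         classes = colnames(detection_prob),
         genes = rownames(detection_prob)),
    class = "sim_config")
}

#' Generate a synthetic single-cell UMI count dataset
#'
#' Counts follow a hurdle model: gene `g` is detected in a cell of class `c`
#' with probability `detection_prob[g, c]`; detected entries draw a
#' zero-truncated negative binomial whose mean is scaled by a per-cell
#' log-normal library factor. Detection status is therefore exactly
#' Bernoulli in the planted probability, which is what the thresholding
#' calibration assumes.
#'
#' @param config A [sim_config()] object.
#' @param stage Stage label attached to every cell (e.g. `"L1"`).
#' @param sample_id Batch label attached to every cell.
#'
#' @return A list of class `single_cell_dataset` with elements `counts`
#'   (cell-by-gene integer matrix), `cell_class`, `cell_stage`, `sample_id`.
#' @export
generate_counts <- function(config, stage = "L1", sample_id = "sim1") {
  stopifnot(inherits(config, "sim_config"))
  n_cells <- sum(config$cells_per_class)
  cell_class <- rep(config$classes, times = config$cells_per_class)
  with_seed(config$seed, {
    lib <- if (config$libsize_sigma > 0) {
      exp(stats::rnorm(n_cells, -config$libsize_sigma^2 / 2,
                       config$libsize_sigma))
    } else rep(1, n_cells)
    counts <- matrix(0L, nrow = n_cells, ncol = config$n_genes,
                     dimnames = list(sprintf("cell%05d", seq_len(n_cells)),
                                     config$genes))
    for (ci in seq_along(config$classes)) {
      rows <- which(cell_class == config$classes[ci])
      p <- config$detection_prob[, ci]
      on <- matrix(stats::runif(length(rows) * config$n_genes),
                   nrow = length(rows)) < rep(p, each = length(rows))
      if (!any(on)) next
      mu <- config$nb_mean * lib[rows][row(on)[on]]
      ## zero-truncated NB via inverse CDF above the zero mass
      p0 <- stats::pnbinom(0, size = config$nb_dispersion, mu = mu)
      u <- p0 + stats::runif(length(mu)) * (1 - p0)
      counts[rows, ][on] <- as.integer(
        stats::qnbinom(pmin(u, 1 - 1e-12), size = config$nb_dispersion,
                       mu = mu))
    }
    structure(list(counts = counts,
                   cell_class = cell_class,
                   cell_stage = rep(stage, n_cells),
                   sample_id = rep(sample_id, n_cells)),
              class = "single_cell_dataset")
  })
}

#' Generate a binary ground-truth expression matrix
#'
#' An entry is 1 exactly when the planted detection probability is at or
#' above `p_on` (boundary inclusive), restricted to a designated subset of
#' ground-truth genes. Plays the role of a curated known-expression matrix
#' for scoring thresholding accuracy.
#'
#' @param config A [sim_config()] object.
#' @param p_on Detection-probability cutoff in `(0, 1)` defining "truly
#'   expressed".
#' @param genes Genes to include (default: all genes in `config`).
#'
#' @return Binary gene-by-class integer matrix.
#' @export
generate_ground_truth <- function(config, p_on, genes = NULL) {
  stopifnot(inherits(config, "sim_config"), p_on > 0, p_on < 1)
  if (is.null(genes)) genes <- config$genes
  truth <- (config$detection_prob[genes, , drop = FALSE] >= p_on) * 1L
  storage.mode(truth) <- "integer"
  truth
}

#' Generate a branch-structured 2-D embedding with planted maturation trends
#'
#' Emulates the geometry of a dimensionality-reduced lineage: a progenitor
#' cluster near the origin, with branches radiating outward so that distance
#' from the branch point tracks maturation. A subset of genes is planted
#' with expression linear (plus Gaussian noise) in the true distance, with a
#' recorded sign, on one branch each.
#'
#' @param n_branches Number of post-mitotic branches (>= 1).
#' @param cells_per_branch Cells per branch (the progenitor cluster gets the
#'   same number).
#' @param n_genes Total genes in the accompanying expression matrix.
#' @param n_planted Number of genes planted with a maturation trend.
#' @param noise_sd Gaussian noise SD added to planted expression.
#' @param slope Absolute expression change per unit of true distance.
#' @param max_distance Maximal planted true distance along a branch.
#' @param seed Integer seed.
#'
#' @return A list of class `embedded_lineage`: `coords` (cell x 2),
#'   `branch_id`, `true_distance`, `planted_genes` (data.frame gene, branch,
#'   sign), and `expression` (cell-by-gene log-scale matrix).
#' @export
generate_lineage <- function(n_branches, cells_per_branch, n_genes = 100,
                             n_planted = 10, noise_sd = 0.5, slope = 1,
                             max_distance = 5, seed = 1L) {
  stopifnot(n_branches >= 1, cells_per_branch >= 1, n_planted <= n_genes)
  with_seed(seed, {
    branches <- sprintf("branch%d", seq_len(n_branches))
    n_cells <- cells_per_branch * (n_branches + 1)
    branch_id <- c(rep("progenitor", cells_per_branch),
                   rep(branches, each = cells_per_branch))
    true_distance <- c(rep(0, cells_per_branch),
                       stats::runif(cells_per_branch * n_branches,
                                    0, max_distance))
    angle <- 2 * pi * (match(branch_id, branches) - 1) / n_branches
    angle[branch_id == "progenitor"] <- 0
    jitter <- matrix(stats::rnorm(2 * n_cells, 0, 0.05), ncol = 2)
    coords <- cbind(x = true_distance * cos(angle),
                    y = true_distance * sin(angle)) + jitter
    rownames(coords) <- sprintf("cell%05d", seq_len(n_cells))
    genes <- sprintf("gene%04d", seq_len(n_genes))
    planted <- data.frame(
      gene = genes[seq_len(n_planted)],
      branch = branches[1 + (seq_len(n_planted) - 1) %% n_branches],
      sign = ifelse(seq_len(n_planted) %% 2 == 0, -1, 1))
    expr <- matrix(stats::rnorm(n_cells * n_genes, 0, max(noise_sd, 1e-8)),
                   nrow = n_cells, dimnames = list(rownames(coords), genes))
    if (noise_sd == 0) expr[] <- 0
    base <- slope * max_distance  # keep downregulated genes nonnegative-ish
    for (k in seq_len(nrow(planted))) {
      rows <- which(branch_id %in% c("progenitor", planted$branch[k]))
      expr[rows, planted$gene[k]] <- expr[rows, planted$gene[k]] + base +
        planted$sign[k] * slope * true_distance[rows]
    }
    lineage <- structure(
      list(coords = coords, branch_id = branch_id,
           true_distance = true_distance, planted_genes = planted,
           expression = expr),
      class = "embedded_lineage")
    dataset <- structure(
      list(counts = NULL, cell_class = branch_id,
           cell_stage = rep("L1", n_cells),
           sample_id = rep("sim1", n_cells)),
      class = "single_cell_dataset")
    list(lineage = lineage, dataset = dataset)
  })
}

#' Generate a synthetic ligand-receptor interaction table
#'
#' Rows pair a neuropeptide precursor (NPP) gene with a GPCR gene and carry
#' an in-vitro potency (EC50, nM). A fraction of pairs is high potency
#' (EC50 at or below 500 nM), matching the cutoff used when building
#' signaling networks.
#'
#' @param n_npp Number of NPP genes.
#' @param n_gpcr Number of GPCR genes.
#' @param pairs_per_npp Interactions drawn per NPP gene.
#' @param frac_high_potency Probability that a pair is high potency.
#' @param seed Integer seed.
#'
#' @return data.frame with columns `npp`, `gpcr`, `ec50_nM`.
#' @export
generate_interactions <- function(n_npp, n_gpcr, pairs_per_npp = 1,
                                  frac_high_potency = 0.6, seed = 1L) {
  stopifnot(n_npp >= 1, n_gpcr >= 1, pairs_per_npp >= 1)
  with_seed(seed, {
    npp <- rep(sprintf("npp%02d", seq_len(n_npp)), each = pairs_per_npp)
    gpcr <- sprintf("gpcr%02d",
                    unlist(lapply(seq_len(n_npp), function(i)
                      sample.int(n_gpcr, pairs_per_npp,
                                 replace = pairs_per_npp > n_gpcr))))
    high <- stats::runif(length(npp)) < frac_high_potency
    ec50 <- ifelse(high, stats::runif(length(npp), 1, 500),
                   stats::runif(length(npp), 501, 5000))
    data.frame(npp = npp, gpcr = gpcr, ec50_nM = ec50)
  })
}

#' Generate a synthetic class-level connectome with planted gene enrichment
#'
#' Assigns each neuron class to one process bundle and one body region
#' (bundles nest within regions, so short-range reachability implies
#' mid-range), draws a symmetric membrane-contact graph, overlays a directed
#' synapse graph as a subset of contacts, and plants expression shifts for
#' designated genes in the synaptic-partner sets of designated focal
#' classes. The planted truth is recorded so recovery can be scored.
#'
#' @param classes Character vector of neuron-class names.
#' @param n_bundles Number of process bundles.
#' @param contact_density Probability that an unordered class pair is in
#'   membrane contact.
#' @param synapse_frac Probability that a contact edge carries a directed
#'   synapse (each direction drawn independently).
#' @param planted_genes Character vector of genes to plant (may be empty).
#' @param effect Expression shift (log-scale units) added in the synaptic
#'   partner set of the focal class; 0 plants nothing.
#' @param n_genes Total genes in the synthetic expression matrix.
#' @param direction Which partner set carries the planted shift: classes
#'   receiving `"output"` from, or providing `"input"` to, the focal class.
#' @param seed Integer seed.
#'
#' @return A list of class `synthetic_connectome`: `bundles`, `regions`
#'   (named per class), `contact` and `synapse` (class-by-class matrices),
#'   `expression` (gene-by-class, log-scale), and `planted` (data.frame
#'   gene, focal, direction, effect).
#' @export
generate_connectome <- function(classes, n_bundles = 3,
                                contact_density = 0.4, synapse_frac = 0.3,
                                planted_genes = character(), effect = 0,
                                n_genes = 50, direction = "output",
                                seed = 1L) {
  stopifnot(synapse_frac <= 1, synapse_frac >= 0, effect >= 0,
            direction %in% c("input", "output"))
  n <- length(classes)
  with_seed(seed, {
    bundles <- sprintf("bundle%02d", sample.int(n_bundles, n, replace = TRUE))
    names(bundles) <- classes
    region_of_bundle <- sample(c("head", "midbody", "tail"),
                               n_bundles, replace = TRUE)
    names(region_of_bundle) <- sprintf("bundle%02d", seq_len(n_bundles))
    regions <- region_of_bundle[bundles]
    names(regions) <- classes

    contact <- matrix(0L, n, n, dimnames = list(classes, classes))
    upper <- which(upper.tri(contact))
    hit <- upper[stats::runif(length(upper)) < contact_density]
    contact[hit] <- 1L
    contact <- contact + t(contact)

    synapse <- matrix(0L, n, n, dimnames = list(classes, classes))
    idx <- which(contact > 0)  # both orientations of each contact
    syn <- idx[stats::runif(length(idx)) < synapse_frac]
    synapse[syn] <- 1L

    genes <- if (n_genes >= 1) sprintf("cam%03d", seq_len(n_genes))
             else character()
    expression <- matrix(pmax(stats::rnorm(length(genes) * n, 2, 1), 0),
                         nrow = length(genes),
                         dimnames = list(genes, classes))
    planted <- data.frame(gene = character(), focal = character(),
                          direction = character(), effect = numeric())
    if (length(planted_genes) > 0 && effect > 0) {
      focal <- sample(classes, length(planted_genes), replace = TRUE)
      for (k in seq_along(planted_genes)) {
        partners <- if (direction == "output") {
          classes[synapse[focal[k], ] > 0]
        } else {
          classes[synapse[, focal[k]] > 0]
        }
        expression[planted_genes[k], partners] <-
          expression[planted_genes[k], partners] + effect
      }
      planted <- data.frame(gene = planted_genes, focal = focal,
                            direction = direction, effect = effect)
    }
    structure(list(bundles = bundles, regions = regions, contact = contact,
                   synapse = synapse, expression = expression,
                   planted = planted),
              class = "synthetic_connectome")
  })
}

#' Write a synthetic dataset as a 10x-style MatrixMarket triplet
#'
#' @param dataset A `single_cell_dataset`.
#' @param dir Output directory (created if missing). Writes `matrix.mtx`
#'   (genes x cells, as in 10x output), `genes.tsv` and `cells.tsv` (with
#'   class/stage/sample columns).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "single_cell_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(dataset$counts), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(gene = colnames(dataset$counts)),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(cell = rownames(dataset$counts),
               cell_class = dataset$cell_class,
               cell_stage = dataset$cell_stage,
               sample_id = dataset$sample_id),
    file.path(dir, "cells.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(dir)
}

#' Read a 10x-style MatrixMarket triplet written by [write_dataset()]
#'
#' @param dir Directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return A `single_cell_dataset`.
#' @export
read_dataset <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.table(file.path(dir, "cells.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  counts <- t(m)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(cells$cell, genes)
  structure(list(counts = counts, cell_class = cells$cell_class,
                 cell_stage = cells$cell_stage,
                 sample_id = cells$sample_id),
            class = "single_cell_dataset")
}
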