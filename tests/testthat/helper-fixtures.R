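# Shared fixtures, built in code at test time.

# Small profiled dataset with a planted ground truth, used by the
# thresholding and calibration tests.
make_profiled_fixture <- function(n_classes = 10, cells = 60, n_genes = 80,
                                  n_truth = 40, p_on = 0.2, seed = 11) {
  cfg <- sim_config(n_classes, cells, n_genes, seed = seed)
  ds <- generate_counts(cfg)
  prof <- aggregate_profiles(size_factor_normalize(ds), ds$cell_class)
  truth <- generate_ground_truth(cfg, p_on, genes = cfg$genes[seq_len(n_truth)])
  list(cfg = cfg, dataset = ds, profile = prof, truth = truth)
}

# Independent recomputation of the thresholded detection calls and their
# confusion rates: the no-bootstrap oracle for calibration point estimates.
oracle_rates <- function(proportion, truth, fraction) {
  prop <- proportion[rownames(truth), , drop = FALSE]
  cutoff <- fraction * apply(prop, 1, max)
  calls <- (prop > 0 & prop >= cutoff) * 1L
  tp <- sum(calls == 1 & truth == 1); fp <- sum(calls == 1 & truth == 0)
  fn <- sum(calls == 0 & truth == 1); tn <- sum(calls == 0 & truth == 0)
  c(tpr = tp / (tp + fn), fpr = fp / (fp + tn),
    fdr = if (tp + fp > 0) fp / (tp + fp) else 0)
}

# A deterministic binary expression matrix over named genes and classes.
make_expr_bin <- function(genes, classes, density = 0.4, seed = 1) {
  set.seed(seed)
  matrix(rbinom(length(genes) * length(classes), 1, density),
         length(genes), length(classes),
         dimnames = list(genes, classes))
}
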