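test_that("size factors follow the geometric-mean convention", {
  m <- matrix(c(60, 40, 300, 100), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("g1", "g2")))
  # totals 100 and 400 -> geometric mean 200 -> factors 0.5 and 2
  norm <- size_factor_normalize(m)
  expect_equal(norm["a", ], c(g1 = 120, g2 = 80))
  expect_equal(norm["b", ], c(g1 = 150, g2 = 50))

  same <- matrix(50, 3, 2, dimnames = list(letters[1:3], c("g1", "g2")))
  expect_equal(size_factor_normalize(same), same)

  # product of size factors is 1 for any input
  set.seed(2)
  counts <- matrix(rpois(200, 5) + 1, 20, 10,
                   dimnames = list(paste0("c", 1:20), paste0("g", 1:10)))
  totals <- rowSums(counts)
  factors <- totals / exp(mean(log(totals)))
  expect_equal(prod(factors), 1, tolerance = 1e-12)

  zero <- rbind(counts, z = 0)
  expect_error(size_factor_normalize(zero), "z")
})

test_that("aggregation yields detection proportions and TPM columns", {
  counts <- matrix(0L, 10, 3,
                   dimnames = list(paste0("c", 1:10), c("g1", "g2", "g3")))
  counts[1:5, "g1"] <- 2L
  counts[, "g2"] <- 1L
  prof <- aggregate_profiles(size_factor_normalize(counts),
                             rep("A", 10))
  expect_equal(prof$proportion["g1", "A"], 0.5)
  expect_equal(prof$proportion["g3", "A"], 0)
  expect_equal(prof$tpm["g3", "A"], 0)
  expect_equal(sum(prof$tpm[, "A"]), 1e6, tolerance = 1e-6)
})

test_that("prefilter partitions genes by the ubiquitous and low rules", {
  prop <- rbind(ubiq = c(0.011, 0.3, 0.5),
                low = c(0.005, 0.019, 0.01),
                mid = c(0.005, 0.10, 0.30))
  colnames(prop) <- c("A", "B", "C")
  prof <- structure(list(proportion = prop), class = "pseudobulk_profile")
  pf <- prefilter_genes(prof)
  expect_identical(pf$retained_ubiquitous, "ubiq")
  expect_identical(pf$removed_low, "low")
  expect_identical(pf$to_threshold, "mid")
})

test_that("dynamic thresholds zero classes strictly below the cutoff", {
  prop <- rbind(focal = c(0.423, 0.015, 0.020),
                other = c(0.10, 0.05, 0.0))
  tpm <- rbind(focal = c(1000, 50, 70), other = c(300, 200, 0))
  colnames(prop) <- colnames(tpm) <- c("A", "B", "C")
  prof <- structure(list(proportion = prop, tpm = tpm),
                    class = "pseudobulk_profile")
  thr <- dynamic_threshold(prof, 0.04)
  expect_equal(thr$per_gene_cutoff[["focal"]], 0.01692)
  expect_equal(thr$tpm_thresholded["focal", ], c(A = 1000, B = 0, C = 70))

  # fraction 0: no cutoff, nothing zeroed
  thr0 <- dynamic_threshold(prof, 0)
  expect_equal(thr0$tpm_thresholded, tpm)

  # a proportion exactly at the cutoff is retained
  prop2 <- rbind(g = c(0.5, 0.05))
  tpm2 <- rbind(g = c(10, 20))
  colnames(prop2) <- colnames(tpm2) <- c("A", "B")
  prof2 <- structure(list(proportion = prop2, tpm = tpm2),
                     class = "pseudobulk_profile")
  thr2 <- dynamic_threshold(prof2, 0.1)  # cutoff 0.05 == proportion in B
  expect_equal(thr2$tpm_thresholded["g", "B"], 20)
})

test_that("thresholding is idempotent and zeroed sets nest with fraction", {
  fx <- make_profiled_fixture()
  prof <- fx$profile
  pf <- prefilter_genes(prof)
  t1 <- dynamic_threshold(prof, 0.05, pf)
  # idempotence: re-applying the same cutoffs changes nothing
  prof2 <- prof
  prof2$tpm <- t1$tpm_thresholded
  t1b <- dynamic_threshold(prof2, 0.05, pf)
  expect_equal(t1b$tpm_thresholded, t1$tpm_thresholded)

  t2 <- dynamic_threshold(prof, 0.20, pf)
  zero1 <- t1$tpm_thresholded == 0
  zero2 <- t2$tpm_thresholded == 0
  expect_true(all(zero2[zero1]))
})

test_that("prefiltered ubiquitous genes pass through and removed genes zero", {
  prop <- rbind(u = c(0.02, 0.03), r = c(0.001, 0.002), t = c(0.3, 0.001))
  tpm <- rbind(u = c(5, 6), r = c(1, 1), t = c(100, 2))
  colnames(prop) <- colnames(tpm) <- c("A", "B")
  prof <- structure(list(proportion = prop, tpm = tpm),
                    class = "pseudobulk_profile")
  pf <- prefilter_genes(prof)
  thr <- dynamic_threshold(prof, 0.5, pf)
  expect_equal(thr$tpm_thresholded["u", ], c(A = 5, B = 6))
  expect_equal(thr$tpm_thresholded["r", ], c(A = 0, B = 0))
  expect_equal(thr$tpm_thresholded["t", ], c(A = 100, B = 0))
  expect_error(dynamic_threshold(
    structure(list(proportion = rbind(z = c(0, 0)),
                   tpm = rbind(z = c(0, 0))),
              class = "pseudobulk_profile"), 0.1),
    "prefiltered")
})

test_that("confusion rates match a brute-force count", {
  truth <- rbind(c(1, 0, 1), c(0, 0, 1), c(1, 1, 0), c(0, 1, 0))
  expect_equal(confusion_rates(truth, truth), c(tpr = 1, fpr = 0, fdr = 0))
  none <- truth * 0
  expect_equal(confusion_rates(none, truth), c(tpr = 0, fpr = 0, fdr = 0))

  set.seed(31)
  calls <- matrix(rbinom(12, 1, 0.5), 4, 3)
  got <- confusion_rates(calls, truth)
  tp <- fp <- fn <- tn <- 0
  for (i in 1:4) for (j in 1:3) {
    if (calls[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1
    if (calls[i, j] == 1 && truth[i, j] == 0) fp <- fp + 1
    if (calls[i, j] == 0 && truth[i, j] == 1) fn <- fn + 1
    if (calls[i, j] == 0 && truth[i, j] == 0) tn <- tn + 1
  }
  expect_equal(got, c(tpr = tp / (tp + fn), fpr = fp / (fp + tn),
                      fdr = fp / (tp + fp)))
  expect_error(confusion_rates(calls[, 1:2], truth), "dimensions")
})

test_that("calibration point estimates equal the no-bootstrap oracle", {
  fx <- make_profiled_fixture(seed = 11)
  grid <- c(0, 0.05, 0.15, 0.3)
  tab <- calibrate_thresholds(fx$profile, fx$truth, grid,
                              n_boot = 150, seed = 42)
  for (i in seq_along(grid)) {
    oc <- oracle_rates(fx$profile$proportion, fx$truth, grid[i])
    expect_equal(c(tpr = tab$tpr[i], fpr = tab$fpr[i], fdr = tab$fdr[i]),
                 oc)
  }
  # point estimates are bootstrap-seed invariant; CIs are seed-reproducible
  tab2 <- calibrate_thresholds(fx$profile, fx$truth, grid,
                               n_boot = 150, seed = 43)
  expect_equal(tab2$tpr, tab$tpr)
  tab3 <- calibrate_thresholds(fx$profile, fx$truth, grid,
                               n_boot = 150, seed = 42)
  expect_identical(tab3, tab)
  # intervals bracket the point estimate
  expect_true(all(tab$tpr_ci_lo <= tab$tpr & tab$tpr <= tab$tpr_ci_hi))
  expect_true(all(tab$fdr_ci_lo <= tab$fdr & tab$fdr <= tab$fdr_ci_hi))
})

test_that("level selection returns the nearest grid row, ties downward", {
  tab <- data.frame(fraction = c(0.1, 0.2, 0.3),
                    tpr = c(0.9, 0.8, 0.7),
                    fpr = c(0.2, 0.1, 0.05),
                    fdr = c(0.3, 0.2, 0.1))
  class(tab) <- c("calibration_table", "data.frame")
  exact <- data.frame(tpr = 0.8, fpr = 0.1, fdr = 0.2)
  expect_equal(select_levels(tab, exact), 0.2)
  # equidistant between rows 1 and 2 -> smaller fraction wins
  mid <- data.frame(tpr = 0.85, fpr = 0.15, fdr = 0.25)
  expect_equal(select_levels(tab, mid), 0.1)
  # perturbation below half the inter-row gap recovers the nearest row
  near <- data.frame(tpr = 0.71, fpr = 0.06, fdr = 0.11)
  expect_equal(select_levels(tab, near), 0.3)
  expect_error(select_levels(tab[0, ], exact), "empty")
})

test_that("the default fraction grid spans [0, 1] with 272 values", {
  g <- default_fraction_grid()
  expect_length(g, 272)
  expect_equal(range(g), c(0, 1))
})
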