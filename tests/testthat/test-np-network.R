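np_fixture <- function(n_classes = 12, seed = 1) {
  classes <- sprintf("N%02d", seq_len(n_classes))
  genes <- c(sprintf("npp%02d", 1:4), sprintf("gpcr%02d", 1:4))
  expr <- make_expr_bin(genes, classes, density = 0.4, seed = seed)
  bundles <- setNames(rep(c("b1", "b2", "b3"), length.out = n_classes),
                      classes)
  regions <- setNames(
    c(b1 = "head", b2 = "head", b3 = "tail")[bundles], classes)
  list(classes = classes, expr = expr, bundles = bundles,
       regions = regions)
}

test_that("interaction filtering is inclusive at 500 nM and needs both stages", {
  fx <- np_fixture()
  tab <- data.frame(npp = c("npp01", "npp02", "npp03"),
                    gpcr = c("gpcr01", "gpcr02", "gpcr03"),
                    ec50_nM = c(500, 501, 100))
  expr2 <- fx$expr
  expr2["npp03", ] <- 0  # absent from the second stage
  out <- filter_interactions(tab, list(fx$expr, expr2))
  expect_identical(out$npp, "npp01")
})

test_that("proximity matrices encode bundle and region reachability", {
  b <- c(A = "b1", B = "b1", C = "b2", D = "b3")
  r <- c(A = "head", B = "head", C = "head", D = "tail")
  short <- build_proximity(b, r, "short")
  mid <- build_proximity(b, r, "mid")
  expect_equal(short$reachable["A", "B"], 1)   # same bundle
  expect_equal(short$reachable["A", "C"], 0)
  expect_equal(mid$reachable["A", "C"], 1)     # same region
  expect_equal(mid$reachable["A", "D"], 0)     # head vs tail
  expect_equal(short$reachable["A", "D"], 0)
  expect_true(all(diag(mid$reachable) == 1))
  expect_true(isSymmetric(mid$reachable))
  # short-range reachability implies mid-range when bundles nest
  expect_true(all(mid$reachable[short$reachable == 1] == 1))
  expect_error(build_proximity(c(A = NA, B = "b1"),
                               c(A = "head", B = "head")), "unassigned")
})

test_that("pair layers follow the expression-product-times-mask formula", {
  classes <- c("A", "B", "C")
  expr <- matrix(0, 2, 3, dimnames = list(c("npp01", "gpcr01"), classes))
  expr["npp01", "A"] <- 1
  expr["gpcr01", "B"] <- 1
  prox_all <- build_proximity(setNames(rep("b1", 3), classes),
                              setNames(rep("head", 3), classes), "short")
  pair <- list(npp = "npp01", gpcr = "gpcr01", ec50_nM = 10)
  layer <- build_pair_network(expr, pair, prox_all)
  expect_equal(sum(layer$adjacency), 1)
  expect_equal(layer$adjacency["A", "B"], 1)

  prox_none <- prox_all
  prox_none$reachable["A", "B"] <- prox_none$reachable["B", "A"] <- 0L
  expect_equal(sum(build_pair_network(expr, pair, prox_none)$adjacency), 0)

  expr2 <- expr
  expr2["gpcr01", "A"] <- 1
  self <- build_pair_network(expr2, pair, prox_all)
  expect_equal(self$adjacency["A", "A"], 1)
  expect_error(build_pair_network(expr, list(npp = "missing",
                                             gpcr = "gpcr01"), prox_all),
               "rows")
})

test_that("aggregation counts layer multiplicity and conserves edges", {
  fx <- np_fixture(seed = 3)
  prox <- build_proximity(fx$bundles, fx$regions, "mid")
  pairs <- data.frame(npp = c("npp01", "npp02", "npp01"),
                      gpcr = c("gpcr01", "gpcr01", "gpcr02"),
                      ec50_nM = 10)
  layers <- lapply(seq_len(nrow(pairs)), function(i)
    build_pair_network(fx$expr, pairs[i, ], prox))
  net <- aggregate_network(layers, "L1")
  manual <- layers[[1]]$adjacency + layers[[2]]$adjacency +
    layers[[3]]$adjacency
  expect_equal(net$weighted, manual)
  expect_equal(sum(net$weighted),
               sum(vapply(layers, function(l) sum(l$adjacency), numeric(1))))
  # layer edges never violate the proximity mask
  for (l in layers) {
    expect_equal(sum(l$adjacency[prox$reachable == 0]), 0)
  }
  # removing a layer never increases any weighted entry
  net2 <- aggregate_network(layers[1:2], "L1")
  expect_true(all(net2$weighted <= net$weighted))
  # empty network
  net0 <- aggregate_network(list(), "L1", classes = fx$classes)
  expect_true(all(net0$weighted == 0))
})

test_that("degrees are computed on the binarized network", {
  classes <- c("A", "B", "C", "D", "E", "F")
  w <- matrix(0L, 6, 6, dimnames = list(classes, classes))
  w["A", c("B", "C", "D")] <- 2L   # 3 outgoing from A, multiplicities ignored
  w[c("E", "F"), "A"] <- 1L        # 2 incoming to A
  net <- structure(list(weighted = w, layers = list(), stage = "L1"),
                   class = "np_network")
  d <- np_degrees(net)
  expect_equal(d[d$class == "A", c("in_degree", "out_degree", "degree")],
               data.frame(in_degree = 2, out_degree = 3, degree = 5,
                          row.names = 1L))
  expect_equal(sum(d$in_degree), sum(d$out_degree))
  expect_equal(sum(d$in_degree), sum(w > 0))
  empty <- structure(list(weighted = w * 0L), class = "np_network")
  expect_true(all(np_degrees(empty)$degree == 0))
})

test_that("topology classes follow the restricted/broad boundary", {
  classes <- sprintf("n%03d", 1:120)
  mk <- function(npp_n, gpcr_n) {
    e <- matrix(0, 2, 120, dimnames = list(c("npp01", "gpcr01"), classes))
    e["npp01", seq_len(npp_n)] <- 1
    e["gpcr01", seq_len(gpcr_n)] <- 1
    e
  }
  pair <- list(npp = "npp01", gpcr = "gpcr01")
  expect_equal(classify_topology(mk(12, 80), pair), "broadcaster")
  expect_equal(classify_topology(mk(80, 12), pair), "integrative")
  expect_equal(classify_topology(mk(50, 50), pair), "local")
  expect_equal(classify_topology(mk(51, 51), pair), "pervasive")
  # neuron-level counting via class sizes
  sizes <- setNames(rep(2, 120), classes)
  expect_equal(classify_topology(mk(26, 26), pair, class_sizes = sizes),
               "pervasive")
})

test_that("stage comparison partitions edges and scores conservation", {
  fx <- np_fixture(seed = 5)
  prox <- build_proximity(fx$bundles, fx$regions, "mid")
  pairs <- data.frame(npp = c("npp01", "npp02", "npp03"),
                      gpcr = c("gpcr01", "gpcr02", "gpcr03"),
                      ec50_nM = 10)
  layers_a <- lapply(seq_len(nrow(pairs)), function(i)
    build_pair_network(fx$expr, pairs[i, ], prox))
  net_a <- aggregate_network(layers_a, "L1")

  same <- compare_stages(net_a, net_a)
  expect_true(all(same$edges$category == "conserved_identical"))
  expect_equal(unname(same$summary["conserved_frac_a"]), 1)

  # drop a layer in stage b: its exclusive edges become a_only
  net_b <- aggregate_network(layers_a[1:2], "L4")
  cmp <- compare_stages(net_a, net_b)
  expect_equal(nrow(cmp$edges), sum(net_a$weighted > 0 | net_b$weighted > 0))
  only3 <- layers_a[[3]]$adjacency > 0 &
    (layers_a[[1]]$adjacency + layers_a[[2]]$adjacency) == 0
  expect_equal(sum(cmp$edges$category == "a_only"), sum(only3))

  # shared vs different pair sets on a single edge
  mk_layer <- function(npp, gpcr, from, to, classes) {
    adj <- matrix(0L, length(classes), length(classes),
                  dimnames = list(classes, classes))
    adj[from, to] <- 1L
    structure(list(npp = npp, gpcr = gpcr, ec50_nM = 1, adjacency = adj),
              class = "pair_layer")
  }
  cl <- c("A", "B")
  na <- aggregate_network(list(mk_layer("p1", "r1", "A", "B", cl),
                               mk_layer("p2", "r2", "A", "B", cl)), "a")
  nb <- aggregate_network(list(mk_layer("p2", "r2", "A", "B", cl),
                               mk_layer("p3", "r3", "A", "B", cl)), "b")
  expect_equal(compare_stages(na, nb)$edges$category, "conserved_shared")
  nc <- aggregate_network(list(mk_layer("p3", "r3", "A", "B", cl)), "c")
  nd <- aggregate_network(list(mk_layer("p1", "r1", "A", "B", cl)), "d")
  expect_equal(compare_stages(nc, nd)$edges$category, "conserved_different")
})

test_that("conservation decreases as pairs are swapped between stages", {
  classes <- sprintf("N%02d", 1:15)
  genes <- c(sprintf("npp%02d", 1:6), sprintf("gpcr%02d", 1:6))
  prox <- build_proximity(setNames(rep("b1", 15), classes),
                          setNames(rep("head", 15), classes), "short")
  base <- make_expr_bin(genes, classes, density = 0.5, seed = 8)
  pairs <- data.frame(npp = sprintf("npp%02d", 1:6),
                      gpcr = sprintf("gpcr%02d", 1:6), ec50_nM = 10)
  build_net <- function(expr, stage) {
    aggregate_network(lapply(seq_len(nrow(pairs)), function(i)
      build_pair_network(expr, pairs[i, ], prox)), stage)
  }
  net_a <- build_net(base, "a")
  fracs <- vapply(c(0, 0.2, 0.5), function(q) {
    set.seed(100)
    flip <- matrix(runif(length(base)) < q, nrow(base))
    perturbed <- base
    perturbed[flip] <- 1 - perturbed[flip]
    cmp <- compare_stages(net_a, build_net(perturbed, "b"))
    unname(cmp$summary["conserved_frac_a"])
  }, numeric(1))
  expect_true(all(diff(fracs) < 0))
  expect_equal(fracs[1], 1)
})
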