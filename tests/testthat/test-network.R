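graph_from_pairs <- function(pairs, nodes) {
  igraph::graph_from_data_frame(
    data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2]),
    directed = FALSE, vertices = nodes)
}

brute_cross <- function(candidates, reference, net) {
  a <- setdiff(candidates, reference)
  b <- unique(reference)
  el <- igraph::as_edgelist(net)
  n <- 0L
  for (g in a) for (h in b) {
    hit <- (el[, 1] == g & el[, 2] == h) | (el[, 1] == h & el[, 2] == g)
    n <- n + sum(hit)
  }
  n
}

test_that("cross-set connectivity counts only edges joining the two sets", {
  net <- graph_from_pairs(rbind(c("a", "c"), c("a", "d"), c("c", "d")),
                          c("a", "b", "c", "d"))
  expect_equal(cross_connectivity(c("a", "b"), c("c", "d"), net), 2)
  # symmetry in the two sets
  expect_equal(cross_connectivity(c("c", "d"), c("a", "b"), net), 2)
  # disjoint sets, no cross edges
  expect_equal(cross_connectivity("b", c("c", "d"), net), 0)
  # genes absent from the network contribute nothing
  expect_equal(cross_connectivity(c("a", "zz"), c("c", "d"), net), 2)
  # overlap genes count as reference, so their edges are internal
  expect_equal(cross_connectivity(c("a", "c"), c("c", "d"), net), 2)
})

test_that("cross-set connectivity equals a brute-force pair scan on random instances", {
  set.seed(99)
  for (i in 1:30) {
    nodes <- sprintf("n%02d", 1:12)
    g <- gen_network(nodes, background_edge_prob = runif(1, 0.1, 0.6),
                     seed = i)$network
    cand <- sample(nodes, sample(2:5, 1))
    ref <- sample(nodes, sample(2:5, 1))
    expect_equal(cross_connectivity(cand, ref, g),
                 brute_cross(cand, ref, g))
  }
})

test_that("PPI permutation test reports below-resolution p as < 1/n", {
  nodes <- c(sprintf("c%02d", 1:4), sprintf("r%02d", 1:10),
             sprintf("b%02d", 1:40))
  cand <- sprintf("c%02d", 1:4)
  ref <- sprintf("r%02d", 1:10)
  g <- gen_network(nodes, background_edge_prob = 0.01,
                   set_a = cand, set_b = ref, cross_edge_prob = 0.9,
                   seed = 4)$network
  res <- ppi_permutation_test(cand, ref, g, setdiff(nodes, ref),
                              n_permutations = 1000, seed = 1)
  expect_true(res$below_resolution)
  expect_equal(res$p_value, 0)
  expect_equal(perm_p_label(res), "< 0.001")
})

test_that("degenerate backgrounds give p = 1 and draw-size checks", {
  nodes <- c("a", "b", "c", "d")
  g <- graph_from_pairs(rbind(c("a", "c"), c("b", "d")), nodes)
  # background identical to candidates: every draw is the candidate set
  res <- ppi_permutation_test(c("a", "b"), c("c", "d"), g, c("a", "b"),
                              n_permutations = 50, seed = 1)
  expect_equal(res$p_value, 1)
  expect_error(ppi_permutation_test(c("a", "b"), character(), g, "a",
                                    n_permutations = 10, seed = 1),
               "subset")
})

test_that("permutation p is invariant to background relabeling (exchangeability)", {
  fx_net <- gen_network(sprintf("n%02d", 1:30), 0.2, seed = 3)$network
  cand <- c("n01", "n02", "n03")
  ref <- c("n10", "n11", "n12", "n13")
  bg <- setdiff(sprintf("n%02d", 1:30), ref)
  p1 <- ppi_permutation_test(cand, ref, fx_net, bg, 500, seed = 9)
  p2 <- ppi_permutation_test(cand, ref, fx_net, rev(bg), 500, seed = 9)
  expect_equal(p1$observed_statistic, p2$observed_statistic)
  # same null law either way; with the same seed the draws differ only by
  # labels, and the p-values agree closely
  expect_lt(abs(p1$p_value - p2$p_value), 0.05)
})

test_that("co-expression edges follow the absolute-correlation rule", {
  mat <- rbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6), g3 = c(3, 2, 1),
               g4 = c(5, 5, 5))
  se <- make_expr(mat, age_days = c(100, 200, 300),
                  region = rep("DFC", 3))
  cm <- c(DFC = "PFC-MSC")
  net <- quiet(coexpression_network(se, "PFC-MSC", cm,
                                    c("g1", "g4"), c("g2", "g3"), 0.8))
  el <- igraph::as_edgelist(net)
  key <- apply(el, 1, function(r) paste(sort(r), collapse = "-"))
  # r(g1,g2) = 1 and r(g1,g3) = -1 are edges; g4 is flat (no edges)
  expect_setequal(key, c("g1-g2", "g1-g3"))
  expect_true("g4" %in% igraph::V(net)$name)
})

test_that("co-expression networks match a brute-force all-pairs scan", {
  set.seed(7)
  for (i in 1:10) {
    mat <- matrix(rnorm(6 * 5), nrow = 6,
                  dimnames = list(sprintf("g%d", 1:6), NULL))
    se <- make_expr(mat, age_days = rep(100, 5), region = rep("DFC", 5))
    cm <- c(DFC = "X")
    a <- c("g1", "g2", "g3")
    b <- c("g4", "g5", "g6")
    net <- coexpression_network(se, "X", cm, a, b, 0.5)
    got <- igraph::gsize(net)
    expected <- 0L
    for (g in a) for (h in b) {
      if (abs(cor(mat[g, ], mat[h, ])) > 0.5) expected <- expected + 1L
    }
    expect_equal(got, expected)
  }
})

test_that("cluster-wise permutation test handles degenerate candidates and small clusters", {
  mat <- matrix(rnorm(40), nrow = 8,
                dimnames = list(sprintf("g%d", 1:8), NULL))
  se <- make_expr(mat, age_days = rep(100, 5), region = rep("DFC", 5))
  cm <- c(DFC = "X")
  # candidates with no expression rows: observed 0, p = 1
  res <- quiet(coexpression_permutation_test(
    se, cm, candidates = c("zz1", "zz2"),
    reference = c("g5", "g6"),
    background = c(sprintf("g%d", 1:4), "zz1", "zz2"),
    r_threshold = 0.8, n_permutations = 50, seed = 1))
  expect_equal(res$clusters$X$observed_statistic, 0)
  expect_equal(res$clusters$X$p_value, 1)

  se2 <- make_expr(mat[, 1:2, drop = FALSE], age_days = c(100, 200),
                   region = c("DFC", "DFC"))
  expect_error(quiet(coexpression_permutation_test(
    se2, cm, "g1", "g5", sprintf("g%d", 1:4), 0.8, 10, 1)),
    "at least 3")
})

test_that("adding a cross edge never decreases the observed statistic nor raises p", {
  nodes <- sprintf("n%02d", 1:20)
  cand <- nodes[1:4]
  ref <- nodes[10:15]
  bg <- setdiff(nodes, ref)
  g <- gen_network(nodes, 0.15, seed = 5)$network
  base <- ppi_permutation_test(cand, ref, g, bg, 400, seed = 2)
  # add a new candidate-reference edge
  g2 <- igraph::add_edges(g, c("n01", "n12"))
  aug <- ppi_permutation_test(cand, ref, g2, bg, 400, seed = 2)
  expect_gte(aug$observed_statistic, base$observed_statistic)
  expect_lte(aug$p_value, base$p_value)
})
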