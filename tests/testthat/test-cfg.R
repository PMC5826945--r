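mk_perm <- function(p, n = 1000) {
  perm_test_result(10, n, as.integer(round(p * n)))
}

test_that("the CFG score is the channel count, in any channel order", {
  genes <- c("a", "b", "c")
  lbf <- data.frame(gene_id = genes, total_lbf = c(5, 1, 3),
                    corrected_p = c(0.01, 0.2, 0.04))
  ev <- quiet(build_evidence(genes, lbf = lbf, alpha = 0.05))
  expect_equal(ev$score, as.integer(ev$sherlock_discovery))
  expect_equal(ev$sherlock_discovery, c(TRUE, FALSE, TRUE))

  # full house: all nine channels true -> score 9
  ext <- expand.grid(gene_id = "a",
                     channel = c("brain_structure", "cognition",
                                 "functional_assay"),
                     value = 1, stringsAsFactors = FALSE)
  ev9 <- quiet(build_evidence(
    "a",
    lbf = data.frame(gene_id = "a", total_lbf = 5, corrected_p = 1e-3),
    smr = data.frame(gene_id = "a", corrected_p = 1e-3),
    replication = data.frame(gene_id = "a", corrected_p = 1e-3),
    ppi = list(test = mk_perm(0.001), gene_cross = c(a = 3)),
    coexpr = structure(list(clusters = list(X = mk_perm(0.002)),
                            gene_cross = list(X = c(a = 2))),
                       class = "coexpr_perm_result"),
    de = data.frame(gene_id = "a", p_two_sided = 0.004,
                    direction = "up"),
    external = ext, alpha = 0.05))
  expect_equal(ev9$score, 9L)
  ev0 <- quiet(build_evidence("zz", lbf = lbf, alpha = 0.05))
  expect_equal(ev0$score, 0L)
})

test_that("channel rules: set-level p plus per-gene connectivity; DE needs consistent direction", {
  genes <- c("a", "b")
  lbf <- data.frame(gene_id = genes, total_lbf = c(2, 1),
                    corrected_p = c(0.01, 0.01))
  # significant set-level PPI but gene b has no cross edges
  ev <- quiet(build_evidence(
    genes, lbf = lbf,
    ppi = list(test = mk_perm(0.01), gene_cross = c(a = 2, b = 0)),
    alpha = 0.05))
  expect_equal(ev$ppi, c(TRUE, FALSE))
  # non-significant set-level test awards nothing
  ev2 <- quiet(build_evidence(
    genes, lbf = lbf,
    ppi = list(test = mk_perm(0.4), gene_cross = c(a = 2, b = 2)),
    alpha = 0.05))
  expect_false(any(ev2$ppi))
  # below-resolution p (0 exceedances) counts as significant
  ev3 <- quiet(build_evidence(
    genes, lbf = lbf,
    ppi = list(test = perm_test_result(10, 1000, 0),
               gene_cross = c(a = 1, b = 1)),
    alpha = 0.05))
  expect_true(all(ev3$ppi))

  # DE: significant in one region -> point; conflicting directions -> none
  de <- data.frame(gene_id = c("a", "a", "b", "b"),
                   p_two_sided = c(0.01, 0.3, 0.01, 0.02),
                   direction = c("up", "down", "up", "down"))
  ev4 <- quiet(build_evidence(genes, lbf = lbf, de = de, alpha = 0.05))
  expect_equal(ev4$differential_expression, c(TRUE, FALSE))
})

test_that("external channels default to false, ignore unknown genes, reject unknown channels", {
  genes <- c("a", "b")
  lbf <- data.frame(gene_id = genes, total_lbf = 1:2, corrected_p = 1)
  ev <- quiet(build_evidence(genes, lbf = lbf))
  expect_false(any(ev$brain_structure | ev$cognition | ev$functional_assay))

  ext <- data.frame(gene_id = c("a", "nope"), channel = "cognition",
                    value = 1)
  expect_warning(ev2 <- build_evidence(genes, lbf = lbf, external = ext),
                 "unknown gene")
  expect_equal(ev2$cognition, c(TRUE, FALSE))

  bad <- data.frame(gene_id = "a", channel = "telepathy", value = 1)
  expect_error(quiet(build_evidence(genes, lbf = lbf, external = bad)),
               "telepathy")
})

test_that("ranking orders by score, then LBF, then gene id, with tie groups", {
  ev <- data.frame(gene_id = c("a", "b", "c"), stringsAsFactors = FALSE)
  for (ch in cfg_channels()) ev[[ch]] <- FALSE
  ev$score <- c(5L, 3L, 5L)
  lbf <- data.frame(gene_id = c("a", "b", "c"), total_lbf = c(9, 2, 4))
  rk <- rank_genes(ev, lbf)
  expect_equal(rk$gene_id, c("a", "c", "b"))
  expect_equal(rk$rank, 1:3)
  expect_equal(rk$tie_group, 1:3)

  # exact ties share a tie group
  lbf2 <- data.frame(gene_id = c("a", "b", "c"), total_lbf = c(4, 2, 4))
  rk2 <- rank_genes(ev, lbf2)
  expect_equal(rk2$gene_id, c("a", "c", "b"))
  expect_equal(rk2$tie_group, c(1, 1, 2))

  single <- rank_genes(ev[1, ], lbf)
  expect_equal(single$rank, 1L)
})

test_that("adding a true channel never lowers a gene's rank", {
  set.seed(14)
  for (i in 1:20) {
    n <- 6
    ev <- data.frame(gene_id = letters[1:n], stringsAsFactors = FALSE)
    for (ch in cfg_channels()) ev[[ch]] <- runif(n) < 0.4
    ev$score <- as.integer(rowSums(ev[, cfg_channels()]))
    lbf <- data.frame(gene_id = letters[1:n], total_lbf = rnorm(n))
    base <- rank_genes(ev, lbf)
    g <- sample(letters[1:n], 1)
    off <- cfg_channels()[!unlist(ev[ev$gene_id == g, cfg_channels()])]
    if (length(off) == 0) next
    ev2 <- ev
    ev2[ev2$gene_id == g, sample(off, 1)] <- TRUE
    ev2$score <- as.integer(rowSums(ev2[, cfg_channels()]))
    aug <- rank_genes(ev2, lbf)
    expect_lte(aug$rank[aug$gene_id == g], base$rank[base$gene_id == g])
  }
})
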