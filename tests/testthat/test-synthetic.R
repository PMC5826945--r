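test_that("generators are pure functions of their seed", {
  a <- gen_gwas_eqtl(n_snps = 200, n_genes = 20, n_risk_genes = 2,
                     esnps_per_gene = 3, seed = 5)
  b <- gen_gwas_eqtl(n_snps = 200, n_genes = 20, n_risk_genes = 2,
                     esnps_per_gene = 3, seed = 5)
  expect_identical(a$gwas, b$gwas)
  expect_identical(a$eqtl, b$eqtl)
  expect_identical(a$truth$risk_genes, b$truth$risk_genes)
  c <- gen_gwas_eqtl(n_snps = 200, n_genes = 20, n_risk_genes = 2,
                     esnps_per_gene = 3, seed = 6)
  expect_false(identical(a$gwas$z_score, c$gwas$z_score))

  p1 <- quiet(gen_expression_panel(genes = 30, donors = default_donors(9),
                                   regions = "DFC", n_cases = 3,
                                   n_controls = 3, seed = 2))
  p2 <- quiet(gen_expression_panel(genes = 30, donors = default_donors(9),
                                   regions = "DFC", n_cases = 3,
                                   n_controls = 3, seed = 2))
  expect_identical(SummarizedExperiment::assay(p1$expr),
                   SummarizedExperiment::assay(p2$expr))

  g1 <- gen_network(letters[1:10], 0.3, seed = 9)
  g2 <- gen_network(letters[1:10], 0.3, seed = 9)
  expect_identical(igraph::as_edgelist(g1$network),
                   igraph::as_edgelist(g2$network))
})

test_that("eSNP assignment rejects infeasible counts", {
  expect_error(gen_gwas_eqtl(n_snps = 10, n_genes = 5, n_risk_genes = 1,
                             esnps_per_gene = 3),
               "infeasible")
})

test_that("all eSNPs carry strong eQTL signal; only risk-gene eSNPs carry GWAS signal", {
  sim <- gen_gwas_eqtl(seed = 3)
  expect_true(all(table(sim$eqtl$gene_id) == 5))
  # leading eSNP of every gene is cis (SMR instrument always available)
  lead <- !duplicated(sim$eqtl$gene_id)
  expect_true(all(sim$eqtl$cis_trans[lead] == "cis"))
  risk_esnps <- sim$eqtl$snp_id[sim$eqtl$gene_id %in% sim$truth$risk_genes]
  z <- abs(sim$gwas$z_score[match(sim$gwas$snp_id, sim$gwas$snp_id)])
  z_risk <- abs(sim$gwas$z_score[sim$gwas$snp_id %in% risk_esnps])
  z_null <- abs(sim$gwas$z_score[!sim$gwas$snp_id %in% risk_esnps])
  expect_gt(mean(z_risk), 3)
  expect_lt(mean(z_null), 1.5)
})

test_that("null GWAS effect makes risk genes indistinguishable in the GWAS", {
  sim <- gen_gwas_eqtl(gwas_effect_mu = 0, seed = 11)
  risk_esnps <- sim$eqtl$snp_id[sim$eqtl$gene_id %in% sim$truth$risk_genes]
  z_risk <- sim$gwas$z_score[sim$gwas$snp_id %in% risk_esnps]
  ks <- suppressWarnings(ks.test(z_risk, "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("co-expression block with loading 1 and noise 0.1 gives |r| > 0.8 for nearly all pairs", {
  block <- sprintf("g%03d", 1:10)
  panel <- quiet(gen_expression_panel(
    genes = 30, donors = default_donors(30), regions = "DFC",
    coexpr_block = list(genes = block, loading = 1),
    n_cases = 0, n_controls = 0, noise_sd = 0.1, seed = 4))
  mat <- SummarizedExperiment::assay(panel$expr)
  r <- cor(t(mat[block, ]))
  vals <- abs(r[upper.tri(r)])
  expect_gte(mean(vals > 0.8), 0.95)
})

test_that("early-high genes decline by the decay factor; decay 0 is flat", {
  panel <- quiet(gen_expression_panel(
    genes = 20, donors = default_donors(30), regions = "DFC",
    early_high_genes = sprintf("g%03d", 1:5), decay = 0.7,
    n_cases = 0, n_controls = 0, noise_sd = 0.05, seed = 8))
  mat <- SummarizedExperiment::assay(panel$expr)
  age <- SummarizedExperiment::colData(panel$expr)$age_days
  g <- "g001"
  early_mean <- mean(mat[g, age <= 400])
  late_mean <- mean(mat[g, age >= 3200])
  expect_equal(late_mean / early_mean, 0.3, tolerance = 0.05)

  flat <- quiet(gen_expression_panel(
    genes = 20, donors = default_donors(30), regions = "DFC",
    early_high_genes = sprintf("g%03d", 1:5), decay = 0,
    n_cases = 0, n_controls = 0, noise_sd = 0.05, seed = 8))
  fmat <- SummarizedExperiment::assay(flat$expr)
  expect_lt(abs(mean(fmat[g, age <= 400]) - mean(fmat[g, age >= 3200])),
            0.1)
})

test_that("panel generation requires two donors per developmental window", {
  few <- data.frame(donor_id = c("d1", "d2"), age_days = c(100, 5000),
                    stage = c("fetal", "adult"))
  expect_error(gen_expression_panel(genes = 5, donors = few,
                                    regions = "DFC"),
               "at least 2 donors")
})

test_that("planted network matches the cross/background edge rule", {
  genes <- letters[1:8]
  A <- c("a", "b", "c")
  B <- c("c", "d", "e")   # overlap in c
  g <- gen_network(genes, background_edge_prob = 0,
                   set_a = A, set_b = B, cross_edge_prob = 1,
                   seed = 2)$network
  # brute-force expectation: exactly the pairs joining A and B
  expected <- 0L
  for (i in seq_along(genes)) for (j in seq_along(genes)) {
    if (i < j) {
      u <- genes[i]; v <- genes[j]
      if ((u %in% A && v %in% B) || (u %in% B && v %in% A))
        expected <- expected + 1L
    }
  }
  expect_equal(igraph::gsize(g), expected)
  expect_equal(sum(igraph::which_loop(g)), 0)

  null_g <- gen_network(genes, background_edge_prob = 0.5,
                        set_a = A, set_b = B, cross_edge_prob = 0.5,
                        seed = 3)$network
  expect_equal(sum(igraph::which_loop(null_g)), 0)
  expect_false(igraph::any_multiple(null_g))

  expect_error(gen_network(genes, background_edge_prob = 1.5),
               "probabilities")
})

test_that("truth ledger round-trips through JSON", {
  fx <- quiet(gen_study_fixture(seed = 12, n_genes = 20,
                                n_reference = 10,
                                n_background_extra = 5,
                                replication = FALSE))
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(fx$truth, path)
  back <- read_truth(path)
  expect_identical(back$risk_genes, fx$truth$risk_genes)
  expect_identical(back$early_high_genes, fx$truth$early_high_genes)
  expect_identical(back$de_genes, fx$truth$de_genes)
  expect_identical(sort(back$coexpr_block_genes),
                   sort(fx$truth$coexpr_block_genes))
})

test_that("planted sets are subsets of the generated gene universe", {
  fx <- quiet(gen_study_fixture(seed = 13, n_genes = 20,
                                n_reference = 10,
                                n_background_extra = 5,
                                replication = FALSE))
  universe <- rownames(SummarizedExperiment::assay(fx$expr))
  expect_true(all(fx$truth$risk_genes %in% universe))
  expect_true(all(fx$truth$early_high_genes %in% universe))
  expect_true(all(names(fx$truth$de_genes) %in% universe))
  expect_true(all(fx$truth$coexpr_block_genes %in% universe))
  expect_error(
    gen_expression_panel(genes = 5, donors = default_donors(9),
                         regions = "DFC",
                         early_high_genes = "not_a_gene"),
    "not in the generated gene universe")
})
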