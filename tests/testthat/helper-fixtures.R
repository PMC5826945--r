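# Shared fixtures and a memoised end-to-end study runner.

quiet <- function(expr) {
  withr::with_options(list(convergene.quiet = TRUE),
                      suppressMessages(suppressWarnings(expr)))
}

# Small SummarizedExperiment builder for handmade matrices.
make_expr <- function(mat, age_days = rep(1000, ncol(mat)),
                      region = rep("DFC", ncol(mat)),
                      diagnosis = rep(NA_character_, ncol(mat)),
                      donor_id = sprintf("d%02d", seq_len(ncol(mat)))) {
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  cd <- S4Vectors::DataFrame(donor_id = donor_id, region = region,
                             age_days = age_days,
                             stage = convergene::stage_from_age(age_days),
                             diagnosis = diagnosis,
                             row.names = colnames(mat))
  SummarizedExperiment::SummarizedExperiment(assays = list(expr = mat),
                                             colData = cd)
}

# In-memory end-to-end run of the study fixture: discovery and
# replication LBF scans, SMR, PPI and co-expression permutation tests,
# DE, and the CFG ranking. Memoised across test files.
.study_cache <- new.env(parent = emptyenv())

run_study <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  res <- quiet({
    fx <- gen_study_fixture(seed = seed)
    seeds <- withr::with_seed(seed, sample.int(2^31 - 2, 5))
    lbf <- lbf_scan(fx$gwas, fx$eqtl, seed = seeds[1])
    cands <- lbf$gene_id[lbf$corrected_p < 0.05]
    repl <- lbf_scan(fx$gwas, fx$eqtl_replication, seed = seeds[2])
    smr <- smr_scan(fx$gwas, fx$eqtl)
    ppi <- list(
      test = ppi_permutation_test(cands, fx$reference, fx$network,
                                  fx$background, 1000L, seeds[3]),
      gene_cross = convergene:::reference_degree(
        intersect(setdiff(cands, fx$reference),
                  igraph::V(fx$network)$name),
        fx$reference, fx$network))
    coexpr <- coexpression_permutation_test(fx$expr, fx$clusters, cands,
                                            fx$reference, fx$background,
                                            0.8, 1000L, seeds[4])
    de <- de_scan(fx$expr, cands)
    cfg <- if (length(cands) > 0) {
      rank_genes(build_evidence(cands, lbf = lbf, smr = smr, ppi = ppi,
                                coexpr = coexpr, de = de,
                                replication = repl, alpha = 0.05),
                 lbf)
    }
    list(truth = fx$truth, lbf = lbf, candidates = cands,
         replication = repl, smr = smr, ppi = ppi, coexpr = coexpr,
         de = de, cfg = cfg)
  })
  .study_cache[[key]] <- res
  res
}

study_seeds <- function(n = 20) seq(101, by = 7, length.out = n)
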