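#' Run the full prioritization pipeline
#'
#' Orchestrates every stage over files on disk and writes per-stage
#' result tables plus a run manifest to `out_dir`:
#' \enumerate{
#'   \item discovery LBF scan (`lbf.tsv`); candidate genes are those with
#'     Bonferroni-corrected empirical p below `alpha`;
#'   \item optional replication LBF scan with an independent eQTL panel
#'     (`lbf_replication.tsv`);
#'   \item SMR scan (`smr.tsv`);
#'   \item PPI connectivity permutation test of the candidates against
#'     the reference set (`ppi_permutation.tsv`);
#'   \item cluster-wise co-expression permutation test
#'     (`coexpression_permutation.tsv`);
#'   \item developmental-pattern permutation test on developmental
#'     samples (`pattern_permutation.tsv`);
#'   \item case-control differential expression (`de.tsv`);
#'   \item CFG evidence and ranking (`cfg_ranking.tsv`).
#' }
#' The manifest (`manifest.json`) records the package version, the full
#' configuration, the seed, md5 checksums of every input, and the
#' candidate list; a rerun with the same seed and inputs is
#' byte-identical. Any stage failure aborts with the stage name and
#' cause.
#'
#' @param config a [pipeline_config()].
#' @param paths named list of input paths: `gwas`, `eqtl`, `expr_values`,
#'   `expr_meta`, `clusters`, `network`, `reference`, `background`;
#'   optional: `eqtl_replication`, `external_channels`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all in-memory stage results and the
#'   written paths.
#' @export
run_pipeline <- function(config, paths, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  required <- c("gwas", "eqtl", "expr_values", "expr_meta", "clusters",
                "network", "reference", "background")
  missing <- setdiff(required, names(paths))
  if (length(missing) > 0)
    stopf("missing input path(s): %s", paste(missing, collapse = ", "))
  for (nm in names(paths)) {
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]]))
      stopf("input file not found: %s", paths[[nm]])
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  inputs <- stage("read inputs", function() {
    list(gwas = read_gwas_summary(paths$gwas),
         eqtl = read_eqtl_table(paths$eqtl),
         eqtl_replication = if (!is.null(paths$eqtl_replication))
           read_eqtl_table(paths$eqtl_replication),
         expr = read_expression(paths$expr_values, paths$expr_meta),
         clusters = read_region_clusters(paths$clusters),
         network = read_network_tsv(paths$network),
         reference = read_gene_set(paths$reference),
         background = read_gene_set(paths$background),
         external = if (!is.null(paths$external_channels))
           read_result_table(paths$external_channels))
  })

  seeds <- withr::with_seed(config$rng_seed, sample.int(2^31 - 2, 5))

  lbf <- stage("lbf", function()
    lbf_scan(inputs$gwas, inputs$eqtl, config$esnp_p_threshold,
             config$lbf_prior_variance_w, config$n_null_draws_lbf,
             seed = seeds[1]))
  candidates <- lbf$gene_id[lbf$corrected_p < config$alpha]
  log_msg("%d candidate gene(s) significant after Bonferroni correction",
          length(candidates))

  replication <- NULL
  if (!is.null(inputs$eqtl_replication)) {
    replication <- stage("lbf replication", function()
      lbf_scan(inputs$gwas, inputs$eqtl_replication,
               config$esnp_p_threshold, config$lbf_prior_variance_w,
               config$n_null_draws_lbf, seed = seeds[2]))
  }

  smr <- stage("smr", function()
    smr_scan(inputs$gwas, inputs$eqtl, config$smr_instrument_p_threshold))

  ppi <- stage("ppi permutation", function() {
    test <- ppi_permutation_test(candidates, inputs$reference,
                                 inputs$network, inputs$background,
                                 config$n_permutations, seed = seeds[3])
    gene_cross <- reference_degree(
      intersect(setdiff(candidates, inputs$reference),
                igraph::V(inputs$network)$name),
      inputs$reference, inputs$network)
    list(test = test, gene_cross = gene_cross)
  })

  coexpr <- stage("coexpression permutation", function()
    coexpression_permutation_test(inputs$expr, inputs$clusters,
                                  candidates, inputs$reference,
                                  inputs$background,
                                  config$coexpr_r_threshold,
                                  config$n_permutations, seed = seeds[4]))

  pattern <- stage("pattern permutation", function() {
    dev <- is.na(SummarizedExperiment::colData(inputs$expr)$diagnosis)
    pattern_permutation_test(inputs$expr[, dev], candidates,
                             inputs$background, config$n_permutations,
                             seed = seeds[5],
                             early_stage_max = config$early_stage_max,
                             late_stage_min = config$late_stage_min)
  })

  de <- stage("differential expression", function()
    de_scan(inputs$expr, candidates))

  cfg <- stage("cfg", function() {
    if (length(candidates) == 0) {
      log_msg("no significant candidate genes; CFG ranking is empty")
      return(data.frame(gene_id = character(), score = integer(),
                        total_lbf = numeric(), rank = integer(),
                        tie_group = integer()))
    }
    ev <- build_evidence(candidates, lbf = lbf, smr = smr, ppi = ppi,
                         coexpr = coexpr, de = de,
                         replication = replication,
                         external = inputs$external,
                         alpha = config$alpha)
    rank_genes(ev, lbf)
  })

  out <- c(lbf = "lbf.tsv", smr = "smr.tsv",
           ppi = "ppi_permutation.tsv",
           coexpr = "coexpression_permutation.tsv",
           pattern = "pattern_permutation.tsv",
           de = "de.tsv", cfg = "cfg_ranking.tsv")
  out_paths <- stats::setNames(file.path(out_dir, out), names(out))
  write_result_table(lbf, out_paths["lbf"])
  write_result_table(smr, out_paths["smr"])
  write_result_table(perm_result_row(ppi$test, stage = "ppi"),
                     out_paths["ppi"])
  write_result_table(coexpr$table, out_paths["coexpr"])
  write_result_table(perm_result_row(pattern, stage = "pattern"),
                     out_paths["pattern"])
  write_result_table(de, out_paths["de"])
  write_result_table(cfg, out_paths["cfg"])
  if (!is.null(replication)) {
    out_paths["lbf_replication"] <- file.path(out_dir, "lbf_replication.tsv")
    write_result_table(replication, out_paths["lbf_replication"])
  }

  manifest <- list(
    package = "convergene",
    version = as.character(utils::packageVersion("convergene")),
    config = unclass(config),
    seed = config$rng_seed,
    stage_seeds = as.list(stats::setNames(
      seeds, c("lbf", "lbf_replication", "ppi", "coexpr", "pattern"))),
    inputs = lapply(paths[!vapply(paths, is.null, logical(1))],
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    outputs = as.list(out_paths),
    n_genes_tested = nrow(lbf),
    candidates = as.list(candidates))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  invisible(list(lbf = lbf, replication = replication, smr = smr,
                 ppi = ppi, coexpr = coexpr, pattern = pattern, de = de,
                 cfg = cfg, candidates = candidates,
                 paths = c(out_paths, manifest = manifest_path)))
}
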