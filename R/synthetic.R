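## Synthetic fixtures with planted ground truth. Every generator is a pure
## function of its parameters and seed (withr::with_seed, global RNG state
## untouched). SNPs are simulated independently (no LD) on the
## standardized z scale with unit standard error.

new_truth <- function(...) {
  structure(list(...), class = "synthetic_truth")
}

#' Generate paired GWAS and eQTL summary statistics with planted risk genes
#'
#' Every gene receives `esnps_per_gene` eSNPs whose eQTL z-scores are drawn
#' from Normal(`eqtl_effect_mu`, 1) with random sign, so all genes look
#' alike on the eQTL side. On the GWAS side all SNPs are null
#' (z ~ Normal(0, 1)) except the eSNPs of the `n_risk_genes` planted risk
#' genes, which draw z from Normal(`gwas_effect_mu`, 1) with random sign.
#' This reproduces the overlap structure the integrative scoring assumes:
#' risk genes are exactly those whose expression-associated SNPs are also
#' disease-associated. P-values are two-sided normal tail probabilities.
#'
#' @param n_snps total number of GWAS SNPs.
#' @param n_genes number of genes with eQTL records.
#' @param n_risk_genes number of planted risk genes.
#' @param esnps_per_gene eSNPs assigned to each gene.
#' @param gwas_effect_mu mean |z| of risk-gene eSNPs in the GWAS (0 gives
#'   the null model where risk and non-risk genes are indistinguishable).
#' @param eqtl_effect_mu mean |z| of eQTL associations.
#' @param prop_cis probability that a non-leading eSNP is annotated `cis`
#'   (the leading eSNP of every gene is always `cis`, so each gene has an
#'   SMR-eligible instrument).
#' @param gene_ids,risk_genes optional explicit gene universe / risk set
#'   (defaults: `gene001`... and a seeded sample).
#' @param snp_prefix prefix for generated SNP identifiers.
#' @param seed integer seed.
#' @return list with elements `gwas` (SNP association data.frame), `eqtl`
#'   (eQTL association data.frame) and `truth` (a `synthetic_truth` with
#'   the planted risk genes and the eSNP map).
#' @examples
#' sim <- gen_gwas_eqtl(n_snps = 200, n_genes = 20, n_risk_genes = 2,
#'                      esnps_per_gene = 3, seed = 1)
#' sim$truth$risk_genes
#' @export
gen_gwas_eqtl <- function(n_snps = 1000, n_genes = 100, n_risk_genes = 3,
                          esnps_per_gene = 5, gwas_effect_mu = 5,
                          eqtl_effect_mu = 7, prop_cis = 0.8,
                          gene_ids = NULL, risk_genes = NULL,
                          snp_prefix = "rs", seed = 1L) {
  stopifnot(n_risk_genes <= n_genes, esnps_per_gene >= 1,
            gwas_effect_mu >= 0, eqtl_effect_mu >= 0)
  if (esnps_per_gene * n_genes > n_snps)
    stopf("infeasible counts: %d genes x %d eSNPs exceed %d SNPs",
          n_genes, esnps_per_gene, n_snps)
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("gene%03d", seq_len(n_genes))
  } else {
    stopifnot(length(gene_ids) == n_genes)
  }
  snp_ids <- sprintf("%s%05d", snp_prefix, seq_len(n_snps))

  withr::with_seed(seed, {
    if (is.null(risk_genes)) {
      risk_genes <- sort(sample(gene_ids, n_risk_genes))
    } else {
      stopifnot(all(risk_genes %in% gene_ids),
                length(risk_genes) == n_risk_genes)
    }
    esnp_ids <- sample(snp_ids, n_genes * esnps_per_gene)
    esnp_gene <- rep(gene_ids, each = esnps_per_gene)

    eqtl_z <- stats::rnorm(length(esnp_ids), mean = eqtl_effect_mu, sd = 1) *
      sample(c(-1, 1), length(esnp_ids), replace = TRUE)
    gwas_z <- stats::rnorm(n_snps)
    names(gwas_z) <- snp_ids
    risk_esnps <- esnp_ids[esnp_gene %in% risk_genes]
    gwas_z[risk_esnps] <-
      stats::rnorm(length(risk_esnps), mean = gwas_effect_mu, sd = 1) *
      sample(c(-1, 1), length(risk_esnps), replace = TRUE)

    lead <- !duplicated(esnp_gene)          # first eSNP of each gene: cis
    cis <- lead | stats::runif(length(esnp_ids)) < prop_cis
  })

  gwas <- data.frame(snp_id = snp_ids, z_score = unname(gwas_z),
                     p_value = p_from_z(gwas_z), sign_known = TRUE,
                     stringsAsFactors = FALSE)
  eqtl <- data.frame(snp_id = esnp_ids, gene_id = esnp_gene,
                     z_score = eqtl_z, p_value = p_from_z(eqtl_z),
                     sign_known = TRUE,
                     cis_trans = ifelse(cis, "cis", "trans"),
                     stringsAsFactors = FALSE)
  truth <- new_truth(risk_genes = risk_genes,
                     esnp_map = split(esnp_ids, esnp_gene),
                     seeds = list(gwas_eqtl = seed))
  list(gwas = gwas, eqtl = eqtl, truth = truth)
}

#' Default developmental donor table
#'
#' A deterministic panel of donors whose ages (post-conception days) cover
#' the embryonic/fetal window, intermediate childhood ages, and adult ages,
#' mirroring a developmental brain atlas: one third of donors in each of
#' the early (<= `early_age`), intermediate, and late (>= `late_age`)
#' windows, log-spaced in age.
#'
#' @param n number of donors.
#' @param early_age,late_age window bounds in post-conception days.
#' @return data.frame with columns `donor_id`, `age_days`, `stage`.
#' @export
default_donors <- function(n = 42, early_age = 400, late_age = 3200) {
  n3 <- floor(n / 3)
  ages <- c(exp(seq(log(56), log(early_age), length.out = n3)),
            exp(seq(log(early_age * 1.3), log(late_age * 0.85),
                    length.out = n - 2 * n3)),
            exp(seq(log(late_age), log(14880), length.out = n3)))
  data.frame(donor_id = sprintf("d%02d", seq_len(n)),
             age_days = ages,
             stage = stage_from_age(ages),
             stringsAsFactors = FALSE)
}

#' Developmental stage label from post-conception age
#'
#' @param age_days numeric vector of ages in post-conception days
#'   (birth at 280 days).
#' @return character vector of stage labels.
#' @export
stage_from_age <- function(age_days) {
  cut(age_days, breaks = c(0, 280, 1010, 3200, 4940, Inf),
      labels = c("fetal", "infant", "child", "adolescent", "adult"),
      right = FALSE) |> as.character()
}

resolve_gene_subset <- function(spec, universe, what) {
  if (is.null(spec)) return(character())
  if (is.numeric(spec)) {
    stopifnot(spec <= length(universe))
    if (spec == 0) return(character())
    return(sort(sample(universe, spec)))
  }
  missing <- setdiff(spec, universe)
  if (length(missing) > 0)
    stopf("%s gene '%s' is not in the generated gene universe",
          what, missing[1])
  spec
}

#' Generate an expression panel with planted developmental, co-expression
#' and case-control structure
#'
#' Builds a genes-by-samples matrix with complete sample metadata. The
#' panel has two sample groups: developmental reference samples (each
#' donor measured in each of `regions`; diagnosis `NA`) and a case-control
#' group (`n_cases` + `n_controls` adult donors measured in
#' `cc_regions`). Planted structure, all optional:
#' \describe{
#'   \item{early-high genes}{mean expression declines multiplicatively
#'     from the early to the late developmental window by factor `decay`
#'     (linear in log age between the windows).}
#'   \item{co-expression block}{block genes share a per-sample latent
#'     factor with coefficient `coexpr_block$loading`, giving expected
#'     pairwise correlation loading^2 / (loading^2 + noise_sd^2).}
#'   \item{differentially expressed genes}{shifted by `de_shift`
#'     (expression units, random sign per gene) in case samples.}
#' }
#'
#' @param genes gene universe: a count (ids auto-generated) or a character
#'   vector of gene ids.
#' @param donors data.frame as from [default_donors()] (0-row data.frame
#'   for a case-control-only panel).
#' @param regions region codes sampled for every developmental donor.
#' @param early_high_genes planted early-high set: a count or gene ids.
#' @param decay fractional early-to-late decline of early-high genes,
#'   in [0, 1).
#' @param coexpr_block `list(genes = count-or-ids, loading = numeric)`
#'   or `NULL` for no block.
#' @param de_genes planted case-control set: a count or gene ids.
#' @param de_shift expression-unit shift of `de_genes` in cases.
#' @param n_cases,n_controls case-control donor counts.
#' @param cc_regions regions sampled for case-control donors.
#' @param noise_sd standard deviation of i.i.d. measurement noise.
#' @param early_age,late_age developmental window bounds (post-conception
#'   days) used to anchor the decay ramp.
#' @param seed integer seed.
#' @return list with `expr` (a `SummarizedExperiment`, assay `expr`) and
#'   `truth` (planted sets; `de_genes` is a named vector of directions).
#' @examples
#' panel <- gen_expression_panel(genes = 20, donors = default_donors(12),
#'                               regions = "DFC", n_cases = 4,
#'                               n_controls = 4, seed = 1)
#' dim(panel$expr)
#' @export
gen_expression_panel <- function(genes = 200,
                                 donors = default_donors(),
                                 regions = names(brain_region_clusters()),
                                 early_high_genes = 0, decay = 0.7,
                                 coexpr_block = NULL,
                                 de_genes = 0, de_shift = 2,
                                 n_cases = 19, n_controls = 19,
                                 cc_regions = c("HIP", "DFC", "STR"),
                                 noise_sd = 1,
                                 early_age = 400, late_age = 3200,
                                 seed = 1L) {
  stopifnot(decay >= 0, decay < 1, noise_sd > 0)
  if (is.numeric(genes) && length(genes) == 1) {
    genes <- sprintf("g%03d", seq_len(genes))
  }
  n_genes <- length(genes)
  has_dev <- !is.null(donors) && nrow(donors) > 0
  if (has_dev) {
    n_early <- sum(donors$age_days <= early_age)
    n_late <- sum(donors$age_days >= late_age)
    if (n_early < 2 || n_late < 2)
      stopf("need at least 2 donors in each developmental window (got %d early, %d late)",
            n_early, n_late)
  }

  ## sample table
  samp <- data.frame(sample_id = character(), donor_id = character(),
                     region = character(), age_days = numeric(),
                     stage = character(), diagnosis = character(),
                     stringsAsFactors = FALSE)
  if (has_dev) {
    dev <- expand.grid(donor_id = donors$donor_id, region = regions,
                       stringsAsFactors = FALSE)
    dev <- dev[order(dev$donor_id, dev$region), ]
    dev$age_days <- donors$age_days[match(dev$donor_id, donors$donor_id)]
    dev$stage <- donors$stage[match(dev$donor_id, donors$donor_id)]
    dev$diagnosis <- NA_character_
    dev$sample_id <- paste(dev$donor_id, dev$region, sep = ".")
    samp <- rbind(samp, dev[, names(samp)])
  }
  if (n_cases + n_controls > 0) {
    cc_id <- c(sprintf("case%02d", seq_len(n_cases)),
               sprintf("ctrl%02d", seq_len(n_controls)))
    cc_diag <- rep(c("case", "control"), c(n_cases, n_controls))
    cc <- expand.grid(donor_id = cc_id, region = cc_regions,
                      stringsAsFactors = FALSE)
    cc <- cc[order(cc$donor_id, cc$region), ]
    cc$age_days <- 11230            # adult, ~30 years post conception
    cc$stage <- "adult"
    cc$diagnosis <- cc_diag[match(cc$donor_id, cc_id)]
    cc$sample_id <- paste(cc$donor_id, cc$region, sep = ".")
    samp <- rbind(samp, cc[, names(samp)])
  }
  n_samples <- nrow(samp)
  if (n_samples == 0) stopf("panel has no samples")

  withr::with_seed(seed, {
    early_set <- resolve_gene_subset(early_high_genes, genes, "early-high")
    de_set <- resolve_gene_subset(de_genes, genes, "differential-expression")
    block_set <- character()
    loading <- 0
    if (!is.null(coexpr_block)) {
      block_set <- resolve_gene_subset(coexpr_block$genes, genes,
                                       "co-expression block")
      loading <- coexpr_block$loading
    }
    base <- stats::runif(n_genes, 5, 10)
    de_dir <- sample(c(-1, 1), length(de_set), replace = TRUE)
    factor_s <- stats::rnorm(n_samples)
    noise <- matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                    nrow = n_genes)
  })
  names(de_dir) <- de_set

  mat <- matrix(rep(base, n_samples), nrow = n_genes)
  rownames(mat) <- genes
  colnames(mat) <- samp$sample_id

  if (length(early_set) > 0 && decay > 0) {
    ramp <- (log(samp$age_days) - log(early_age)) /
      (log(late_age) - log(early_age))
    ramp <- pmin(pmax(ramp, 0), 1)
    mat[early_set, ] <- mat[early_set, , drop = FALSE] *
      rep(1 - decay * ramp, each = length(early_set))
  }
  if (length(block_set) > 0 && loading != 0) {
    mat[block_set, ] <- mat[block_set, , drop = FALSE] +
      rep(loading * factor_s, each = length(block_set))
  }
  if (length(de_set) > 0 && de_shift != 0) {
    is_case <- !is.na(samp$diagnosis) & samp$diagnosis == "case"
    if (any(is_case)) {
      mat[de_set, is_case] <- mat[de_set, is_case, drop = FALSE] +
        de_dir * de_shift
    }
  }
  mat <- mat + noise

  cd <- S4Vectors::DataFrame(donor_id = samp$donor_id,
                             region = samp$region,
                             age_days = samp$age_days,
                             stage = samp$stage,
                             diagnosis = samp$diagnosis,
                             row.names = samp$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = mat), colData = cd)
  truth <- new_truth(early_high_genes = early_set,
                     de_genes = de_dir,
                     coexpr_block_genes = block_set,
                     seeds = list(expression = seed))
  list(expr = se, truth = truth)
}

#' Generate a random network with planted cross-set enrichment
#'
#' Simple undirected graph over `genes`: every unordered pair is an edge
#' independently, with probability `cross_edge_prob` for pairs joining
#' `set_a` and `set_b` (each such pair drawn once, including pairs inside
#' the overlap of the two sets) and `background_edge_prob` otherwise.
#'
#' @param genes character vector of node ids.
#' @param background_edge_prob background edge probability.
#' @param set_a,set_b gene sets receiving `cross_edge_prob` edges.
#' @param cross_edge_prob edge probability between `set_a` and `set_b`.
#' @param seed integer seed.
#' @return list with `network` (undirected igraph, named vertices) and
#'   `truth` (the planted sets).
#' @export
gen_network <- function(genes, background_edge_prob = 0.02,
                        set_a = character(), set_b = character(),
                        cross_edge_prob = background_edge_prob,
                        seed = 1L) {
  for (p in c(background_edge_prob, cross_edge_prob)) {
    if (!(is.numeric(p) && length(p) == 1 && is.finite(p) && p >= 0 && p <= 1))
      stopf("edge probabilities must be in [0, 1]")
  }
  stopifnot(all(set_a %in% genes), all(set_b %in% genes))
  n <- length(genes)
  idx <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  gi <- genes[idx[, 1]]
  gj <- genes[idx[, 2]]
  cross <- (gi %in% set_a & gj %in% set_b) | (gi %in% set_b & gj %in% set_a)
  prob <- ifelse(cross, cross_edge_prob, background_edge_prob)
  withr::with_seed(seed, {
    keep <- stats::runif(length(prob)) < prob
  })
  edges <- data.frame(gene_a = gi[keep], gene_b = gj[keep],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = genes)
  truth <- new_truth(enriched_candidate_set = intersect(set_a, genes),
                     reference_set = intersect(set_b, genes),
                     seeds = list(network = seed))
  list(network = g, truth = truth)
}

#' Generate a complete study fixture with coherent planted truth
#'
#' Composes the three generators into one bundle emulating a full study:
#' paired GWAS/eQTL tables (discovery and replication eQTL panels against
#' one GWAS) with planted risk genes; an expression panel in which the
#' risk genes are early-high in development, differentially expressed in
#' cases, and co-expressed (together with part of the reference set) via a
#' shared latent factor; a PPI network with excess risk-gene-to-reference
#' edges; and a GWAS-significant reference gene set. The defaults are a
#' desk-scale version of the study design the pipeline addresses:
#' 100 candidate genes with 5 eSNPs each and 3 planted risk genes
#' (GWAS |z| ~ 5, eQTL |z| ~ 7), a 60-gene reference set, 42
#' developmental donors across 16 brain regions in four clusters, and 19
#' cases vs 19 controls in three regions.
#'
#' @param seed integer master seed; sub-generator seeds are derived from
#'   it.
#' @param n_genes,n_risk_genes,esnps_per_gene,gwas_effect_mu,eqtl_effect_mu
#'   passed to [gen_gwas_eqtl()].
#' @param n_reference size of the GWAS-significant reference gene set.
#' @param n_background_extra additional filler genes in the expression /
#'   network universe.
#' @param replication whether to generate a second, independent eQTL panel
#'   (for the replication evidence channel).
#' @return list with elements `gwas`, `eqtl`, `eqtl_replication`, `expr`
#'   (SummarizedExperiment), `network` (igraph), `candidates_truth`,
#'   `reference`, `background`, `clusters`, `truth`.
#' @export
gen_study_fixture <- function(seed = 1L, n_genes = 100, n_risk_genes = 3,
                              esnps_per_gene = 5, gwas_effect_mu = 5,
                              eqtl_effect_mu = 7, n_reference = 60,
                              n_background_extra = 40,
                              replication = TRUE) {
  sub <- withr::with_seed(seed, sample.int(2^31 - 2, 5))
  sim1 <- gen_gwas_eqtl(n_snps = 1000, n_genes = n_genes,
                        n_risk_genes = n_risk_genes,
                        esnps_per_gene = esnps_per_gene,
                        gwas_effect_mu = gwas_effect_mu,
                        eqtl_effect_mu = eqtl_effect_mu,
                        snp_prefix = "rs", seed = sub[1])
  risk <- sim1$truth$risk_genes
  gene_ids <- unique(sim1$eqtl$gene_id)
  gwas <- sim1$gwas
  eqtl_repl <- NULL
  if (replication) {
    sim2 <- gen_gwas_eqtl(n_snps = 1000, n_genes = n_genes,
                          n_risk_genes = n_risk_genes,
                          esnps_per_gene = esnps_per_gene,
                          gwas_effect_mu = gwas_effect_mu,
                          eqtl_effect_mu = eqtl_effect_mu,
                          gene_ids = sort(gene_ids), risk_genes = risk,
                          snp_prefix = "rx", seed = sub[2])
    gwas <- rbind(gwas, sim2$gwas)
    eqtl_repl <- sim2$eqtl
  }
  reference <- sprintf("ref%03d", seq_len(n_reference))
  filler <- sprintf("bg%03d", seq_len(n_background_extra))
  universe <- c(gene_ids, reference, filler)

  block_ref <- reference[seq_len(min(15, n_reference))]
  panel <- gen_expression_panel(
    genes = universe,
    donors = default_donors(42),
    regions = names(brain_region_clusters()),
    early_high_genes = risk, decay = 0.7,
    coexpr_block = list(genes = c(risk, block_ref), loading = 6),
    de_genes = risk, de_shift = 2,
    n_cases = 19, n_controls = 19, noise_sd = 1,
    seed = sub[3])
  net <- gen_network(universe, background_edge_prob = 0.02,
                     set_a = risk, set_b = reference,
                     cross_edge_prob = 0.5, seed = sub[4])

  truth <- new_truth(risk_genes = risk,
                     early_high_genes = panel$truth$early_high_genes,
                     de_genes = panel$truth$de_genes,
                     coexpr_block_genes = panel$truth$coexpr_block_genes,
                     enriched_candidate_set = risk,
                     seeds = list(master = seed, gwas_eqtl = sub[1],
                                  replication = if (replication) sub[2],
                                  expression = sub[3], network = sub[4]))
  list(gwas = gwas, eqtl = sim1$eqtl, eqtl_replication = eqtl_repl,
       expr = panel$expr, network = net$network,
       reference = reference,
       background = setdiff(universe, reference),
       clusters = brain_region_clusters(),
       truth = truth)
}

#' Write a study fixture bundle to a directory
#'
#' Emits the TSV formats the readers consume (`gwas.tsv`, `eqtl.tsv`,
#' optionally `eqtl_replication.tsv`, `expr_values.tsv`, `expr_meta.tsv`,
#' `network.tsv`, `reference.txt`, `background.txt`, `clusters.tsv`) plus
#' the planted-truth ledger `truth.json`.
#'
#' @param fixture a bundle from [gen_study_fixture()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(gwas = file.path(dir, "gwas.tsv"),
             eqtl = file.path(dir, "eqtl.tsv"),
             expr_values = file.path(dir, "expr_values.tsv"),
             expr_meta = file.path(dir, "expr_meta.tsv"),
             network = file.path(dir, "network.tsv"),
             reference = file.path(dir, "reference.txt"),
             background = file.path(dir, "background.txt"),
             clusters = file.path(dir, "clusters.tsv"),
             truth = file.path(dir, "truth.json"))
  write_assoc <- function(df, path) {
    out <- df[, intersect(c("snp_id", "gene_id", "cis_trans"), names(df)),
              drop = FALSE]
    out$z <- df$z_score
    out$p <- df$p_value
    write_result_table(out, path)
  }
  write_assoc(fixture$gwas, paths["gwas"])
  write_assoc(fixture$eqtl, paths["eqtl"])
  if (!is.null(fixture$eqtl_replication)) {
    paths["eqtl_replication"] <- file.path(dir, "eqtl_replication.tsv")
    write_assoc(fixture$eqtl_replication, paths["eqtl_replication"])
  }
  write_expression(fixture$expr, paths["expr_values"], paths["expr_meta"])
  write_network_tsv(fixture$network, paths["network"])
  writeLines(fixture$reference, paths["reference"])
  writeLines(fixture$background, paths["background"])
  write_result_table(data.frame(region = names(fixture$clusters),
                                cluster = unname(fixture$clusters),
                                stringsAsFactors = FALSE),
                     paths["clusters"])
  write_truth(fixture$truth, paths["truth"])
  invisible(paths)
}

#' Write / read a planted-truth ledger
#'
#' @param truth a `synthetic_truth` object.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  if (!is.null(x$de_genes)) x$de_genes <- as.list(x$de_genes)
  jsonlite::write_json(x, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stopf("truth ledger not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$de_genes)) {
    x$de_genes <- unlist(x$de_genes)
    storage.mode(x$de_genes) <- "double"
  }
  structure(x, class = "synthetic_truth")
}
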