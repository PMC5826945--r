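## Tabular input/output. All tables are tab-separated with a header row;
## lines starting with '#' are comments. Gene and SNP identifiers are
## opaque case-sensitive strings.

read_tsv_checked <- function(path, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  if (file.size(path) == 0) {
    warning(sprintf("%s file '%s' is empty", what, path), call. = FALSE)
    return(data.frame())
  }
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

## Validate and complete a z/p pair: recover |z| from p (sign unknown) or
## p from z. Returns the data.frame with z_score, p_value, sign_known.
complete_zp <- function(df, path) {
  has_p <- "p" %in% names(df)
  has_z <- "z" %in% names(df)
  if (!has_p && !has_z)
    stopf("format error in '%s': need column 'p' or 'z'", path)
  if (has_p) {
    bad <- which(!is.finite(df$p) | df$p <= 0 | df$p > 1)
    if (length(bad) > 0)
      stopf("validation error in '%s': p outside (0,1] at data row %d",
            path, bad[1])
  }
  if (has_z && any(!is.finite(df$z)))
    stopf("validation error in '%s': non-finite z value", path)
  if (has_p && has_z) {
    rel <- abs(p_from_z(df$z) - df$p) / pmax(df$p, .Machine$double.xmin)
    if (any(rel > 1e-6))
      stopf("validation error in '%s': p and z disagree at data row %d",
            path, which(rel > 1e-6)[1])
    df$z_score <- df$z
    df$p_value <- df$p
    df$sign_known <- TRUE
  } else if (has_z) {
    df$z_score <- df$z
    df$p_value <- p_from_z(df$z)
    df$sign_known <- TRUE
  } else {
    df$z_score <- z_from_p(df$p)
    df$p_value <- df$p
    df$sign_known <- FALSE
  }
  df
}

#' Read GWAS summary statistics
#'
#' Reads a tab-separated table with header columns `snp_id` and at least
#' one of `p` (two-sided p-value) or `z` (z-score). When only `p` is given
#' the absolute z-score is recovered through the two-sided normal quantile
#' and flagged as sign-unknown (`sign_known = FALSE`); every statistic in
#' the pipeline depends on z only through z^2, so this is lossless here.
#'
#' @param path path to the summary-statistics TSV.
#' @return data.frame with columns `snp_id`, `z_score`, `p_value`,
#'   `sign_known`, one row per SNP.
#' @export
read_gwas_summary <- function(path) {
  df <- read_tsv_checked(path, "GWAS summary")
  if (nrow(df) == 0)
    return(data.frame(snp_id = character(), z_score = numeric(),
                      p_value = numeric(), sign_known = logical()))
  if (!"snp_id" %in% names(df))
    stopf("format error in '%s': missing required column 'snp_id'", path)
  dup <- unique(df$snp_id[duplicated(df$snp_id)])
  if (length(dup) > 0)
    stopf("duplicate snp_id in '%s': %s", path, dup[1])
  df <- complete_zp(df, path)
  df[, c("snp_id", "z_score", "p_value", "sign_known")]
}

#' Read an eQTL association table
#'
#' Reads a tab-separated table with columns `snp_id`, `gene_id`, one of
#' `p`/`z`, and `cis_trans` (values `cis` or `trans`). Each (SNP, gene)
#' pair must be unique.
#'
#' @param path path to the eQTL TSV.
#' @return data.frame with columns `snp_id`, `gene_id`, `z_score`,
#'   `p_value`, `sign_known`, `cis_trans`.
#' @export
read_eqtl_table <- function(path) {
  df <- read_tsv_checked(path, "eQTL")
  if (nrow(df) == 0) {
    warning(sprintf("eQTL table '%s' has no records", path), call. = FALSE)
    return(data.frame(snp_id = character(), gene_id = character(),
                      z_score = numeric(), p_value = numeric(),
                      sign_known = logical(), cis_trans = character()))
  }
  for (col in c("snp_id", "gene_id", "cis_trans")) {
    if (!col %in% names(df))
      stopf("format error in '%s': missing required column '%s'", path, col)
  }
  bad <- which(!df$cis_trans %in% c("cis", "trans"))
  if (length(bad) > 0)
    stopf("validation error in '%s': unknown cis_trans token '%s' at data row %d",
          path, df$cis_trans[bad[1]], bad[1])
  key <- paste(df$snp_id, df$gene_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    stopf("duplicated (snp, gene) pair in '%s': (%s, %s)",
          path, df$snp_id[dup[1]], df$gene_id[dup[1]])
  df <- complete_zp(df, path)
  df[, c("snp_id", "gene_id", "z_score", "p_value", "sign_known", "cis_trans")]
}

#' Read a gene set (one identifier per line)
#'
#' @param path text file with one gene id per line; '#' lines and blank
#'   lines ignored.
#' @return character vector of unique gene ids, in file order.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stopf("gene-set file not found: %s", path)
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Read / write an undirected network edge list
#'
#' `read_network_tsv()` reads a two-column tab-separated edge list
#' (columns `gene_a`, `gene_b`) into an undirected [igraph][igraph::graph]
#' graph; self-loops and duplicate edges are removed with a warning.
#' `write_network_tsv()` writes a graph back to the same format.
#'
#' @param path edge-list TSV path.
#' @param extra_nodes optional isolated nodes to include.
#' @return an undirected `igraph` graph with named vertices.
#' @export
read_network_tsv <- function(path, extra_nodes = character()) {
  df <- read_tsv_checked(path, "network edge list")
  if (nrow(df) == 0) {
    return(igraph::make_empty_graph(directed = FALSE) +
             igraph::vertices(unique(extra_nodes)))
  }
  for (col in c("gene_a", "gene_b")) {
    if (!col %in% names(df))
      stopf("format error in '%s': missing required column '%s'", path, col)
  }
  nodes <- unique(c(df$gene_a, df$gene_b, extra_nodes))
  g <- igraph::graph_from_data_frame(df[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = nodes)
  if (igraph::any_multiple(g) || any(igraph::which_loop(g))) {
    warning(sprintf("network '%s' contained duplicate edges or self-loops; simplified",
                    path), call. = FALSE)
    g <- igraph::simplify(g)
  }
  g
}

#' @rdname read_network_tsv
#' @param net an undirected igraph graph with named vertices.
#' @export
write_network_tsv <- function(net, path) {
  el <- igraph::as_edgelist(net)
  df <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                   stringsAsFactors = FALSE)
  write_result_table(df, path)
  invisible(path)
}

#' Read an expression panel into a SummarizedExperiment
#'
#' The expression values file is a TSV whose first column is `gene_id` and
#' whose remaining columns are sample identifiers. The metadata file is a
#' TSV with columns `sample_id`, `donor_id`, `region`, `age_days`
#' (post-conception days), `stage`, `diagnosis` (`case`, `control`, or
#' `NA` for developmental reference samples). Every expression column must
#' have a metadata row.
#'
#' @param values_path expression matrix TSV.
#' @param meta_path sample metadata TSV.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `expr` and the metadata as column data.
#' @export
read_expression <- function(values_path, meta_path) {
  vals <- read_tsv_checked(values_path, "expression matrix")
  meta <- read_tsv_checked(meta_path, "sample metadata")
  if (!"gene_id" %in% names(vals))
    stopf("format error in '%s': missing required column 'gene_id'", values_path)
  for (col in c("sample_id", "donor_id", "region", "age_days", "stage",
                "diagnosis")) {
    if (!col %in% names(meta))
      stopf("format error in '%s': missing required column '%s'", meta_path, col)
  }
  if (anyDuplicated(vals$gene_id))
    stopf("duplicate gene_id in '%s'", values_path)
  mat <- as.matrix(vals[, setdiff(names(vals), "gene_id"), drop = FALSE])
  rownames(mat) <- vals$gene_id
  missing <- setdiff(colnames(mat), meta$sample_id)
  if (length(missing) > 0)
    stopf("sample '%s' has expression values but no metadata row", missing[1])
  meta <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
  if (any(!is.finite(meta$age_days) | meta$age_days <= 0))
    stopf("validation error in '%s': ages must be positive", meta_path)
  diag <- as.character(meta$diagnosis)
  diag[diag %in% c("", "NA")] <- NA_character_
  bad <- which(!is.na(diag) & !diag %in% c("case", "control"))
  if (length(bad) > 0)
    stopf("validation error in '%s': diagnosis must be case/control/NA", meta_path)
  cd <- S4Vectors::DataFrame(donor_id = meta$donor_id,
                             region = meta$region,
                             age_days = meta$age_days,
                             stage = meta$stage,
                             diagnosis = diag,
                             row.names = meta$sample_id)
  SummarizedExperiment::SummarizedExperiment(assays = list(expr = mat),
                                             colData = cd)
}

#' Write an expression panel to value + metadata TSVs
#'
#' @param expr a `SummarizedExperiment` as produced by [read_expression()]
#'   or [gen_expression_panel()].
#' @param values_path,meta_path output paths.
#' @export
write_expression <- function(expr, values_path, meta_path) {
  mat <- SummarizedExperiment::assay(expr, "expr")
  vals <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write_result_table(vals, values_path)
  cd <- SummarizedExperiment::colData(expr)
  meta <- data.frame(sample_id = rownames(cd),
                     donor_id = cd$donor_id, region = cd$region,
                     age_days = cd$age_days, stage = cd$stage,
                     diagnosis = ifelse(is.na(cd$diagnosis), "NA",
                                        cd$diagnosis),
                     stringsAsFactors = FALSE)
  write_result_table(meta, meta_path)
  invisible(c(values_path, meta_path))
}

#' Read a region-to-cluster map
#'
#' TSV with columns `region` and `cluster`; every region must map to
#' exactly one cluster.
#'
#' @param path map TSV.
#' @return named character vector, region code -> cluster name.
#' @export
read_region_clusters <- function(path) {
  df <- read_tsv_checked(path, "region cluster map")
  for (col in c("region", "cluster")) {
    if (!col %in% names(df))
      stopf("format error in '%s': missing required column '%s'", path, col)
  }
  if (anyDuplicated(df$region))
    stopf("region mapped to more than one cluster in '%s'", path)
  stats::setNames(df$cluster, df$region)
}

#' Canonical brain region clusters
#'
#' The four-cluster grouping of brain regions used by the co-expression
#' analysis: visual/temporal cortex (V1C-STC), prefrontal-motor-somatosensory
#' cortex (PFC-MSC), striatum-hippocampus-amygdala (STR-AMY), and
#' thalamus-cerebellum (MD-CBC).
#'
#' @return named character vector, region code -> cluster name.
#' @examples
#' brain_region_clusters()["DFC"]
#' @export
brain_region_clusters <- function() {
  c(V1C = "V1C-STC", ITC = "V1C-STC", IPC = "V1C-STC", A1C = "V1C-STC",
    STC = "V1C-STC",
    M1C = "PFC-MSC", S1C = "PFC-MSC", VFC = "PFC-MSC", MFC = "PFC-MSC",
    DFC = "PFC-MSC", OFC = "PFC-MSC",
    STR = "STR-AMY", HIP = "STR-AMY", AMY = "STR-AMY",
    MD = "MD-CBC", CBC = "MD-CBC")
}

#' Write / read a result table
#'
#' Tab-separated with header; numeric columns are serialized with 17
#' significant digits so a write-then-read round trip reproduces doubles
#' exactly.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @export
write_result_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  read_tsv_checked(path, "result table")
}
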