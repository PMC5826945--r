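## Cross-set connectivity permutation tests in PPI and co-expression
## networks. Statistic: number of edges joining the candidate set to the
## reference set; edges internal to either set are excluded, and genes in
## both sets count as reference.

#' Cross-set connectivity
#'
#' Number of network edges with one endpoint in `candidates` (minus any
#' overlap with `reference`) and the other in `reference`. Edges internal
#' to either set are excluded, so the count measures connectivity between
#' the sets, and the function is symmetric in its two set arguments.
#' Genes absent from the network contribute no edges.
#'
#' @param candidates candidate gene ids.
#' @param reference reference gene ids.
#' @param net undirected igraph graph with named vertices.
#' @return integer edge count.
#' @export
cross_connectivity <- function(candidates, reference, net) {
  a <- setdiff(candidates, reference)
  b <- unique(reference)
  if (length(a) == 0 || length(b) == 0) return(0L)
  el <- igraph::as_edgelist(net)
  if (nrow(el) == 0) return(0L)
  sum((el[, 1] %in% a & el[, 2] %in% b) |
        (el[, 1] %in% b & el[, 2] %in% a))
}

## Per-node count of neighbors inside the reference set (0 for nodes
## absent from the network). Used so each permutation is an O(draw) sum.
reference_degree <- function(genes, reference, net) {
  ref <- unique(reference)
  out <- stats::setNames(integer(length(genes)), genes)
  el <- igraph::as_edgelist(net)
  if (nrow(el) == 0) return(out)
  cross1 <- el[, 1] %in% ref & !(el[, 2] %in% ref)
  cross2 <- el[, 2] %in% ref & !(el[, 1] %in% ref)
  counts <- table(c(el[cross2, 1], el[cross1, 2]))
  hit <- intersect(names(counts), genes)
  out[hit] <- as.integer(counts[hit])
  out
}

#' PPI connectivity permutation test
#'
#' Tests whether the candidate set has more edges to the reference set
#' than random gene sets of matched size. Each permutation draws, without
#' replacement from `background` minus the reference set, as many genes
#' as there are measurable candidates (candidates that are in the network
#' and not in the reference set -- absent genes shrink the draw, matching
#' the observed set's measurable size), and recomputes the cross-set
#' connectivity. The p-value is the fraction of permutations whose
#' statistic is at least the observed one; when no permutation reaches it
#' the result is reported as "< 1/n_permutations".
#'
#' @param candidates candidate gene ids (must be a subset of
#'   `background`).
#' @param reference reference gene ids.
#' @param net undirected igraph graph with named vertices.
#' @param background gene universe to draw matched sets from.
#' @param n_permutations number of random draws.
#' @param seed integer seed.
#' @return a [perm_test_result()].
#' @export
ppi_permutation_test <- function(candidates, reference, net, background,
                                 n_permutations = 1000L, seed = 1L) {
  if (!all(candidates %in% background))
    stopf("candidates must be a subset of the background universe")
  nodes <- igraph::V(net)$name
  eff <- setdiff(candidates, reference)
  measurable <- intersect(eff, nodes)
  if (length(measurable) < length(eff))
    log_msg("%d candidate gene(s) not in the network; draw size reduced to %d",
            length(eff) - length(measurable), length(measurable))
  pool <- setdiff(background, reference)
  if (length(pool) < length(measurable))
    stopf("background smaller than the permutation draw size")
  deg <- reference_degree(pool, reference, net)
  observed <- cross_connectivity(candidates, reference, net)
  k <- length(measurable)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations),
           function(i) sum(deg[sample(length(pool), k)]),
           numeric(1))
  })
  perm_test_result(observed, n_permutations, sum(perm >= observed),
                   seed = seed, n_drawn = k)
}

#' Cluster-wise co-expression network
#'
#' Builds the co-expression graph between two gene sets over the samples
#' of one region cluster: genes g in `genes_a` and h in `genes_b` are
#' connected iff the absolute Pearson correlation of their expression
#' across the cluster's samples exceeds `r_threshold`. Genes with zero
#' variance in the cluster have undefined correlations and produce no
#' edges (logged). Nodes are the union of both sets restricted to genes
#' present in the panel.
#'
#' @param expr expression `SummarizedExperiment` (assay `expr`).
#' @param cluster cluster name to select samples.
#' @param clustermap named character vector, region -> cluster.
#' @param genes_a,genes_b gene sets to connect.
#' @param r_threshold absolute correlation threshold in (0, 1).
#' @return undirected igraph graph with named vertices.
#' @export
coexpression_network <- function(expr, cluster, clustermap, genes_a,
                                 genes_b, r_threshold = 0.8) {
  if (!is_prob(r_threshold)) stopf("'r_threshold' must be in (0, 1)")
  samp <- cluster_samples(expr, cluster, clustermap)
  mat <- SummarizedExperiment::assay(expr, "expr")[, samp, drop = FALSE]
  nodes <- intersect(unique(c(genes_a, genes_b)), rownames(mat))
  a <- intersect(unique(genes_a), nodes)
  b <- intersect(unique(genes_b), nodes)
  sds <- apply(mat[nodes, , drop = FALSE], 1, stats::sd)
  flat <- nodes[sds == 0]
  if (length(flat) > 0)
    log_msg("%d gene(s) with zero variance in cluster %s excluded from edges",
            length(flat), cluster)
  a_ok <- setdiff(a, flat)
  b_ok <- setdiff(b, flat)
  edges <- NULL
  if (length(a_ok) > 0 && length(b_ok) > 0) {
    r <- stats::cor(t(mat[a_ok, , drop = FALSE]),
                    t(mat[b_ok, , drop = FALSE]))
    hit <- which(abs(r) > r_threshold, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      ga <- a_ok[hit[, 1]]
      gb <- b_ok[hit[, 2]]
      keep <- ga != gb
      key <- ifelse(ga < gb, paste(ga, gb), paste(gb, ga))
      keep <- keep & !duplicated(key)
      edges <- data.frame(gene_a = ga[keep], gene_b = gb[keep],
                          stringsAsFactors = FALSE)
    }
  }
  if (is.null(edges))
    edges <- data.frame(gene_a = character(), gene_b = character())
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

cluster_samples <- function(expr, cluster, clustermap) {
  cd <- SummarizedExperiment::colData(expr)
  regions <- names(clustermap)[clustermap == cluster]
  samp <- rownames(cd)[cd$region %in% regions]
  if (length(samp) < 3)
    stopf("cluster %s has %d sample(s); at least 3 required", cluster,
          length(samp))
  samp
}

#' Cluster-wise co-expression permutation test
#'
#' For each cluster of the region map, counts the co-expression edges
#' (absolute Pearson correlation > `r_threshold` over the cluster's
#' samples) between the candidate set and the reference set, then
#' compares the count with matched-size random gene sets drawn from
#' `background` minus the reference set. Candidates missing from the
#' panel, or flat within a cluster, shrink that cluster's draw size.
#'
#' @param expr expression `SummarizedExperiment`.
#' @param clustermap named character vector, region -> cluster.
#' @param candidates,reference,background gene sets as in
#'   [ppi_permutation_test()].
#' @param r_threshold absolute correlation threshold.
#' @param n_permutations number of random draws per cluster.
#' @param seed integer seed (one stream across clusters).
#' @return list of class `coexpr_perm_result`: `clusters` (named list of
#'   [perm_test_result()]), `gene_cross` (named list: per-cluster named
#'   vector of candidate cross-edge counts), `table` (summary
#'   data.frame, one row per cluster).
#' @export
coexpression_permutation_test <- function(expr, clustermap, candidates,
                                          reference, background,
                                          r_threshold = 0.8,
                                          n_permutations = 1000L,
                                          seed = 1L) {
  clusters <- unique(unname(clustermap))
  mat <- SummarizedExperiment::assay(expr, "expr")
  pool_all <- setdiff(background, reference)
  cand_all <- setdiff(candidates, reference)
  results <- list()
  gene_cross <- list()
  withr::with_seed(seed, {
    for (cl in clusters) {
      samp <- cluster_samples(expr, cl, clustermap)
      sub <- mat[, samp, drop = FALSE]
      present <- rownames(sub)
      sds <- apply(sub, 1, stats::sd)
      flat <- present[sds == 0]
      ref_m <- setdiff(intersect(reference, present), flat)
      pool_m <- setdiff(intersect(pool_all, present), flat)
      cand_m <- setdiff(intersect(cand_all, present), flat)
      k <- length(cand_m)
      if (length(pool_m) < k)
        stopf("cluster %s: background smaller than the permutation draw size", cl)
      rows_needed <- union(pool_m, cand_m)
      cnt <- stats::setNames(integer(length(rows_needed)), rows_needed)
      if (length(ref_m) > 0 && length(rows_needed) > 0) {
        ## pool and candidates exclude reference genes, so no gene pairs
        ## with itself here
        r <- stats::cor(t(sub[rows_needed, , drop = FALSE]),
                        t(sub[ref_m, , drop = FALSE]))
        cnt <- stats::setNames(as.integer(rowSums(abs(r) > r_threshold)),
                               rows_needed)
      }
      obs_cnt <- cnt[cand_m]
      observed <- sum(obs_cnt)
      cnt_pool <- cnt[pool_m]
      perm <- vapply(seq_len(n_permutations),
                     function(i) sum(cnt_pool[sample(length(pool_m), k)]),
                     numeric(1))
      results[[cl]] <- perm_test_result(observed, n_permutations,
                                        sum(perm >= observed),
                                        seed = seed, n_drawn = k)
      gene_cross[[cl]] <- obs_cnt
    }
  })
  tab <- do.call(rbind, lapply(names(results), function(cl)
    perm_result_row(results[[cl]], cluster = cl)))
  structure(list(clusters = results, gene_cross = gene_cross,
                 table = tab),
            class = "coexpr_perm_result")
}

#' @export
print.coexpr_perm_result <- function(x, ...) {
  cat("co-expression permutation test by cluster:\n")
  for (cl in names(x$clusters))
    cat(sprintf("  %-8s observed = %d, P %s\n", cl,
                x$clusters[[cl]]$observed_statistic,
                perm_p_label(x$clusters[[cl]])))
  invisible(x)
}
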