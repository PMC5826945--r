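#' CFG evidence channel names
#'
#' The nine convergent-functional-genomics evidence channels, in fixed
#' order: discovery-stage integrative eQTL-GWAS scoring, PPI
#' connectivity, co-expression connectivity, case-control differential
#' expression, replication of the integrative scoring with independent
#' eQTL data, SMR validation, and three externally supplied channels
#' (brain-structure association, cognition association, functional
#' assay). Each channel contributes one point to a gene's cumulative
#' score.
#'
#' @return character vector of length 9.
#' @export
cfg_channels <- function() {
  c("sherlock_discovery", "ppi", "coexpression",
    "differential_expression", "sherlock_replication", "smr",
    "brain_structure", "cognition", "functional_assay")
}

#' Build the per-gene CFG evidence matrix
#'
#' Derives the six in-pipeline channels from stage results and merges the
#' three external channels:
#' \describe{
#'   \item{sherlock_discovery / sherlock_replication / smr}{Bonferroni-
#'     corrected p below `alpha` in the respective scan.}
#'   \item{ppi}{set-level permutation p below `alpha` (or below
#'     resolution) and, when per-gene cross-edge counts are available,
#'     the gene itself has at least one edge to the reference set.}
#'   \item{coexpression}{at least one cluster with permutation p below
#'     `alpha` in which the gene has at least one cross-edge (set-level p
#'     alone when per-gene counts are unavailable).}
#'   \item{differential_expression}{raw p below `alpha` in at least one
#'     region, with a consistent direction across all significant
#'     regions.}
#' }
#' External channels default to `FALSE` when unsupplied (logged); rows of
#' the external table referencing unknown genes are ignored with a
#' warning.
#'
#' @param genes gene ids to score.
#' @param lbf discovery [lbf_scan()] table.
#' @param smr [smr_scan()] table, or `NULL`.
#' @param ppi `list(test = perm_test_result, gene_cross = named counts)`
#'   from the PPI stage, or `NULL`.
#' @param coexpr a `coexpr_perm_result`, or `NULL`.
#' @param de [de_scan()] table, or `NULL`.
#' @param replication replication [lbf_scan()] table, or `NULL`.
#' @param external data.frame with columns `gene_id`, `channel`
#'   (`brain_structure`, `cognition`, `functional_assay`), `value`
#'   (0/1), or `NULL`.
#' @param alpha significance threshold for awarding a point.
#' @return data.frame with `gene_id`, one logical column per channel,
#'   and the integer `score` (0-9).
#' @export
build_evidence <- function(genes, lbf, smr = NULL, ppi = NULL,
                           coexpr = NULL, de = NULL, replication = NULL,
                           external = NULL, alpha = 0.05) {
  stopifnot(length(genes) >= 1)
  ev <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  sig_in <- function(tab, col = "corrected_p") {
    if (is.null(tab) || nrow(tab) == 0) return(rep(FALSE, length(genes)))
    p <- tab[[col]][match(genes, tab$gene_id)]
    !is.na(p) & p < alpha
  }
  ev$sherlock_discovery <- sig_in(lbf)

  ev$ppi <- rep(FALSE, length(genes))
  if (!is.null(ppi)) {
    set_sig <- ppi$test$below_resolution || ppi$test$p_value < alpha
    if (set_sig) {
      if (is.null(ppi$gene_cross)) {
        ev$ppi <- rep(TRUE, length(genes))
      } else {
        cnt <- ppi$gene_cross[match(genes, names(ppi$gene_cross))]
        ev$ppi <- !is.na(cnt) & cnt >= 1
      }
    }
  }

  ev$coexpression <- rep(FALSE, length(genes))
  if (!is.null(coexpr)) {
    for (cl in names(coexpr$clusters)) {
      res <- coexpr$clusters[[cl]]
      if (res$below_resolution || res$p_value < alpha) {
        cnt <- coexpr$gene_cross[[cl]]
        if (is.null(cnt)) {
          ev$coexpression <- rep(TRUE, length(genes))
        } else {
          hit <- cnt[match(genes, names(cnt))]
          ev$coexpression <- ev$coexpression | (!is.na(hit) & hit >= 1)
        }
      }
    }
  }

  ev$differential_expression <- vapply(genes, function(g) {
    if (is.null(de) || nrow(de) == 0) return(FALSE)
    rows <- de[de$gene_id == g & de$p_two_sided < alpha, , drop = FALSE]
    nrow(rows) >= 1 && length(unique(rows$direction)) == 1
  }, logical(1), USE.NAMES = FALSE)

  ev$sherlock_replication <- sig_in(replication)
  ev$smr <- sig_in(smr)

  for (ch in c("brain_structure", "cognition", "functional_assay")) {
    ev[[ch]] <- rep(FALSE, length(genes))
  }
  if (is.null(external)) {
    log_msg("no external channel file supplied; channels 7-9 default to FALSE")
  } else {
    for (col in c("gene_id", "channel", "value")) {
      if (!col %in% names(external))
        stopf("external channel table must have columns gene_id, channel, value")
    }
    bad_ch <- setdiff(unique(external$channel),
                      c("brain_structure", "cognition", "functional_assay"))
    if (length(bad_ch) > 0)
      stopf("unknown external channel '%s'", bad_ch[1])
    unknown <- setdiff(unique(external$gene_id), genes)
    if (length(unknown) > 0)
      warning(sprintf("external channel rows for %d unknown gene(s) ignored (e.g. %s)",
                      length(unknown), unknown[1]), call. = FALSE)
    keep <- external$gene_id %in% genes
    for (i in which(keep)) {
      ev[ev$gene_id == external$gene_id[i], external$channel[i]] <-
        as.logical(as.integer(external$value[i]))
    }
  }
  ev$score <- as.integer(rowSums(ev[, cfg_channels()]))
  ev
}

#' Rank genes by cumulative CFG score
#'
#' Descending by score, ties broken by descending gene LBF, then by gene
#' id. `tie_group` numbers maximal runs of genes with identical
#' (score, LBF).
#'
#' @param evidence evidence data.frame from [build_evidence()].
#' @param lbf discovery [lbf_scan()] table supplying the tie-break LBF
#'   (genes absent from it rank last within their score).
#' @return the evidence data.frame with added `total_lbf`, `rank`,
#'   `tie_group`, sorted by rank.
#' @export
rank_genes <- function(evidence, lbf = NULL) {
  stopifnot(nrow(evidence) >= 1)
  tl <- rep(-Inf, nrow(evidence))
  if (!is.null(lbf) && nrow(lbf) > 0) {
    m <- match(evidence$gene_id, lbf$gene_id)
    tl[!is.na(m)] <- lbf$total_lbf[m[!is.na(m)]]
  }
  evidence$total_lbf <- tl
  ord <- order(-evidence$score, -evidence$total_lbf, evidence$gene_id)
  out <- evidence[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  new_grp <- c(TRUE, out$score[-1] != out$score[-nrow(out)] |
                 out$total_lbf[-1] != out$total_lbf[-nrow(out)])
  out$tie_group <- cumsum(new_grp)
  rownames(out) <- NULL
  out
}
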