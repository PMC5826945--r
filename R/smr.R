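#' Select the SMR instrument for a gene
#'
#' The instrument is the cis eQTL record with the smallest p-value among
#' those strictly below `instrument_p_threshold` (ties broken by snp_id).
#' Trans records are never used as instruments. A gene with no qualifying
#' cis eQTL has no instrument and returns `NULL` (logged, not an error):
#' such genes are skipped by the scan.
#'
#' @param eqtl eQTL association data.frame.
#' @param gene_id gene identifier.
#' @param instrument_p_threshold instrument p-value cut-off in (0, 1).
#' @return one-row data.frame (`snp_id`, `z_score`, `p_value`,
#'   `cis_trans`) or `NULL`.
#' @export
select_instrument <- function(eqtl, gene_id,
                              instrument_p_threshold = 5e-8) {
  if (!is_prob(instrument_p_threshold))
    stopf("'instrument_p_threshold' must be in (0, 1)")
  rows <- eqtl[eqtl$gene_id == gene_id & eqtl$cis_trans == "cis" &
                 eqtl$p_value < instrument_p_threshold, , drop = FALSE]
  if (nrow(rows) == 0) {
    log_msg("gene %s has no instrument (no cis eQTL below %g)",
            gene_id, instrument_p_threshold)
    return(NULL)
  }
  rows <- rows[order(rows$p_value, rows$snp_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows[1, c("snp_id", "z_score", "p_value", "cis_trans"), drop = FALSE]
}

#' SMR test statistic
#'
#' The summary-data Mendelian-randomization statistic for a single
#' instrument,
#' \deqn{T_{SMR} = \frac{z_{GWAS}^2\, z_{eQTL}^2}{z_{GWAS}^2 + z_{eQTL}^2},}
#' approximately chi-square with 1 degree of freedom under the null of no
#' mediated effect. `T` is symmetric in its arguments, invariant to sign
#' flips, bounded by min(z_GWAS^2, z_eQTL^2), and tends to z_GWAS^2 as
#' the instrument grows strong. `smr_test()` adds the upper-tail
#' chi-square(1) p-value. Vectorized.
#'
#' @param z_gwas GWAS z-score of the instrument.
#' @param z_eqtl eQTL z-score of the instrument (non-zero).
#' @return `smr_stat()`: the statistic; `smr_test()`: list with `t_smr`
#'   and `p_smr`.
#' @examples
#' smr_stat(2, 2)   # 16/8 = 2
#' @export
smr_stat <- function(z_gwas, z_eqtl) {
  if (any(!is.finite(z_gwas)) || any(!is.finite(z_eqtl)))
    stopf("non-finite z-score")
  if (any(z_eqtl == 0)) stopf("instrument invalid: z_eqtl = 0")
  (z_gwas^2 * z_eqtl^2) / (z_gwas^2 + z_eqtl^2)
}

#' @rdname smr_stat
#' @export
smr_test <- function(z_gwas, z_eqtl) {
  t <- smr_stat(z_gwas, z_eqtl)
  list(t_smr = t, p_smr = stats::pchisq(t, df = 1, lower.tail = FALSE))
}

#' Genome-wide SMR scan
#'
#' For every gene with a qualifying cis instrument whose SNP is present
#' in the GWAS table, computes the SMR statistic and p-value, then
#' Bonferroni-corrects over the genes tested.
#'
#' @param gwas GWAS association data.frame.
#' @param eqtl eQTL association data.frame.
#' @param instrument_p_threshold instrument p-value cut-off.
#' @return data.frame sorted by ascending `p_smr` with columns `gene_id`,
#'   `instrument_snp`, `cis_trans`, `z_eqtl`, `z_gwas`, `p_eqtl`,
#'   `p_gwas`, `t_smr`, `p_smr`, `corrected_p`.
#' @export
smr_scan <- function(gwas, eqtl, instrument_p_threshold = 5e-8) {
  genes <- sort(unique(eqtl$gene_id))
  rows <- lapply(genes, function(g) {
    inst <- select_instrument(eqtl, g, instrument_p_threshold)
    if (is.null(inst)) return(NULL)
    gi <- match(inst$snp_id, gwas$snp_id)
    if (is.na(gi)) {
      log_msg("gene %s skipped: instrument %s absent from GWAS", g,
              inst$snp_id)
      return(NULL)
    }
    tst <- smr_test(gwas$z_score[gi], inst$z_score)
    data.frame(gene_id = g, instrument_snp = inst$snp_id,
               cis_trans = inst$cis_trans,
               z_eqtl = inst$z_score, z_gwas = gwas$z_score[gi],
               p_eqtl = inst$p_value, p_gwas = gwas$p_value[gi],
               t_smr = tst$t_smr, p_smr = tst$p_smr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(gene_id = character(), instrument_snp = character(),
                      cis_trans = character(), z_eqtl = numeric(),
                      z_gwas = numeric(), p_eqtl = numeric(),
                      p_gwas = numeric(), t_smr = numeric(),
                      p_smr = numeric(), corrected_p = numeric()))
  out$corrected_p <- bonferroni(out$p_smr, nrow(out))
  out <- out[order(out$p_smr, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
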