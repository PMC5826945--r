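#' Per-eSNP log Bayes factor of disease association
#'
#' Approximate log Bayes factor (in nats) comparing "this eSNP has a true
#' disease association" against the null, evaluated from the GWAS z-score
#' on the standardized scale (unit sampling variance). With prior effect
#' variance `W`,
#' \deqn{\mathrm{LBF}(z) = \tfrac12\log\frac{1}{1+W} +
#'       \frac{z^2}{2}\,\frac{W}{1+W}.}
#' The score is strictly increasing in z^2, negative at z = 0 (an eSNP
#' with no disease association is penalized), and changes sign at
#' z^2 = ((1+W)/W) log(1+W): eSNPs that are also disease-associated score
#' positive, eSNPs that are not score negative. Vectorized over `gwas_z`.
#'
#' @param gwas_z GWAS z-score(s) of the eSNP.
#' @param prior_variance_w prior variance W (> 0) of the true standardized
#'   effect under the association model.
#' @return log Bayes factor(s) in nats.
#' @examples
#' esnp_lbf(0, 0.15)   # negative: no disease signal
#' esnp_lbf(3, 1)      # 0.5*log(0.5) + 4.5*0.5
#' @export
esnp_lbf <- function(gwas_z, prior_variance_w = 0.15) {
  if (any(!is.finite(gwas_z))) stopf("non-finite GWAS z-score")
  w <- prior_variance_w
  if (!(is.numeric(w) && length(w) == 1 && is.finite(w) && w > 0))
    stopf("'prior_variance_w' must be a positive number")
  0.5 * log(1 / (1 + w)) + (gwas_z^2 / 2) * (w / (1 + w))
}

#' Identify the eSNPs of a gene
#'
#' All eQTL records for `gene_id` with p-value strictly below
#' `esnp_p_threshold`, sorted by ascending p-value with ties broken by
#' lexicographic snp_id. A gene absent from the table yields an empty
#' result, not an error.
#'
#' @param eqtl eQTL association data.frame (see [read_eqtl_table()]).
#' @param gene_id gene identifier.
#' @param esnp_p_threshold eQTL p-value cut-off in (0, 1).
#' @return data.frame with columns `snp_id`, `z_score`, `p_value`,
#'   `cis_trans`, ordered as above.
#' @export
find_esnps <- function(eqtl, gene_id, esnp_p_threshold = 1e-5) {
  if (!is_prob(esnp_p_threshold)) stopf("'esnp_p_threshold' must be in (0, 1)")
  rows <- eqtl[eqtl$gene_id == gene_id & eqtl$p_value < esnp_p_threshold, ,
               drop = FALSE]
  rows <- rows[order(rows$p_value, rows$snp_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows[, intersect(c("snp_id", "z_score", "p_value", "cis_trans"),
                   names(rows)), drop = FALSE]
}

#' Gene-level LBF score
#'
#' Looks up the GWAS z-score of every eSNP, scores each with
#' [esnp_lbf()], and sums: the gene's LBF is the sum of its per-eSNP log
#' Bayes factors. eSNPs with no GWAS record are dropped with a warning
#' before summation; SNPs associated with disease only (no eQTL record)
#' never enter the score.
#'
#' @param esnps eSNP data.frame from [find_esnps()] (non-empty).
#' @param gwas GWAS association data.frame (see [read_gwas_summary()]).
#' @param prior_variance_w prior variance W.
#' @param gene_id optional gene identifier carried into the result.
#' @return list of class `gene_lbf_result`: `gene_id`, `esnp_ids`,
#'   `esnp_lbfs`, `total_lbf`, `top_esnp` (the eSNP maximizing the LBF).
#' @export
gene_lbf <- function(esnps, gwas, prior_variance_w = 0.15,
                     gene_id = NA_character_) {
  if (is.null(esnps) || nrow(esnps) == 0)
    stopf("gene not testable: no eSNPs below threshold")
  z <- gwas$z_score[match(esnps$snp_id, gwas$snp_id)]
  missing <- is.na(z)
  if (any(missing)) {
    warning(sprintf("dropping %d eSNP(s) with no GWAS record (e.g. %s)",
                    sum(missing), esnps$snp_id[which(missing)[1]]),
            call. = FALSE)
    esnps <- esnps[!missing, , drop = FALSE]
    z <- z[!missing]
  }
  if (length(z) == 0)
    stopf("gene not testable: no eSNP has a GWAS record")
  lbfs <- esnp_lbf(z, prior_variance_w)
  structure(list(gene_id = gene_id,
                 esnp_ids = esnps$snp_id,
                 esnp_lbfs = lbfs,
                 total_lbf = sum(lbfs),
                 top_esnp = esnps$snp_id[which.max(lbfs)]),
            class = "gene_lbf_result")
}

## Monte-Carlo null totals for genes with n_esnps null eSNPs
lbf_null_totals <- function(n_esnps, prior_variance_w, n_draws) {
  z <- matrix(stats::rnorm(n_draws * n_esnps), nrow = n_draws)
  rowSums(esnp_lbf(z, prior_variance_w))
}

#' Empirical p-value for a gene's LBF score
#'
#' Monte-Carlo null: draws `n_null_draws` genes, each with `n_esnps` GWAS
#' z-scores from the standard normal (eSNP status fixed, disease
#' association null), sums their per-eSNP LBFs, and returns the add-one
#' empirical p-value `(1 + #(null >= observed)) / (1 + n_null_draws)`.
#'
#' @param observed_total observed gene LBF (nats).
#' @param n_esnps number of eSNPs contributing to the observed score.
#' @param prior_variance_w prior variance W.
#' @param n_null_draws number of null genes (>= 100).
#' @param seed integer seed.
#' @return empirical p-value in (0, 1].
#' @export
lbf_empirical_p <- function(observed_total, n_esnps,
                            prior_variance_w = 0.15,
                            n_null_draws = 10000L, seed = 1L) {
  if (!(is_count(n_esnps) && n_esnps >= 1)) stopf("'n_esnps' must be >= 1")
  if (!(is_count(n_null_draws) && n_null_draws >= 100))
    stopf("'n_null_draws' must be >= 100")
  if (!is.finite(observed_total)) stopf("non-finite observed LBF")
  nulls <- withr::with_seed(seed,
    lbf_null_totals(n_esnps, prior_variance_w, n_null_draws))
  (1 + sum(nulls >= observed_total)) / (1 + n_null_draws)
}

#' Bonferroni correction
#'
#' `bonferroni()` multiplies a p-value by the number of tests and caps at
#' one; `bonferroni_threshold()` gives the equivalent per-test
#' significance threshold alpha / n_tests.
#'
#' @param p p-value(s).
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error rate.
#' @return corrected p-value(s) / per-test threshold.
#' @examples
#' bonferroni_threshold(0.05, 8998)   # 5.6e-6 at two significant figures
#' @export
bonferroni <- function(p, n_tests) {
  if (!(is_count(n_tests) && n_tests >= 1)) stopf("'n_tests' must be >= 1")
  pmin(1, p * n_tests)
}

#' @rdname bonferroni
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!(is_count(n_tests) && n_tests >= 1)) stopf("'n_tests' must be >= 1")
  alpha / n_tests
}

#' Bayes factor from a log Bayes factor
#'
#' `exp(lbf)`: the odds of the association model against the null. An LBF
#' of 5.64 corresponds to a gene about 281 times more likely to be
#' associated than under the null.
#'
#' @param lbf log Bayes factor(s) in nats.
#' @return Bayes factor(s).
#' @export
lbf_to_bayes_factor <- function(lbf) {
  if (any(!is.finite(lbf))) stopf("non-finite LBF")
  exp(lbf)
}

#' Genome-wide LBF scan
#'
#' Scores every gene in the eQTL table that has at least one eSNP:
#' identifies eSNPs, sums per-eSNP LBFs, attaches a Monte-Carlo empirical
#' p-value and a Bonferroni-corrected p-value (over the genes tested).
#' Null draws are shared across genes with the same eSNP count, and the
#' whole scan is a deterministic function of `seed`.
#'
#' @param gwas GWAS association data.frame.
#' @param eqtl eQTL association data.frame.
#' @param esnp_p_threshold eSNP p-value cut-off.
#' @param prior_variance_w prior variance W.
#' @param n_null_draws Monte-Carlo null size per eSNP count.
#' @param seed integer seed.
#' @return data.frame sorted by descending `total_lbf` with columns
#'   `gene_id`, `n_esnps`, `total_lbf`, `bayes_factor`, `top_esnp`,
#'   `top_esnp_cis_trans`, `p_eqtl_top`, `p_gwas_top`, `empirical_p`,
#'   `corrected_p`.
#' @export
lbf_scan <- function(gwas, eqtl, esnp_p_threshold = 1e-5,
                     prior_variance_w = 0.15, n_null_draws = 10000L,
                     seed = 1L) {
  genes <- sort(unique(eqtl$gene_id))
  rows <- vector("list", length(genes))
  withr::with_seed(seed, {
    null_cache <- new.env(parent = emptyenv())
    for (i in seq_along(genes)) {
      g <- genes[i]
      esnps <- find_esnps(eqtl, g, esnp_p_threshold)
      if (nrow(esnps) == 0) next
      res <- gene_lbf(esnps, gwas, prior_variance_w, gene_id = g)
      k <- length(res$esnp_ids)
      key <- as.character(k)
      if (is.null(null_cache[[key]])) {
        null_cache[[key]] <- lbf_null_totals(k, prior_variance_w,
                                             n_null_draws)
      }
      emp_p <- (1 + sum(null_cache[[key]] >= res$total_lbf)) /
        (1 + n_null_draws)
      top <- match(res$top_esnp, esnps$snp_id)
      rows[[i]] <- data.frame(
        gene_id = g, n_esnps = k, total_lbf = res$total_lbf,
        bayes_factor = lbf_to_bayes_factor(res$total_lbf),
        top_esnp = res$top_esnp,
        top_esnp_cis_trans = if ("cis_trans" %in% names(esnps))
          esnps$cis_trans[top] else NA_character_,
        p_eqtl_top = esnps$p_value[top],
        p_gwas_top = gwas$p_value[match(res$top_esnp, gwas$snp_id)],
        empirical_p = emp_p, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(gene_id = character(), n_esnps = integer(),
                      total_lbf = numeric(), bayes_factor = numeric(),
                      top_esnp = character(),
                      top_esnp_cis_trans = character(),
                      p_eqtl_top = numeric(), p_gwas_top = numeric(),
                      empirical_p = numeric(), corrected_p = numeric()))
  out$corrected_p <- bonferroni(out$empirical_p, nrow(out))
  out <- out[order(-out$total_lbf, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
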