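#' Two-sample Student's t-test for case-control expression
#'
#' Classical pooled-variance two-sample t-test (n1 + n2 - 2 degrees of
#' freedom) of expression between cases and controls, with a two-sided
#' p-value; a Welch (unequal-variance) switch is provided. The direction
#' is `up` when the case mean exceeds the control mean.
#'
#' @param case_values,control_values numeric expression vectors, each of
#'   length >= 2.
#' @param var_equal pooled-variance (classical Student) test when `TRUE`
#'   (default), Welch otherwise.
#' @return list with `mean_case`, `mean_control`, `t_statistic`, `df`,
#'   `p_two_sided`, `direction`.
#' @examples
#' de_test(c(2, 4, 6), c(1, 3, 5))
#' @export
de_test <- function(case_values, control_values, var_equal = TRUE) {
  if (length(case_values) < 2 || length(control_values) < 2)
    stopf("each group needs at least 2 values")
  if (stats::var(c(case_values, control_values)) == 0)
    stopf("zero pooled variance: expression is constant")
  tt <- stats::t.test(case_values, control_values, var.equal = var_equal)
  m1 <- mean(case_values)
  m0 <- mean(control_values)
  list(mean_case = m1, mean_control = m0,
       t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_two_sided = tt$p.value,
       direction = if (m1 > m0) "up" else "down")
}

#' Case-control differential-expression scan
#'
#' Runs [de_test()] for every candidate gene in every requested region
#' with at least 2 case and 2 control samples. Genes or regions failing
#' the preconditions (too few samples, constant expression) are skipped
#' with a log message. Raw p-values are reported; no multiple-testing
#' correction is applied at this stage.
#'
#' @param expr expression `SummarizedExperiment` with `diagnosis`
#'   metadata.
#' @param candidates candidate gene ids.
#' @param regions regions to test; default: all regions with >= 2 cases
#'   and >= 2 controls.
#' @param var_equal see [de_test()].
#' @return data.frame with one row per (gene, region): `gene_id`,
#'   `region`, `n_case`, `n_control`, `mean_case`, `mean_control`,
#'   `t_statistic`, `df`, `p_two_sided`, `direction`.
#' @export
de_scan <- function(expr, candidates, regions = NULL, var_equal = TRUE) {
  cd <- SummarizedExperiment::colData(expr)
  if (!any(cd$diagnosis %in% "case") || !any(cd$diagnosis %in% "control"))
    stopf("expression panel has no case or no control samples")
  mat <- SummarizedExperiment::assay(expr, "expr")
  if (is.null(regions)) {
    cc <- table(cd$region[!is.na(cd$diagnosis)], cd$diagnosis[!is.na(cd$diagnosis)])
    regions <- rownames(cc)[cc[, "case"] >= 2 & cc[, "control"] >= 2]
  }
  present <- intersect(candidates, rownames(mat))
  skipped <- setdiff(candidates, present)
  if (length(skipped) > 0)
    log_msg("%d candidate gene(s) absent from the expression panel skipped",
            length(skipped))
  rows <- list()
  for (rg in regions) {
    in_rg <- cd$region == rg
    case_s <- in_rg & cd$diagnosis %in% "case"
    ctrl_s <- in_rg & cd$diagnosis %in% "control"
    if (sum(case_s) < 2 || sum(ctrl_s) < 2) {
      log_msg("region %s skipped: fewer than 2 cases or controls", rg)
      next
    }
    for (g in present) {
      res <- tryCatch(de_test(mat[g, case_s], mat[g, ctrl_s], var_equal),
                      error = function(e) {
                        log_msg("gene %s in region %s skipped: %s", g, rg,
                                conditionMessage(e))
                        NULL
                      })
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, region = rg,
        n_case = sum(case_s), n_control = sum(ctrl_s),
        mean_case = res$mean_case, mean_control = res$mean_control,
        t_statistic = res$t_statistic, df = res$df,
        p_two_sided = res$p_two_sided, direction = res$direction,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), region = character(),
                      n_case = integer(), n_control = integer(),
                      mean_case = numeric(), mean_control = numeric(),
                      t_statistic = numeric(), df = numeric(),
                      p_two_sided = numeric(), direction = character())
  rownames(out) <- NULL
  out
}
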