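#' Min-max standardization
#'
#' Linear rescaling of an expression vector onto [0, 1]:
#' x' = (x - min) / (max - min). The minimum maps to 0 and the maximum to
#' 1; a constant vector is mapped to all zeros with a warning (so flat
#' housekeeping genes do not abort batch runs). Idempotent on
#' non-constant vectors.
#'
#' @param values numeric vector, length >= 2.
#' @return normalized vector in [0, 1].
#' @examples
#' minmax_normalize(c(2, 4, 6))
#' @export
minmax_normalize <- function(values) {
  if (length(values) < 2) stopf("need at least 2 values to normalize")
  if (any(!is.finite(values))) stopf("non-finite expression value")
  rng <- range(values)
  if (rng[1] == rng[2]) {
    warning("constant expression vector; normalized to all zeros",
            call. = FALSE)
    return(rep(0, length(values)))
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

## per-gene flag: mean normalized expression strictly higher in the early
## window than in the late window
early_high_flags <- function(expr, genes, early_stage_max, late_stage_min) {
  cd <- SummarizedExperiment::colData(expr)
  early <- cd$age_days <= early_stage_max
  late <- cd$age_days >= late_stage_min
  if (!any(early) || !any(late))
    stopf("empty developmental window (early: %d samples, late: %d samples)",
          sum(early), sum(late))
  mat <- SummarizedExperiment::assay(expr, "expr")
  present <- intersect(genes, rownames(mat))
  if (length(present) < length(genes))
    log_msg("%d candidate gene(s) absent from the expression panel dropped",
            length(genes) - length(present))
  flags <- vapply(present, function(g) {
    x <- suppressWarnings(minmax_normalize(mat[g, ]))
    mean(x[early]) > mean(x[late])
  }, logical(1))
  stats::setNames(flags, present)
}

#' Early-versus-late developmental expression statistic
#'
#' Normalizes each candidate gene's trajectory with
#' [minmax_normalize()] across all its samples, then compares the mean
#' normalized expression over early samples (age <= `early_stage_max`)
#' with late samples (age >= `late_stage_min`); ages are post-conception
#' days and intermediate samples are ignored. The statistic is the number
#' of genes whose early mean strictly exceeds the late mean (ties and
#' flat genes count as not exceeding). Candidates absent from the panel
#' are dropped with a log message.
#'
#' @param expr expression `SummarizedExperiment`.
#' @param candidates candidate gene ids.
#' @param early_stage_max,late_stage_min window bounds in post-conception
#'   days.
#' @return integer count of early-high genes.
#' @export
early_late_statistic <- function(expr, candidates, early_stage_max = 400,
                                 late_stage_min = 3200) {
  sum(early_high_flags(expr, candidates, early_stage_max, late_stage_min))
}

#' Developmental-pattern permutation test
#'
#' Tests whether the candidate set contains more early-high genes than
#' matched random sets: each permutation draws as many genes as there are
#' measurable candidates from `background` and recomputes the early-high
#' count. P-value is the fraction of permutations with a statistic at
#' least the observed one ("< 1/n" when none reaches it).
#'
#' @param expr expression `SummarizedExperiment`.
#' @param candidates candidate gene ids.
#' @param background gene universe to draw matched sets from.
#' @param n_permutations number of random draws.
#' @param seed integer seed.
#' @param early_stage_max,late_stage_min window bounds in post-conception
#'   days.
#' @return a [perm_test_result()].
#' @export
pattern_permutation_test <- function(expr, candidates, background,
                                     n_permutations = 1000L, seed = 1L,
                                     early_stage_max = 400,
                                     late_stage_min = 3200) {
  flags_all <- early_high_flags(expr, union(background, candidates),
                                early_stage_max, late_stage_min)
  cand_m <- intersect(candidates, names(flags_all))
  pool <- intersect(background, names(flags_all))
  k <- length(cand_m)
  if (length(pool) <= k)
    stopf("background must be larger than the permutation draw size")
  observed <- sum(flags_all[cand_m])
  pool_flags <- flags_all[pool]
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations),
           function(i) sum(pool_flags[sample(length(pool), k)]),
           numeric(1))
  })
  perm_test_result(observed, n_permutations, sum(perm >= observed),
                   seed = seed, n_drawn = k)
}

#' Normalized developmental trajectories (long table)
#'
#' Min-max-normalized expression of the requested genes over the
#' developmental samples (diagnosis `NA`), for plotting or export.
#'
#' @param expr expression `SummarizedExperiment`.
#' @param genes gene ids (absent genes dropped).
#' @return data.frame with columns `gene_id`, `sample_id`, `donor_id`,
#'   `region`, `age_days`, `stage`, `normalized_expression`.
#' @export
normalized_trajectories <- function(expr, genes) {
  cd <- SummarizedExperiment::colData(expr)
  dev <- is.na(cd$diagnosis)
  mat <- SummarizedExperiment::assay(expr, "expr")[, dev, drop = FALSE]
  cd <- cd[dev, , drop = FALSE]
  present <- intersect(genes, rownames(mat))
  do.call(rbind, lapply(present, function(g) {
    data.frame(gene_id = g, sample_id = colnames(mat),
               donor_id = cd$donor_id, region = cd$region,
               age_days = cd$age_days, stage = cd$stage,
               normalized_expression =
                 suppressWarnings(minmax_normalize(mat[g, ])),
               stringsAsFactors = FALSE)
  }))
}
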