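#' Pipeline configuration
#'
#' Collects every tunable threshold of the prioritization pipeline in one
#' validated object. Defaults follow the analysis conventions the pipeline
#' implements: an eSNP is an eQTL record with p below `esnp_p_threshold`;
#' the log-Bayes-factor score uses prior effect variance
#' `lbf_prior_variance_w` on the standardized scale; SMR instruments must be
#' genome-wide significant cis eQTL (`smr_instrument_p_threshold`);
#' co-expression edges require absolute Pearson correlation above
#' `coexpr_r_threshold`; permutation tests run `n_permutations` draws; the
#' developmental comparison contrasts samples aged at most `early_stage_max`
#' with samples aged at least `late_stage_min` (both in post-conception
#' days; the defaults bracket the embryonic/fetal window up to ~4 months
#' after birth against ages 8 years and older).
#'
#' @param esnp_p_threshold eQTL p-value cut-off defining eSNPs.
#' @param lbf_prior_variance_w prior variance W of the true standardized
#'   effect under the association model (unitless, > 0).
#' @param smr_instrument_p_threshold eQTL p-value cut-off for SMR
#'   instruments.
#' @param coexpr_r_threshold absolute Pearson correlation above which two
#'   genes are connected in a co-expression network.
#' @param n_permutations number of random gene-set draws per permutation
#'   test.
#' @param n_null_draws_lbf number of Monte-Carlo null genes for the LBF
#'   empirical p-value.
#' @param rng_seed integer master seed; with fixed inputs it determines
#'   every stochastic output of the pipeline.
#' @param early_stage_max upper age bound (post-conception days) of the
#'   early developmental window.
#' @param late_stage_min lower age bound (post-conception days) of the late
#'   developmental window.
#' @param alpha family-wise error rate used for significance calls.
#' @return a validated list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(rng_seed = 42L)
#' cfg$coexpr_r_threshold
#' @export
pipeline_config <- function(esnp_p_threshold = 1e-5,
                            lbf_prior_variance_w = 0.15,
                            smr_instrument_p_threshold = 5e-8,
                            coexpr_r_threshold = 0.8,
                            n_permutations = 1000L,
                            n_null_draws_lbf = 10000L,
                            rng_seed = 1L,
                            early_stage_max = 400,
                            late_stage_min = 3200,
                            alpha = 0.05) {
  cfg <- list(esnp_p_threshold = esnp_p_threshold,
              lbf_prior_variance_w = lbf_prior_variance_w,
              smr_instrument_p_threshold = smr_instrument_p_threshold,
              coexpr_r_threshold = coexpr_r_threshold,
              n_permutations = as.integer(n_permutations),
              n_null_draws_lbf = as.integer(n_null_draws_lbf),
              rng_seed = as.integer(rng_seed),
              early_stage_max = early_stage_max,
              late_stage_min = late_stage_min,
              alpha = alpha)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  for (f in c("esnp_p_threshold", "smr_instrument_p_threshold",
              "coexpr_r_threshold", "alpha")) {
    if (!is_prob(cfg[[f]])) stopf("config field '%s' must be in (0, 1)", f)
  }
  if (!(is.numeric(cfg$lbf_prior_variance_w) && cfg$lbf_prior_variance_w > 0))
    stopf("config field 'lbf_prior_variance_w' must be positive")
  if (!(is_count(cfg$n_permutations) && cfg$n_permutations >= 1))
    stopf("config field 'n_permutations' must be a count >= 1")
  if (!(is_count(cfg$n_null_draws_lbf) && cfg$n_null_draws_lbf >= 100))
    stopf("config field 'n_null_draws_lbf' must be a count >= 100")
  if (!is_count(cfg$rng_seed)) stopf("config field 'rng_seed' must be an integer")
  if (!(cfg$early_stage_max > 0 && cfg$late_stage_min > 0))
    stopf("developmental window bounds must be positive ages")
  if (!(cfg$early_stage_max < cfg$late_stage_min))
    stopf("'early_stage_max' must be smaller than 'late_stage_min'")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (f in names(x)) cat(sprintf("  %-27s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; missing keys take
#' their defaults, unknown keys are an error.
#'
#' @param path path to a YAML (key: value) file.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}
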