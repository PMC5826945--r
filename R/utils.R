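#' Convert between two-sided p-values and z-scores
#'
#' `p_from_z()` returns the two-sided standard-normal tail probability of
#' `|z|`; `z_from_p()` inverts it, returning the (non-negative) two-sided
#' normal quantile. All association statistics in the package work on the
#' standardized (z) scale with unit standard error, so the pair is lossless
#' for everything downstream, which depends on z only through z^2.
#'
#' @param z numeric vector of z-scores.
#' @param p numeric vector of two-sided p-values in (0, 1].
#' @return numeric vector.
#' @examples
#' p_from_z(1.96)
#' z_from_p(0.05)
#' @export
p_from_z <- function(z) 2 * stats::pnorm(-abs(z))

#' @rdname p_from_z
#' @export
z_from_p <- function(p) stats::qnorm(p / 2, lower.tail = FALSE)

## internal logging: plain messages, silenced via option
log_msg <- function(...) {
  if (!isTRUE(getOption("convergene.quiet", FALSE))) {
    message(sprintf(...))
  }
  invisible(NULL)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == as.integer(x)

is_prob <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x > 0 && x < 1

#' Permutation test result
#'
#' Container for a gene-set permutation test: the observed integer statistic,
#' the number of permutations, how many permuted statistics were greater than
#' or equal to the observed one, and the resulting p-value `n_exceeding /
#' n_permutations`. When no permutation reaches the observed value the
#' p-value is zero and is reported with the conventional "< 1/n" label
#' (`below_resolution = TRUE`): a permutation test cannot resolve p below
#' the reciprocal of its permutation count.
#'
#' @param observed observed statistic (numeric scalar).
#' @param n_permutations number of permutations performed.
#' @param n_exceeding number of permutations with statistic >= observed.
#' @param seed integer seed used for the permutation draws (recorded only).
#' @param n_drawn size of the random gene sets drawn in each permutation.
#' @return an object of class `perm_test_result` with fields
#'   `observed_statistic`, `n_permutations`, `n_exceeding`, `p_value`,
#'   `below_resolution`, `seed`, `n_drawn`.
#' @export
perm_test_result <- function(observed, n_permutations, n_exceeding,
                             seed = NA_integer_, n_drawn = NA_integer_) {
  stopifnot(is_count(n_permutations), n_permutations >= 1,
            is_count(n_exceeding), n_exceeding >= 0,
            n_exceeding <= n_permutations)
  structure(
    list(observed_statistic = observed,
         n_permutations = as.integer(n_permutations),
         n_exceeding = as.integer(n_exceeding),
         p_value = n_exceeding / n_permutations,
         below_resolution = n_exceeding == 0L,
         seed = seed,
         n_drawn = as.integer(n_drawn)),
    class = "perm_test_result")
}

#' @export
format.perm_test_result <- function(x, ...) {
  sprintf("permutation test: observed = %s, P %s (%d permutations)",
          format(x$observed_statistic), perm_p_label(x), x$n_permutations)
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Display label for a permutation p-value
#'
#' Formats `p_value` as "< 1/n" when no permutation reached the observed
#' statistic, and as "= p" otherwise.
#'
#' @param x a [perm_test_result()].
#' @return character scalar.
#' @export
perm_p_label <- function(x) {
  stopifnot(inherits(x, "perm_test_result"))
  if (x$below_resolution) {
    sprintf("< %s", format(1 / x$n_permutations))
  } else {
    sprintf("= %s", format(x$p_value))
  }
}

## one row of a per-cluster / per-stage permutation summary table
perm_result_row <- function(x, ...) {
  data.frame(...,
             observed = x$observed_statistic,
             n_drawn = x$n_drawn,
             n_permutations = x$n_permutations,
             n_exceeding = x$n_exceeding,
             p_value = x$p_value,
             below_resolution = x$below_resolution,
             p_label = perm_p_label(x),
             stringsAsFactors = FALSE)
}
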