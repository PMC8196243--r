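# Hartigan's dip test of unimodality with Monte-Carlo calibration.

#' Hartigan & Hartigan's dip statistic
#'
#' Maximal distance between the empirical cdf and the closest unimodal cdf,
#' computed by the iterative convex-minorant / concave-majorant algorithm.
#' The minimum attainable value for a sample of `n` distinct points is
#' `1/(2n)`; a sample of identical values returns 0 (degenerate, trivially
#' unimodal).
#'
#' @param x Numeric vector (need not be sorted).
#' @return The dip statistic (scalar).
#' @export
dip_statistic <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("non-finite values")
  .dip_stat_cpp(sort(x))
}

#' Calibrated dip test of unimodality
#'
#' The dip statistic is compared with a Monte-Carlo null distribution of dips
#' of uniform samples of the same size (the classical calibration: the
#' uniform is the least-favourable unimodal null). The p-value uses the
#' add-one estimator `(1 + #{null >= observed}) / (n_null + 1)`. Significant
#' bimodality is declared at `p < alpha` (default 0.01).
#'
#' @param x Numeric vector of at least 20 values (e.g. P2T times in us).
#' @param n_null Number of Monte-Carlo null samples. Default 10000; values
#'   below 1000 give unstable p-values and raise a warning.
#' @param alpha Significance level. Default 0.01.
#' @param seed Integer seed for the null draws; required.
#' @param null_dips Optional precomputed null dips for samples of size
#'   `length(x)` (see [dip_null_table()]); overrides `n_null`/`seed`.
#' @return List: `dip`, `p_value`, `significant`, `n`, `n_null`.
#' @export
calibrated_dip_test <- function(x, n_null = 10000L, alpha = 0.01, seed,
                                null_dips = NULL) {
  x <- as.numeric(x)
  if (length(x) < 20) stop("need at least 20 values")
  d <- dip_statistic(x)
  if (is.null(null_dips)) {
    if (missing(seed)) stop("seed is required (reproducibility contract)")
    if (n_null < 1000) warning("n_null < 1000: unstable calibrated p-value")
    null_dips <- dip_null_table(length(x), n_null, seed)
  }
  p <- (1 + sum(null_dips >= d)) / (length(null_dips) + 1)
  list(dip = d, p_value = p, significant = p < alpha, n = length(x),
       n_null = length(null_dips))
}

#' Null dip distribution for uniform samples
#'
#' Dips of `n_null` uniform(0,1) samples of size `n`. The dip statistic is
#' location/scale invariant, so this table calibrates any uniform null.
#'
#' @param n Sample size.
#' @param n_null Number of null samples.
#' @param seed Integer seed.
#' @return Numeric vector of null dip statistics.
#' @export
dip_null_table <- function(n, n_null = 10000L, seed) {
  if (missing(seed)) stop("seed is required (reproducibility contract)")
  withr_rng(rng_stream(seed, "dipnull"), {
    vapply(seq_len(n_null),
           function(i) .dip_stat_cpp(sort(stats::runif(n))), numeric(1))
  })
}
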