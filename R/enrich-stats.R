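# Exact hypergeometric tail probability and multiple-testing corrections.

#' Hypergeometric test parameters
#'
#' Validates the four counts of the over-representation test: background size
#' `N`, background proteins carrying the term `K`, query list size `n`, and
#' observed query proteins carrying the term `m`. Violated inequalities are
#' reported by name.
#'
#' @param N,K,n,m Non-negative integers with `K <= N`, `n <= N`,
#'   `m <= min(K, n)`.
#' @return A list of class `hypergeom_params`.
#' @export
hypergeom_params <- function(N, K, n, m) {
  for (nm in c("N", "K", "n", "m")) {
    v <- get(nm)
    if (!is_count(v)) {
      ptm_error(sprintf("hypergeometric parameter %s must be a non-negative integer", nm),
                "ptmenrich_param_error")
    }
  }
  if (K > N) ptm_error("violated: K <= N", "ptmenrich_param_error")
  if (n > N) ptm_error("violated: n <= N", "ptmenrich_param_error")
  if (m > min(K, n)) ptm_error("violated: m <= min(K, n)", "ptmenrich_param_error")
  structure(list(N = as.integer(N), K = as.integer(K),
                 n = as.integer(n), m = as.integer(m)),
            class = "hypergeom_params")
}

#' Exact upper-tail hypergeometric probability
#'
#' Probability of observing at least `m` term-carrying proteins in a draw of
#' `n` from a background of `N` proteins of which `K` carry the term:
#' `sum_{x=m}^{min(K,n)} C(K,x) C(N-K,n-x) / C(N,n)`. The sum is evaluated in
#' log space via `lchoose` so backgrounds of 1e5+ proteins do not overflow.
#' `m = 0` gives exactly 1. A result that underflows to zero is floored at
#' the smallest positive double and flagged with the attribute `underflow`.
#'
#' @inheritParams hypergeom_params
#' @param params Alternatively, a [hypergeom_params] object.
#' @return A probability in (0, 1].
#' @export
hypergeom_pvalue <- function(N, K, n, m, params = NULL) {
  p <- params %||% hypergeom_params(N, K, n, m)
  if (p$m == 0L) return(1)
  xs <- p$m:min(p$K, p$n)
  lg <- lchoose(p$K, xs) + lchoose(p$N - p$K, p$n - xs) - lchoose(p$N, p$n)
  val <- exp(logsumexp(lg))
  val <- min(val, 1)
  if (val <= 0) {
    val <- .Machine$double.xmin
    attr(val, "underflow") <- TRUE
  }
  val
}

check_pvalues <- function(pvalues) {
  if (length(pvalues) == 0L) {
    ptm_error("p-value vector must be non-empty", "ptmenrich_param_error")
  }
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    ptm_error("p-values must lie in (0, 1]", "ptmenrich_param_error")
  }
}

#' Bonferroni family-wise error rate correction
#'
#' Returns both views of the correction: per-test adjusted p-values
#' `min(1, p * T)` and the modified significance level `alpha / T`; the two
#' give identical significance decisions.
#'
#' @param pvalues Numeric vector of raw p-values in (0, 1].
#' @param alpha Significance level.
#' @return List with `adjusted` and `adjusted_alpha`.
#' @export
bonferroni_adjust <- function(pvalues, alpha = 0.05) {
  check_pvalues(pvalues)
  list(adjusted = stats::p.adjust(pvalues, method = "bonferroni"),
       adjusted_alpha = alpha / length(pvalues))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up procedure: with p-values sorted ascending, `q_(i) = p_(i) * T / i`,
#' monotonicity enforced by a cumulative minimum from the largest rank down,
#' capped at 1, returned in input order.
#'
#' @param pvalues Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  check_pvalues(pvalues)
  stats::p.adjust(pvalues, method = "BH")
}
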