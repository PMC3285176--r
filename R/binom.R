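#' Two-sided exact binomial p-value against a balanced allelic null
#'
#' Tests the null hypothesis that both alleles contribute equally to the
#' pooled cSNP read count, i.e. \eqn{k \sim Binomial(n, 0.5)}.  The
#' two-sided p-value is the doubled upper tail of the more extreme count,
#' capped at 1:
#' \deqn{p = \min(1,\; 2\,\Pr(X \ge \max(k, n-k))).}
#' Because the null is symmetric this equals the doubled lower tail of the
#' less extreme count, and the function is symmetric in \code{k}
#' and \code{n - k}.
#'
#' @param k Integer vector of reads supporting one allele (strain A).
#' @param n Integer vector of pooled read depths; recycled against `k`.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' binom_pvalue_two_sided(9, 10)   # 0.021484375
#' binom_pvalue_two_sided(5, 10)   # 1
#' @export
binom_pvalue_two_sided <- function(k, n) {
  if (length(k) == 0L) return(numeric(0))
  bad <- is.na(k) | is.na(n)
  if (any(!bad & (n < 1 | k < 0 | k > n)))
    stop("binom_pvalue_two_sided: require 0 <= k <= n and n >= 1")
  m <- pmax(k, n - k)
  p <- 2 * stats::pbinom(m - 1, n, 0.5, lower.tail = FALSE)
  p <- pmin(p, 1)
  p[bad] <- NA_real_
  p
}

#' Probability that a balanced gene is called monoallelic at depth n
#'
#' Analytic per-gene false-call probability under the balanced null: the
#' chance that \eqn{k \sim Binomial(n, 0.5)} lands in either tail that
#' satisfies the monoallelic call rule (majority-allele proportion
#' \eqn{\ge} `mono_cut` and two-sided exact p-value \eqn{\le} `alpha`).
#' This is the building block of the analytic FDR estimate.
#'
#' @param n Integer vector of pooled depths.
#' @param mono_cut Majority-allele proportion threshold (default 0.85).
#' @param alpha Significance threshold on the exact test (default 0.05).
#' @return Numeric vector of null call probabilities.
#' @seealso [estimate_fdr()]
#' @export
null_call_probability <- function(n, mono_cut = 0.85, alpha = 0.05) {
  vapply(n, function(ni) {
    if (is.na(ni) || ni < 1) return(NA_real_)
    # smallest k in the upper tail meeting both the proportion and the
    # significance rule; the p-value is non-increasing in k above n/2
    k_prop <- ceiling(mono_cut * ni)
    ks <- k_prop:ni
    ok <- binom_pvalue_two_sided(ks, ni) <= alpha
    if (!any(ok)) return(0)
    k_star <- ks[which(ok)[1L]]
    # two symmetric tails; guard against overlap when k_star <= n/2
    up <- stats::pbinom(k_star - 1, ni, 0.5, lower.tail = FALSE)
    lo <- stats::pbinom(ni - k_star, ni, 0.5)
    min(1, up + lo)
  }, numeric(1))
}
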