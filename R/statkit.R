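#' Exact Clopper-Pearson binomial confidence interval
#'
#' Computes the exact (Clopper-Pearson) two-sided confidence interval for a
#' binomial proportion by bisection on the binomial tail probabilities. The
#' lower bound solves \eqn{P(X \ge k \mid p) = \alpha/2} (0 when \eqn{k = 0});
#' the upper bound solves \eqn{P(X \le k \mid p) = \alpha/2} (1 when
#' \eqn{k = n}). These are the intervals conventionally reported for observed
#' recombinant counts in linkage studies; they are conservative (coverage at
#' least \eqn{1 - \alpha}).
#'
#' @param k Number of successes (e.g. observed recombinants), `0 <= k <= n`.
#' @param n Number of trials (e.g. informative meioses).
#' @param alpha Two-sided error rate; `0.05` gives a 95\% interval.
#' @param tol Bisection tolerance on the bound itself.
#' @return An object of class `"binomial_ci"`: a list with elements `k`, `n`,
#'   `estimate` (`k/n`), `low`, `high`, `alpha`. For `n = 0` the estimate and
#'   bounds are `NA`.
#' @examples
#' clopper_pearson(125, 274)   # approx (0.3962, 0.5172)
#' clopper_pearson(0, 63)      # lower bound exactly 0
#' @export
clopper_pearson <- function(k, n, alpha = 0.05, tol = 1e-10) {
  stopifnot(length(k) == 1L, length(n) == 1L, alpha > 0, alpha < 1)
  if (n == 0) {
    out <- list(k = k, n = n, estimate = NA_real_, low = NA_real_,
                high = NA_real_, alpha = alpha)
    class(out) <- "binomial_ci"
    return(out)
  }
  stopifnot(k >= 0, k <= n)
  half <- alpha / 2
  # upper tail P(X >= k | p) is increasing in p; lower tail decreasing in p
  low <- if (k == 0) 0 else {
    .bisect(function(p) stats::pbinom(k - 1, n, p, lower.tail = FALSE) - half,
            0, 1, tol)
  }
  high <- if (k == n) 1 else {
    .bisect(function(p) half - stats::pbinom(k, n, p), 0, 1, tol)
  }
  out <- list(k = k, n = n, estimate = k / n, low = low, high = high,
              alpha = alpha)
  class(out) <- "binomial_ci"
  out
}

# bisection for a function increasing through zero on [lo, hi]
.bisect <- function(f, lo, hi, tol) {
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (hi - lo < tol) break
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' @export
print.binomial_ci <- function(x, digits = 4, ...) {
  cat(sprintf("Exact binomial (Clopper-Pearson) %g%% CI\n", 100 * (1 - x$alpha)))
  cat(sprintf("  k/n = %d/%d = %s,  CI [%s, %s]\n", x$k, x$n,
              format(x$estimate, digits = digits),
              format(x$low, digits = digits),
              format(x$high, digits = digits)))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test on a 2x2 contingency table, using the probability-mass
#' rule: the p-value sums the hypergeometric probabilities of every table with
#' the same margins whose probability does not exceed that of the observed
#' table. Degenerate tables (an empty margin) give p = 1.
#'
#' @param tab A 2x2 matrix of non-negative counts, or a length-4 vector
#'   `c(a, b, c, d)` filled by row.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))  # 34/70
#' @export
fisher_exact_2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2, 2, byrow = TRUE)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Empirical coverage of the Clopper-Pearson interval
#'
#' Simulates binomial draws at a known proportion and reports the fraction of
#' replicates whose exact interval contains the truth. Used to validate the
#' conservativeness of the interval at the sample sizes arising in
#' recombination-fraction estimation.
#'
#' @param p_true True success probability.
#' @param n Trials per replicate.
#' @param alpha Interval error rate.
#' @param reps Number of replicates (>= 100).
#' @param seed Integer seed; the simulation is fully reproducible.
#' @return Fraction of replicates covering `p_true`.
#' @export
binomial_coverage_sim <- function(p_true, n, alpha = 0.05, reps = 2000L,
                                  seed = 1L) {
  stopifnot(reps >= 100L, p_true >= 0, p_true <= 1, n >= 1)
  set.seed(seed)
  ks <- stats::rbinom(reps, n, p_true)
  # interval depends on k only: compute once per distinct count
  uk <- sort(unique(ks))
  cover <- vapply(uk, function(k) {
    ci <- clopper_pearson(k, n, alpha)
    ci$low <= p_true && p_true <= ci$high
  }, logical(1L))
  mean(cover[match(ks, uk)])
}
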