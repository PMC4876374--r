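#' @title Exact binomial chance model and group-distribution tests
#' @description The forced-choice task is a Bernoulli(1/2) guessing process
#'   under the null. A subject is above chance when their number of correct
#'   trials k reaches the smallest k whose exact binomial point probability
#'   drops to the significance level; below chance at the mirror-image bound.
#'   Group counts are compared with chi-square goodness-of-fit tests and
#'   Cohen's omega = sqrt(chi2 / N).
#' @name chance
NULL

#' Exact binomial point probability
#'
#' \eqn{P(X = k) = C(n,k) p^k (1-p)^{n-k}}, evaluated on the log-gamma scale
#' for stability. Vectorized over `k`.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials.
#' @param p Success probability, strictly inside (0, 1).
#' @return Point probability (vector if `k` is a vector).
#' @examples
#' binom_pmf(20, 30, 0.5)   # 0.028: the above-chance criterion at 30 trials
#' @export
binom_pmf <- function(k, n, p) {
  if (any(k < 0 | k > n) || any(k != floor(k)))
    stop("k must be an integer in [0, n]")
  if (!(p > 0 && p < 1)) stop("p must be strictly inside (0, 1)")
  exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p))
}

#' Build the binomial chance model
#'
#' `k_upper` is the smallest trial count above the chance expectation
#' `n * p0` whose point probability is at most `alpha`; for the symmetric
#' case `p0 = 0.5`, `k_lower = n - k_upper`. With the canonical 30-trial
#' design this yields the 20-correct criterion (point probability 0.028) and
#' its mirror at 10.
#'
#' @param n Number of trials (>= 1).
#' @param p0 Chance probability (default 0.5).
#' @param alpha Significance level (default 0.05).
#' @return Object of class `chance_model` with fields `n`, `p0`, `alpha`,
#'   `k_upper`, `k_lower`, and `p_at_k_upper` (the point probability at the
#'   upper criterion).
#' @export
build_chance_model <- function(n, p0 = 0.5, alpha = 0.05) {
  if (n < 1 || n != floor(n)) stop("n must be a positive integer")
  ks <- seq.int(floor(n * p0) + 1L, n)
  ok <- ks[binom_pmf(ks, n, p0) <= alpha]
  if (!length(ok))
    stop("no trial count is significant at alpha = ", alpha,
         " with n = ", n, " trials")
  k_upper <- min(ok)
  if (isTRUE(all.equal(p0, 0.5))) {
    k_lower <- n - k_upper
  } else {
    ks_lo <- seq.int(0L, ceiling(n * p0) - 1L)
    ok_lo <- ks_lo[binom_pmf(ks_lo, n, p0) <= alpha]
    k_lower <- if (length(ok_lo)) max(ok_lo) else -1L
  }
  structure(list(n = as.integer(n), p0 = p0, alpha = alpha,
                 k_upper = as.integer(k_upper), k_lower = as.integer(k_lower),
                 p_at_k_upper = binom_pmf(k_upper, n, p0)),
            class = "chance_model")
}

#' @export
print.chance_model <- function(x, ...) {
  cat("<chance_model> n =", x$n, " p0 =", x$p0, " alpha =", x$alpha, "\n",
      " above chance at >=", x$k_upper, "correct (point p =",
      signif(x$p_at_k_upper, 3), ")\n",
      " below chance at <=", x$k_lower, "correct\n")
  invisible(x)
}

#' Classify a subject against the chance model
#'
#' `SELF` when the number of correct trials reaches `k_upper` (above-chance
#' recognition of the own heart), `OTHER` when it falls to `k_lower` or below
#' (systematic misattribution), `NON_DISCRIMINATOR` in between. Vectorized
#' over `n_correct`.
#'
#' @param n_correct Number of correct trials (0..n).
#' @param model A [build_chance_model()] object.
#' @return Character vector of group labels.
#' @export
classify_subject <- function(n_correct, model) {
  stopifnot(inherits(model, "chance_model"))
  if (any(n_correct < 0 | n_correct > model$n))
    stop("n_correct must lie in [0, ", model$n, "]")
  ifelse(n_correct >= model$k_upper, "SELF",
         ifelse(n_correct <= model$k_lower, "OTHER", "NON_DISCRIMINATOR"))
}

#' Chi-square goodness of fit with Cohen's omega
#'
#' Pearson chi-square \eqn{\sum (O-E)^2/E} against equal (or supplied)
#' expected counts, df = cells - 1, upper-tail p, and the effect size
#' \eqn{\omega = \sqrt{\chi^2 / N}}.
#'
#' @param observed Integer vector of observed counts (>= 2 cells).
#' @param expected `"equal"` (default) or a vector of expected counts, all
#'   positive; rescaled to the observed total.
#' @return Object of class `gof_result`: `chi2`, `df`, `p`, `omega`, `N`.
#' @examples
#' gof_chi2(c(17, 7, 3))   # chi2 = 11.6, omega = 0.65
#' @export
gof_chi2 <- function(observed, expected = "equal") {
  if (length(observed) < 2) stop("need at least 2 cells")
  if (any(observed < 0)) stop("observed counts must be non-negative")
  N <- sum(observed)
  if (identical(expected, "equal")) {
    E <- rep(N / length(observed), length(observed))
  } else {
    if (length(expected) != length(observed))
      stop("expected and observed must have the same length")
    if (any(expected <= 0)) stop("all expected counts must be > 0")
    E <- expected / sum(expected) * N
  }
  chi2 <- sum((observed - E)^2 / E)
  df <- length(observed) - 1L
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 omega = sqrt(chi2 / N), N = N),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("chi2(%d) = %.2f, p = %.3g, Cohen's omega = %.2f (N = %d)\n",
              x$df, x$chi2, x$p, x$omega, x$N))
  invisible(x)
}

#' Post-hoc pairwise group-count comparisons
#'
#' One 2-cell equal-expected [gof_chi2()] per unordered pair of groups, with
#' no multiple-testing adjustment. Pairs with zero total count are skipped
#' with a warning.
#'
#' @param counts_by_group Named integer vector of group counts (>= 2 groups).
#' @return Named list of `gof_result` objects; names are `"A vs B"`.
#' @export
posthoc_pairwise <- function(counts_by_group) {
  if (length(counts_by_group) < 2) stop("need at least 2 groups")
  if (is.null(names(counts_by_group)))
    stop("counts_by_group must be named by group label")
  pairs <- utils::combn(names(counts_by_group), 2, simplify = FALSE)
  out <- list()
  for (pr in pairs) {
    cts <- counts_by_group[pr]
    if (sum(cts) == 0) {
      warning("pair ", pr[1], " vs ", pr[2], " has zero total count; skipped",
              call. = FALSE)
      next
    }
    out[[paste(pr[1], "vs", pr[2])]] <- gof_chi2(as.numeric(cts))
  }
  out
}
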