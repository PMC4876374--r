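#' @title Cohort-level inference
#' @description Paired comparison of meta-d' against d' (paired t with
#'   Cohen's d on the differences), correlations of each with interoceptive
#'   accuracy, the Williams-Steiger t for two dependent correlations sharing
#'   a variable, and Kruskal-Wallis comparisons across the SELF /
#'   NON-DISCRIMINATOR / OTHER groups.
#' @name inference
NULL

#' Paired t test with Cohen's d
#'
#' Classical paired t (df = n - 1); the effect size is the mean of the
#' paired differences divided by their sample standard deviation (n - 1
#' denominator). When all differences are identical the test is degenerate:
#' `t = 0, d = 0, p = 1` for a zero shift, and the `degenerate` flag is set
#' for any constant shift.
#'
#' @param x,y Per-subject values, paired by position (length >= 3).
#' @return Object of class `paired_contrast`: `n`, `mean_x`, `mean_y`, `t`,
#'   `df`, `p`, `cohens_d`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  d <- x - y
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    res <- list(n = n, mean_x = mean(x), mean_y = mean(y),
                t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                df = n - 1L,
                p = if (mean(d) == 0) 1 else 0,
                cohens_d = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                degenerate = TRUE)
  } else {
    tt <- stats::t.test(x, y, paired = TRUE)
    res <- list(n = n, mean_x = mean(x), mean_y = mean(y),
                t = unname(tt$statistic), df = n - 1L,
                p = tt$p.value,
                cohens_d = mean(d) / sd_d,
                degenerate = FALSE)
  }
  structure(res, class = "paired_contrast")
}

#' @export
print.paired_contrast <- function(x, ...) {
  cat(sprintf("paired t(%d) = %.3f, p = %.3g, Cohen's d = %.3f (n = %d)\n",
              x$df, x$t, x$p, x$cohens_d, x$n))
  invisible(x)
}

#' Correlation with two-sided p value
#'
#' Pearson (default) or Spearman correlation via [stats::cor.test()].
#'
#' @param a,b Numeric vectors of equal length (>= 4 complete pairs).
#' @param method `"pearson"` or `"spearman"`.
#' @return List `r`, `p`, `n`, `method`, `undefined` (TRUE when either
#'   vector has zero variance, in which case `r` and `p` are NA).
#' @export
correlate <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(a) == length(b))
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 4) stop("need at least 4 complete pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(a),
                method = method, undefined = TRUE))
  ct <- suppressWarnings(stats::cor.test(a, b, method = method))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a),
       method = method, undefined = FALSE)
}

#' Williams-Steiger test for two dependent correlations sharing a variable
#'
#' Tests r12 = r13 where variable 1 is shared (e.g. interoceptive accuracy
#' correlated with both meta-d' and d' in the same subjects), using
#' Williams' t — the statistic Steiger (1980) recommends and the one behind
#' the common online dependent-correlation calculators:
#' \deqn{t = (r_{12} - r_{13}) \sqrt{\frac{(n-1)(1+r_{23})}
#'   {2\frac{n-1}{n-3}|R| + \bar r^2 (1-r_{23})^3}}}
#' with \eqn{|R| = 1 - r_{12}^2 - r_{13}^2 - r_{23}^2 + 2 r_{12} r_{13}
#' r_{23}} and \eqn{\bar r = (r_{12}+r_{13})/2}; df = n - 3, two-sided p.
#'
#' @param r12,r13 The two correlations sharing variable 1.
#' @param r23 Correlation between variables 2 and 3.
#' @param n Sample size (>= 4).
#' @return Object of class `dependent_corr_test`: `r12`, `r13`, `r23`, `n`,
#'   `t`, `df`, `p`.
#' @export
steiger_test <- function(r12, r13, r23, n) {
  rs <- c(r12, r13, r23)
  if (any(abs(rs) >= 1)) stop("all correlations must lie strictly in (-1, 1)")
  if (n < 4) stop("need n >= 4")
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR < 0)
    stop("the correlation triple (r12, r13, r23) is not positive ",
         "semi-definite; no sample can realize it")
  rbar <- (r12 + r13) / 2
  denom <- 2 * (n - 1) / (n - 3) * detR + rbar^2 * (1 - r23)^3
  t <- (r12 - r13) * sqrt((n - 1) * (1 + r23) / denom)
  df <- n - 3
  structure(list(r12 = r12, r13 = r13, r23 = r23, n = n,
                 t = t, df = df,
                 p = 2 * stats::pt(-abs(t), df)),
            class = "dependent_corr_test")
}

#' @export
print.dependent_corr_test <- function(x, ...) {
  cat(sprintf(
    "dependent correlations: r12 = %.3f vs r13 = %.3f (r23 = %.3f, n = %d): t(%d) = %.3f, p = %.3g\n",
    x$r12, x$r13, x$r23, x$n, x$df, x$t, x$p))
  invisible(x)
}

#' Kruskal-Wallis comparison across groups
#'
#' Rank-based H with tie correction (via [stats::kruskal.test()]),
#' chi-square p with df = groups - 1, and the omega effect size
#' sqrt(H / N). Empty groups are dropped with a warning; if every pooled
#' observation is identical, H = 0 and p = 1.
#'
#' @param values_by_group Named list mapping group label to a numeric
#'   vector of per-subject values.
#' @return List `H`, `df`, `p`, `omega`, `n`, `groups`.
#' @export
kruskal_wallis <- function(values_by_group) {
  keep <- vapply(values_by_group, function(v) length(v[!is.na(v)]) > 0,
                 logical(1))
  if (any(!keep))
    warning("dropping empty group(s): ",
            paste(names(values_by_group)[!keep], collapse = ", "),
            call. = FALSE)
  values_by_group <- values_by_group[keep]
  if (length(values_by_group) < 2) stop("need at least 2 non-empty groups")
  x <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(names(values_by_group),
                  vapply(values_by_group, length, integer(1))))
  ok <- !is.na(x)
  x <- x[ok]; g <- droplevels(g[ok])
  df <- nlevels(g) - 1L
  if (length(unique(x)) == 1) {
    return(list(H = 0, df = df, p = 1, omega = 0, n = length(x),
                groups = levels(g)))
  }
  kt <- stats::kruskal.test(x, g)
  H <- unname(kt$statistic)
  list(H = H, df = df, p = kt$p.value,
       omega = sqrt(H / length(x)), n = length(x), groups = levels(g))
}
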