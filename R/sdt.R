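#' @title Type-1 and type-2 signal detection
#' @description Type-1 sensitivity d' = z(HR) - z(FAR) and criterion
#'   c = -(z(HR) + z(FAR))/2 for the own-heart/other-heart forced choice
#'   (signal = own-heart stimulus, "hit" = responding SELF to it). The
#'   type-2 layer bins the continuous 0-100 confidence ratings into K
#'   levels, cross-tabulates them by response side and stimulus truth, and
#'   estimates metacognitive sensitivity meta-d' by minimizing the
#'   sum-squared error between observed and model cumulative type-2
#'   hit/false-alarm rates under an equal-variance Gaussian observer whose
#'   type-1 criterion is held at the subject's relative criterion
#'   (meta_c = c' * meta-d'). meta-d' lives on the d' scale: meta-d' = d'
#'   is metacognitively optimal, meta-d' < d' indicates confidence carries
#'   less information than the type-1 decision did.
#' @name sdt
NULL

#' Type-1 signal detection statistics
#'
#' @param trials Data frame of one subject's trials (columns `stimulus`,
#'   `response`). Both stimulus classes must be present.
#' @param correction Rate correction keeping HR/FAR inside (0,1):
#'   `"loglin"` (default) adds 0.5 to each of the four type-1 cells;
#'   `"half_count"` replaces rates of 0 with 1/(2N) and 1 with 1 - 1/(2N);
#'   `"none"` leaves raw rates (d' is infinite at 0 or 1).
#' @return Object of class `type1_stats`: counts (`n_signal`, `n_noise`,
#'   `hits`, `false_alarms`), corrected rates (`HR`, `FAR`), `d_prime`,
#'   criterion `c`, and relative criterion `c_rel = c / d_prime`.
#' @export
type1_stats <- function(trials, correction = c("loglin", "half_count", "none")) {
  correction <- match.arg(correction)
  is_sig <- trials$stimulus == "SELF_HEART"
  n_signal <- sum(is_sig); n_noise <- sum(!is_sig)
  if (n_signal == 0 || n_noise == 0)
    stop("both stimulus classes must be present to compute d'")
  hits <- sum(is_sig & trials$response == "SAYS_SELF")
  fas  <- sum(!is_sig & trials$response == "SAYS_SELF")
  rate <- function(x, n) {
    switch(correction,
      loglin = (x + 0.5) / (n + 1),
      half_count = {
        r <- x / n
        if (r == 0) 1 / (2 * n) else if (r == 1) 1 - 1 / (2 * n) else r
      },
      none = x / n)
  }
  HR <- rate(hits, n_signal); FAR <- rate(fas, n_noise)
  d_prime <- stats::qnorm(HR) - stats::qnorm(FAR)
  c_crit <- -0.5 * (stats::qnorm(HR) + stats::qnorm(FAR))
  structure(list(n_signal = n_signal, n_noise = n_noise,
                 hits = hits, false_alarms = fas,
                 HR = HR, FAR = FAR,
                 d_prime = d_prime, c = c_crit,
                 c_rel = if (d_prime == 0) NA_real_ else c_crit / d_prime,
                 correction = correction),
            class = "type1_stats")
}

#' @export
print.type1_stats <- function(x, ...) {
  cat(sprintf(paste0("<type1_stats> %d/%d hits, %d/%d FAs | HR = %.3f, ",
                     "FAR = %.3f | d' = %.3f, c = %.3f\n"),
              x$hits, x$n_signal, x$false_alarms, x$n_noise,
              x$HR, x$FAR, x$d_prime, x$c))
  invisible(x)
}

#' Bin VAS confidence into K levels by within-subject quantiles
#'
#' The confidence scale is a continuous 0-100 VAS; the type-2 model needs
#' discrete rating levels. Cut points are the empirical j/K quantiles of the
#' subject's own ratings (protecting against idiosyncratic scale use);
#' values falling exactly on a cut point go to the lower level.
#'
#' @param trials Data frame with a `confidence` column.
#' @param K Number of levels (>= 2). Requires at least K distinct
#'   confidence values, and strictly increasing quantile cut points.
#' @return List with `scheme` (fields `K`, `edges`: the K-1 cut points) and
#'   `trials`: the input with an integer `conf_level` column in 1..K.
#' @export
bin_confidence <- function(trials, K = 4L) {
  K <- as.integer(K)
  if (K < 2) stop("K must be >= 2")
  conf <- trials$confidence
  if (length(unique(conf)) < K)
    stop("fewer than K = ", K, " distinct confidence values; ",
         "use a smaller K")
  edges <- stats::quantile(conf, probs = seq_len(K - 1) / K,
                           names = FALSE, type = 7)
  if (any(diff(edges) <= 0) || length(unique(edges)) < K - 1)
    stop("confidence quantiles are tied; too few distinct values for K = ",
         K, " - use a smaller K")
  level <- findInterval(conf, edges, left.open = TRUE) + 1L
  trials$conf_level <- level
  list(scheme = list(K = K, edges = edges), trials = trials)
}

#' Construct a type-2 count table directly
#'
#' For each response side, a 2 x K matrix of confidence-level counts with
#' rows `SELF_HEART`/`OTHER_HEART` (stimulus truth) and columns levels
#' 1..K. Mostly used by [type2_counts()]; exposed so model-generated
#' (possibly non-integer) expected counts can be fitted directly.
#'
#' @param self,other 2 x K matrices of counts for responses `SAYS_SELF` and
#'   `SAYS_OTHER`.
#' @param padded Whether zero-cell padding has already been applied.
#' @return Object of class `type2_counts`.
#' @export
new_type2_counts <- function(self, other, padded = FALSE) {
  stopifnot(is.matrix(self), is.matrix(other),
            nrow(self) == 2, nrow(other) == 2,
            ncol(self) == ncol(other))
  rownames(self) <- rownames(other) <- stimulus_levels
  structure(list(self = self, other = other, K = ncol(self),
                 padded = padded, total = sum(self) + sum(other)),
            class = "type2_counts")
}

#' Cross-tabulate binned trials into type-2 counts
#'
#' Counts trials by response side x stimulus truth x confidence level. If
#' any cell of a response side is empty, 1/(2K) is added to every cell of
#' that side (only), keeping the side's observed cumulative rates strictly
#' inside (0, 1) with minimal distortion.
#'
#' @param binned Result of [bin_confidence()] (or a data frame with
#'   `stimulus`, `response`, `conf_level`).
#' @param K Number of levels; taken from the binning scheme if `binned`
#'   came from [bin_confidence()].
#' @return Object of class `type2_counts`; `$raw` holds the unpadded
#'   tables, `$self`/`$other` the (possibly padded) tables used for fitting.
#' @export
type2_counts <- function(binned, K = NULL) {
  if (is.list(binned) && !is.data.frame(binned) && !is.null(binned$scheme)) {
    K <- binned$scheme$K
    trials <- binned$trials
  } else {
    trials <- binned
    if (is.null(K)) K <- max(trials$conf_level)
  }
  tab_side <- function(resp) {
    sub <- trials[trials$response == resp, , drop = FALSE]
    t(sapply(stimulus_levels, function(s) {
      tabulate(sub$conf_level[sub$stimulus == s], nbins = K)
    }))
  }
  self <- tab_side("SAYS_SELF"); other <- tab_side("SAYS_OTHER")
  raw <- list(self = self, other = other)
  pad <- 1 / (2 * K)
  padded_sides <- character(0)
  if (any(self == 0)) { self <- self + pad; padded_sides <- "SAYS_SELF" }
  if (any(other == 0)) {
    other <- other + pad
    padded_sides <- c(padded_sides, "SAYS_OTHER")
  }
  out <- new_type2_counts(self, other, padded = length(padded_sides) > 0)
  out$raw <- raw
  out$padded_sides <- padded_sides
  out$total <- sum(raw$self) + sum(raw$other)
  out
}

# Observed cumulative type-2 probabilities P(conf >= j | stimulus, response)
# for j = 2..K, per response side. Rows: stimulus truth; cols: levels 2..K.
observed_t2_probs <- function(counts) {
  cum <- function(m) {
    cc <- t(apply(m, 1, function(r) rev(cumsum(rev(r))) / sum(r)))
    cc[, -1, drop = FALSE]
  }
  list(self = cum(counts$self), other = cum(counts$other))
}

#' Model cumulative type-2 probabilities of the meta-d' observer
#'
#' Equal-variance Gaussian observer with sensitivity `meta_d` (stimulus
#' means +/- meta_d/2, unit variance) and type-1 criterion fixed at
#' `meta_c = c_rel * meta_d`. For response `SAYS_SELF` and type-2 criterion
#' q >= meta_c, P(conf >= level | stimulus s, SAYS_SELF) =
#' (1 - Phi(q - mu_s)) / (1 - Phi(meta_c - mu_s)); the `SAYS_OTHER` side
#' uses the mirrored lower-tail ratio with criteria below meta_c.
#'
#' @param meta_d Metacognitive sensitivity.
#' @param c_rel Relative type-1 criterion c' = c/d' (from [type1_stats()]).
#' @param t2_self Increasing vector of K-1 type-2 criteria >= meta_c.
#' @param t2_other Decreasing vector of K-1 type-2 criteria <= meta_c.
#' @return List of two 2 x (K-1) matrices (`self`, `other`): cumulative
#'   P(conf >= j | stimulus, response) for j = 2..K, rows = stimulus truth.
#' @export
metad_t2_probs <- function(meta_d, c_rel, t2_self, t2_other) {
  meta_c <- c_rel * meta_d
  mu <- c(SELF_HEART = meta_d / 2, OTHER_HEART = -meta_d / 2)
  eps <- 1e-12
  self <- matrix(NA_real_, 2, length(t2_self),
                 dimnames = list(stimulus_levels, NULL))
  other <- matrix(NA_real_, 2, length(t2_other),
                  dimnames = list(stimulus_levels, NULL))
  for (i in 1:2) {
    m <- mu[i]
    self[i, ] <- (1 - stats::pnorm(t2_self - m)) /
      max(1 - stats::pnorm(meta_c - m), eps)
    other[i, ] <- stats::pnorm(t2_other - m) /
      max(stats::pnorm(meta_c - m), eps)
  }
  list(self = self, other = other)
}

#' Sum-squared error of a meta-d' parameterization
#'
#' The objective minimized by [fit_meta_d()]: squared differences between
#' observed and model cumulative type-2 probabilities (type-2 hit and
#' false-alarm rates at each of the K-1 levels, both response sides).
#'
#' @param counts A `type2_counts` object.
#' @param t1 A [type1_stats()] object (supplies `c_rel`).
#' @param meta_d,t2_self,t2_other Candidate parameters; see
#'   [metad_t2_probs()].
#' @return The SSE (scalar >= 0).
#' @export
metad_sse <- function(counts, t1, meta_d, t2_self, t2_other) {
  obs <- observed_t2_probs(counts)
  mod <- metad_t2_probs(meta_d, t1$c_rel, t2_self, t2_other)
  sum((obs$self - mod$self)^2) + sum((obs$other - mod$other)^2)
}

#' Fit meta-d' by sum-squared-error minimization
#'
#' Jointly estimates `meta_d` and the 2(K-1) type-2 criteria minimizing
#' [metad_sse()]. The type-1 criterion of the model observer is locked to
#' `meta_c = c_rel * meta_d` so that meta-d' is directly comparable to d';
#' monotonicity of the criteria is enforced by optimizing log-increments
#' away from `meta_c`; `meta_d` is restricted to [-5, 5]. Derivative-free
#' (Nelder-Mead) local search from multiple seeded restarts.
#'
#' @param counts A `type2_counts` object.
#' @param t1 The subject's [type1_stats()] (requires `d_prime != 0`).
#' @param n_restarts Number of random restarts (default 8).
#' @param tol Convergence tolerance on the SSE improvement across restarts.
#' @param seed Optional integer seed making the restarts reproducible.
#' @param max_iter Nelder-Mead iteration cap per restart.
#' @return Object of class `meta_fit`: `meta_d`, `meta_c`,
#'   `t2_criteria_self`, `t2_criteria_other`, `sse`, `m_ratio`
#'   (= meta_d / d_prime), `converged`, `n_restarts_used`.
#' @export
fit_meta_d <- function(counts, t1, n_restarts = 8L, tol = 1e-6, seed = NULL,
                       max_iter = 2000L) {
  stopifnot(inherits(counts, "type2_counts"), inherits(t1, "type1_stats"))
  if (!is.finite(t1$d_prime) || t1$d_prime == 0 || is.na(t1$c_rel))
    stop("meta-d' requires a nonzero, finite type-1 d'")
  K <- counts$K
  obs <- observed_t2_probs(counts)
  c_rel <- t1$c_rel

  unpack <- function(theta) {
    md <- theta[1]
    meta_c <- c_rel * md
    a <- theta[2:K]
    b <- theta[(K + 1):(2 * K - 1)]
    list(md = md,
         q = meta_c + cumsum(exp(pmin(a, 20))),
         r = meta_c - cumsum(exp(pmin(b, 20))))
  }
  objective <- function(theta) {
    p <- unpack(theta)
    pen <- if (abs(p$md) > 5) 1e6 * (abs(p$md) - 5)^2 else 0
    mod <- metad_t2_probs(p$md, c_rel, p$q, p$r)
    sum((obs$self - mod$self)^2) + sum((obs$other - mod$other)^2) + pen
  }

  starts <- with_seed(seed, {
    md0 <- max(min(t1$d_prime, 4.5), -4.5)
    base <- c(md0, rep(log(0.5), 2 * (K - 1)))
    c(list(base), lapply(seq_len(max(n_restarts - 1, 0)), function(i)
      c(md0 + stats::rnorm(1, 0, 1),
        log(stats::runif(2 * (K - 1), 0.1, 1.5)))))
  })

  best <- NULL
  used <- 0L
  for (th0 in starts) {
    used <- used + 1L
    fit <- stats::optim(th0, objective, method = "Nelder-Mead",
                        control = list(maxit = max_iter, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value < tol && used >= 2) break
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("meta-d' fit failed to produce a finite SSE after ", used,
         " restarts")
  }
  p <- unpack(best$par)
  md <- max(min(p$md, 5), -5)
  structure(list(meta_d = md,
                 meta_c = c_rel * md,
                 t2_criteria_self = p$q,
                 t2_criteria_other = p$r,
                 sse = metad_sse(counts, t1, md, p$q, p$r),
                 m_ratio = md / t1$d_prime,
                 converged = best$convergence == 0 || best$value < tol,
                 n_restarts_used = used,
                 K = K),
            class = "meta_fit")
}

#' @export
print.meta_fit <- function(x, ...) {
  cat(sprintf(paste0("<meta_fit> meta-d' = %.3f (meta-c = %.3f), ",
                     "M-ratio = %.3f, SSE = %.3g, converged = %s\n"),
              x$meta_d, x$meta_c, x$m_ratio, x$sse, x$converged))
  invisible(x)
}

#' Contrast metacognitive and type-1 sensitivity
#'
#' @param t1 A [type1_stats()] object.
#' @param fit A [fit_meta_d()] object.
#' @return List with `diff = meta_d - d_prime`, `m_ratio = meta_d/d_prime`,
#'   and `undefined` (TRUE when d' = 0, in which case `m_ratio` is NA).
#' @export
meta_contrast <- function(t1, fit) {
  if (t1$d_prime == 0)
    return(list(diff = NA_real_, m_ratio = NA_real_, undefined = TRUE))
  list(diff = fit$meta_d - t1$d_prime,
       m_ratio = fit$meta_d / t1$d_prime,
       undefined = FALSE)
}
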