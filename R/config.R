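#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline: expected trial count,
#' significance level of the binomial chance criterion, number of confidence
#' bins used to discretize the 0-100 VAS ratings for the type-2 model, the
#' type-1 rate correction, and the seed controlling the meta-d' optimizer
#' restarts.
#'
#' @param n_trials_expected Expected number of forced-choice trials per
#'   subject (default 30). Subjects with a different count are analysed with
#'   their actual count, with a warning.
#' @param alpha_chance Significance level of the binomial chance criterion
#'   used to classify subjects (default 0.05).
#' @param n_confidence_bins Number of confidence levels \eqn{K} the VAS
#'   ratings are binned into for the type-2 model (default 4, must be >= 2).
#' @param rate_correction How type-1 hit/false-alarm rates are kept inside
#'   (0, 1): `"loglin"` adds 0.5 to all four type-1 cells; `"half_count"`
#'   replaces 0 with 1/(2N) and 1 with 1 - 1/(2N); `"none"` uses raw rates.
#' @param seed Integer seed for the meta-d' fit restarts and any simulation
#'   run through the pipeline.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(n_trials_expected = 30L,
                            alpha_chance = 0.05,
                            n_confidence_bins = 4L,
                            rate_correction = c("loglin", "half_count", "none"),
                            seed = 1L) {
  rate_correction <- match.arg(rate_correction)
  if (!(is.numeric(alpha_chance) && length(alpha_chance) == 1 &&
        alpha_chance > 0 && alpha_chance < 1))
    stop("`alpha_chance` must be a single number strictly between 0 and 1")
  n_confidence_bins <- as.integer(n_confidence_bins)
  if (is.na(n_confidence_bins) || n_confidence_bins < 2)
    stop("`n_confidence_bins` (K) must be an integer >= 2")
  structure(
    list(n_trials_expected = as.integer(n_trials_expected),
         alpha_chance = alpha_chance,
         n_confidence_bins = n_confidence_bins,
         rate_correction = rate_correction,
         seed = as.integer(seed)),
    class = "analysis_config")
}

#' Round half away from zero
#'
#' Display rounding used in reports: 0.5 rounds to 1, -0.5 to -1, unlike
#' base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stimulus_levels <- c("SELF_HEART", "OTHER_HEART")
response_levels <- c("SAYS_SELF", "SAYS_OTHER")
task_levels     <- c("HEART_SOUND", "BEEP_CONTROL")
group_levels    <- c("SELF", "NON_DISCRIMINATOR", "OTHER")
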