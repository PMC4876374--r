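#' @title Gaussian SDT observer simulator
#' @description Generates trial-level datasets with the statistical
#'   structure the analysis assumes: a balanced 15/15 own/other stimulus
#'   sequence, binary responses from an equal-variance Gaussian observer
#'   (decision variable x ~ N(+/- d'/2, 1) against a criterion c), and
#'   0-100 VAS confidence produced from secondary "type-2" evidence
#'   x2 = x + N(0, sigma_meta). sigma_meta = 0 is the metacognitively ideal
#'   observer (meta-d' = d' in the large-sample limit); larger sigma_meta
#'   degrades confidence resolution, approximately as
#'   meta-d' ~ d'/sqrt(1 + sigma_meta^2). Cohort generation couples
#'   heartbeat-counting accuracy to metacognitive efficiency through a
#'   Gaussian copula, and a deterministic fixture reproduces the published
#'   group-count table for both tasks.
#' @name synthetic
NULL

#' Simulation configuration
#'
#' Defaults describe the studied cohort: 27 subjects, 30 trials (15 own +
#' 15 other), mean sensitivity d' = 0.8 (between-subject sd 0.23), neutral
#' criterion, metacognitive noise sd 1 (calibrated so the large-sample
#' meta-d' at d' = 0.8 is near 0.3), counting-task accuracy mean 0.75 /
#' sd 0.21, and a 0.4
#' correlation between metacognitive efficiency and counting accuracy.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials Trials per subject (even; split half/half by stimulus).
#' @param d_prime_gen Generating type-1 sensitivity.
#' @param c_gen Generating type-1 criterion.
#' @param sigma_meta Metacognitive noise sd (>= 0; 0 = ideal observer).
#' @param conf_scale Monotone map from type-2 evidence distance
#'   `|x2 - c_gen|` to the 0-100 VAS; default `100 * (2 * pnorm(d) - 1)`.
#' @param iacc_mean,iacc_sd Mean and sd of the counting-task accuracy
#'   distribution (Beta-distributed on (0, 1)).
#' @param rho_meta_iacc Target correlation between metacognitive efficiency
#'   and counting accuracy, in [-1, 1].
#' @param seed Integer seed; all generation is reproducible from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 27L, n_trials = 30L,
                       d_prime_gen = 0.8, c_gen = 0, sigma_meta = 1,
                       conf_scale = function(d) 100 * (2 * stats::pnorm(d) - 1),
                       iacc_mean = 0.75, iacc_sd = 0.21,
                       rho_meta_iacc = 0.4, seed = 1L) {
  if (sigma_meta < 0) stop("sigma_meta must be >= 0")
  if (abs(rho_meta_iacc) > 1) stop("rho_meta_iacc must lie in [-1, 1]")
  if (n_trials %% 2 != 0) stop("n_trials must be even (balanced design)")
  if (iacc_sd^2 >= iacc_mean * (1 - iacc_mean))
    stop("iacc_sd too large for a Beta distribution with mean ", iacc_mean)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials),
                 d_prime_gen = d_prime_gen, c_gen = c_gen,
                 sigma_meta = sigma_meta, conf_scale = conf_scale,
                 iacc_mean = iacc_mean, iacc_sd = iacc_sd,
                 rho_meta_iacc = rho_meta_iacc, seed = as.integer(seed)),
            class = "sim_config")
}

# Heartbeat-counting records for one subject with per-subject undercounting
# rate e: counted = round(recorded * (1 - e)), so the accuracy index is
# approximately 1 - e by construction.
simulate_counting <- function(subject_id, error_rate,
                              intervals = c(25, 35, 45, 100)) {
  hr <- max(stats::rnorm(1, 70, 8), 45)
  recorded <- pmax(round(intervals * hr / 60), 1)
  counted <- pmax(round(recorded * (1 - max(error_rate, 0))), 0)
  data.frame(subject_id = subject_id, interval_s = intervals,
             counted = counted, recorded = recorded,
             stringsAsFactors = FALSE)
}

#' Simulate one subject's forced-choice session
#'
#' Balanced stimulus sequence in random order; per trial the decision
#' variable is x ~ N(+d'/2, 1) for the own-heart stimulus and N(-d'/2, 1)
#' otherwise, the response is SAYS_SELF iff x > c, the type-2 evidence is
#' x2 = x + N(0, sigma_meta), and confidence = `conf_scale(|x2 - c|)`.
#'
#' @param cfg A [sim_config()].
#' @param subject_seed Seed for this subject (reproducible independently of
#'   any cohort context).
#' @param subject_id Identifier (default derived from the seed).
#' @param d_prime,c_crit,sigma_meta Per-subject overrides of the generating
#'   parameters (used by [simulate_cohort()]).
#' @param iacc_error Optional counting-task error rate; when given, four
#'   canonical counting intervals are generated as well.
#' @return A [subject_dataset()].
#' @export
simulate_subject <- function(cfg, subject_seed,
                             subject_id = paste0("sim", subject_seed),
                             d_prime = cfg$d_prime_gen,
                             c_crit = cfg$c_gen,
                             sigma_meta = cfg$sigma_meta,
                             iacc_error = NULL) {
  with_seed(subject_seed, {
    n <- cfg$n_trials
    stim <- sample(rep(stimulus_levels, each = n / 2))
    mu <- ifelse(stim == "SELF_HEART", d_prime / 2, -d_prime / 2)
    x <- stats::rnorm(n, mu, 1)
    resp <- ifelse(x > c_crit, "SAYS_SELF", "SAYS_OTHER")
    x2 <- x + stats::rnorm(n, 0, sigma_meta)
    conf <- pmin(pmax(cfg$conf_scale(abs(x2 - c_crit)), 0), 100)
    trials <- data.frame(subject_id = subject_id, trial_index = seq_len(n),
                         stimulus = stim, response = resp, confidence = conf,
                         stringsAsFactors = FALSE)
    counting <- if (!is.null(iacc_error))
      simulate_counting(subject_id, iacc_error) else NULL
    subject_dataset(subject_id, trials, counting, task_tag = "HEART_SOUND")
  })
}

#' Simulate a heterogeneous cohort with latent truth
#'
#' Per-subject latent parameters are drawn around the configured values:
#' d' ~ N(`d_prime_gen`, `sd_d_prime`), c ~ N(`c_gen`, `sd_c`), and
#' sigma_meta is log-normally scattered (sd `sigma_meta_sdlog` on the log
#' scale) around `sigma_meta`. Counting accuracy is Beta(`iacc_mean`,
#' `iacc_sd`) and coupled to metacognitive efficiency via a Gaussian
#' copula: the normal score driving low sigma_meta and the score driving
#' high counting accuracy correlate at `rho_meta_iacc`.
#'
#' @param cfg A [sim_config()].
#' @param heterogeneity List with `sd_d_prime` (default 0.23), `sd_c`
#'   (default 0.2), `sigma_meta_sdlog` (default 0.3).
#' @return List with `cohort` (list of [subject_dataset()]) and `latent`
#'   (data frame of the generating per-subject parameters, for recovery
#'   tests).
#' @export
simulate_cohort <- function(cfg,
                            heterogeneity = list(sd_d_prime = 0.23,
                                                 sd_c = 0.2,
                                                 sigma_meta_sdlog = 0.3)) {
  h <- utils::modifyList(list(sd_d_prime = 0.23, sd_c = 0.2,
                              sigma_meta_sdlog = 0.3),
                         as.list(heterogeneity))
  rho <- cfg$rho_meta_iacc
  with_seed(cfg$seed, {
    n <- cfg$n_subjects
    z1 <- stats::rnorm(n)                       # metacognitive efficiency score
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)  # counting score
    d_i <- stats::rnorm(n, cfg$d_prime_gen, h$sd_d_prime)
    c_i <- stats::rnorm(n, cfg$c_gen, h$sd_c)
    sm_i <- cfg$sigma_meta * exp(h$sigma_meta_sdlog * (-z1))
    m <- cfg$iacc_mean; v <- cfg$iacc_sd^2
    k <- m * (1 - m) / v - 1
    iacc_i <- stats::qbeta(stats::pnorm(z2), m * k, (1 - m) * k)
    seeds <- sample.int(.Machine$integer.max, n)
    ids <- sprintf("S%03d", seq_len(n))
    cohort <- lapply(seq_len(n), function(i)
      simulate_subject(cfg, seeds[i], subject_id = ids[i],
                       d_prime = d_i[i], c_crit = c_i[i],
                       sigma_meta = sm_i[i], iacc_error = 1 - iacc_i[i]))
    list(cohort = cohort,
         latent = data.frame(subject_id = ids, d_prime = d_i, c = c_i,
                             sigma_meta = sm_i, iacc_true = iacc_i,
                             seed = seeds, stringsAsFactors = FALSE))
  })
}

#' Deterministic fixture reproducing the published group-count table
#'
#' Builds a cohort whose per-subject correct-trial counts realize exactly
#' the published group distribution: for the heart-sound task, 27 subjects
#' of whom 17 score 23/30 (SELF), 7 score 15/30 (NON_DISCRIMINATOR) and 3
#' score 7/30 (OTHER); for the beep control task, 16 subjects split 3
#' (26/30), 11 (15/30) and 2 (4/30). Stimuli are laid out 15 own + 15
#' other; responses realize the hit/correct-rejection split; confidences
#' are a fixed deterministic cycle of 30 distinct values (the fixture's
#' type-2 structure is arbitrary and carries no metacognitive signal).
#'
#' @param task `"heart"` (default) or `"beep"`.
#' @return List of [subject_dataset()] objects.
#' @export
make_table1_cohort <- function(task = c("heart", "beep")) {
  task <- match.arg(task)
  spec <- if (task == "heart") {
    data.frame(n_subj = c(17L, 7L, 3L), hits = c(12L, 8L, 4L),
               crs = c(11L, 7L, 3L))
  } else {
    data.frame(n_subj = c(3L, 11L, 2L), hits = c(13L, 8L, 2L),
               crs = c(13L, 7L, 2L))
  }
  tag <- if (task == "heart") "HEART_SOUND" else "BEEP_CONTROL"
  prefix <- if (task == "heart") "S" else "B"
  out <- list()
  s <- 0L
  for (g in seq_len(nrow(spec))) {
    for (i in seq_len(spec$n_subj[g])) {
      s <- s + 1L
      id <- sprintf("%s%02d", prefix, s)
      stim <- rep(stimulus_levels, each = 15L)
      resp <- c(rep("SAYS_SELF", spec$hits[g]),
                rep("SAYS_OTHER", 15L - spec$hits[g]),
                rep("SAYS_OTHER", spec$crs[g]),
                rep("SAYS_SELF", 15L - spec$crs[g]))
      idx <- 1:30
      conf <- ((idx * 7L + s) %% 30L) * 3 + 1   # 30 distinct values in [1, 88]
      trials <- data.frame(subject_id = id, trial_index = idx,
                           stimulus = stim, response = resp,
                           confidence = conf, stringsAsFactors = FALSE)
      out[[s]] <- subject_dataset(id, trials, task_tag = tag)
    }
  }
  out
}

# Number of correct forced-choice trials in a trials data frame.
count_correct <- function(trials) {
  sum((trials$stimulus == "SELF_HEART" & trials$response == "SAYS_SELF") |
      (trials$stimulus == "OTHER_HEART" & trials$response == "SAYS_OTHER"))
}
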