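# Shared fixtures and small oracles, built in code.

# Trials data frame with given type-1 cell counts (balanced n/2 per
# stimulus), deterministic distinct confidences.
make_trials <- function(hits, misses, fas, crs, subject_id = "T1") {
  stim <- c(rep("SELF_HEART", hits + misses), rep("OTHER_HEART", fas + crs))
  resp <- c(rep("SAYS_SELF", hits), rep("SAYS_OTHER", misses),
            rep("SAYS_SELF", fas), rep("SAYS_OTHER", crs))
  n <- length(stim)
  data.frame(subject_id = subject_id, trial_index = seq_len(n),
             stimulus = stim, response = resp,
             confidence = ((seq_len(n) * 7) %% n) * (99 / n),
             stringsAsFactors = FALSE)
}

# Expected per-level type-2 counts generated analytically from the meta-d'
# observer model itself (cumulative probabilities -> level masses x side
# totals). `n_self`/`n_other`: trials per stimulus row for each response.
analytic_t2_counts <- function(meta_d, c_rel, t2_self, t2_other,
                               n_self = c(600, 300), n_other = c(300, 600)) {
  pr <- metad_t2_probs(meta_d, c_rel, t2_self, t2_other)
  level_mass <- function(cum, n) {
    t(apply(cbind(1, cum), 1, function(row) -diff(c(row, 0)))) * n
  }
  new_type2_counts(level_mass(pr$self, n_self),
                   level_mass(pr$other, n_other), padded = TRUE)
}

# Exact-integer Pearson chi2 oracle for equal expected counts:
# chi2 = (k * sum(O^2) - N^2) / N, derived by expanding sum((O - N/k)^2/(N/k)).
chi2_equal_oracle <- function(observed) {
  k <- length(observed); N <- sum(observed)
  (k * sum(observed^2) - N^2) / N
}

# Fit a simulated observer end to end; returns list(t1, fit).
fit_observer <- function(n_trials, d_prime, c_crit = 0, sigma_meta = 0,
                         subject_seed = 1, fit_seed = 1, K = 4) {
  cfg <- sim_config(n_trials = n_trials, d_prime_gen = d_prime,
                    c_gen = c_crit, sigma_meta = sigma_meta)
  ds <- simulate_subject(cfg, subject_seed)
  t1 <- type1_stats(ds$trials)
  fit <- fit_meta_d(type2_counts(bin_confidence(ds$trials, K)), t1,
                    seed = fit_seed)
  list(t1 = t1, fit = fit, trials = ds$trials)
}

# The Table-1 fixture pipeline run is used by several files; compute once.
.fixture_cache <- new.env(parent = emptyenv())
table1_result <- function() {
  if (is.null(.fixture_cache$res))
    .fixture_cache$res <- run_pipeline(make_table1_cohort(),
                                       cfg = analysis_config(seed = 1))
  .fixture_cache$res
}
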