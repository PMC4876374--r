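test_that("simulated hit rate matches the closed-form normal tail", {
  cfg <- sim_config(n_trials = 10000, d_prime_gen = 1.5, c_gen = 0,
                    sigma_meta = 0)
  ds <- simulate_subject(cfg, 3)
  t1 <- type1_stats(ds$trials, "none")
  expect_equal(t1$HR, pnorm(0.75), tolerance = 0.02)
  expect_equal(t1$FAR, pnorm(-0.75), tolerance = 0.02)
})

test_that("long-run accuracy matches the two-class closed form", {
  # accuracy -> (Phi(d/2 - c) + Phi(d/2 + c)) / 2
  for (pars in list(c(0, 0), c(1, 0.4), c(0.8, -0.3))) {
    d <- pars[1]; cc <- pars[2]
    cfg <- sim_config(n_trials = 20000, d_prime_gen = d, c_gen = cc)
    ds <- simulate_subject(cfg, 17)
    acc <- sum(
      (ds$trials$stimulus == "SELF_HEART" &
         ds$trials$response == "SAYS_SELF") |
      (ds$trials$stimulus == "OTHER_HEART" &
         ds$trials$response == "SAYS_OTHER")) / 20000
    expect_equal(acc, (pnorm(d / 2 - cc) + pnorm(d / 2 + cc)) / 2,
                 tolerance = 0.02, info = paste(pars, collapse = ","))
  }
})

test_that("generation is deterministic given the seed", {
  cfg <- sim_config(n_trials = 30)
  a <- simulate_subject(cfg, 99)
  b <- simulate_subject(cfg, 99)
  expect_identical(a$trials, b$trials)
  s1 <- simulate_cohort(sim_config(n_subjects = 4, seed = 7))
  s2 <- simulate_cohort(sim_config(n_subjects = 4, seed = 7))
  expect_identical(s1$latent, s2$latent)
  expect_identical(s1$cohort[[3]]$trials, s2$cohort[[3]]$trials)
})

test_that("confidence is a monotone map of type-2 evidence", {
  cfg <- sim_config()
  d <- seq(0, 6, by = 0.1)
  conf <- cfg$conf_scale(d)
  expect_true(all(diff(conf) > 0))
  expect_true(all(conf >= 0 & conf <= 100))
  ds <- simulate_subject(sim_config(n_trials = 2000), 5)
  expect_true(all(ds$trials$confidence >= 0 & ds$trials$confidence <= 100))
})

test_that("cohort latents realize the metacognition-interoception coupling", {
  cfg <- sim_config(n_subjects = 3000, rho_meta_iacc = 0.4, seed = 2)
  sim <- simulate_cohort(cfg)
  lat <- sim$latent
  # on the copula's normal-score scale the coupling is exactly rho;
  # rank-based normal scores avoid relying on the Beta inverse
  eff_score <- -log(lat$sigma_meta)          # linear in the efficiency score
  expect_equal(cor(eff_score, qnorm(rank(lat$iacc_true) /
                                      (nrow(lat) + 1))),
               0.4, tolerance = 0.05)
  expect_lt(abs(mean(lat$iacc_true) - 0.75), 0.02)
  expect_lt(abs(sd(lat$iacc_true) - 0.21), 0.02)
  expect_lt(abs(mean(lat$d_prime) - 0.8), 0.02)
})

test_that("counting records keep the accuracy index near 1 - error rate", {
  cfg <- sim_config()
  ds <- simulate_subject(cfg, 11, iacc_error = 0.2)
  expect_equal(nrow(ds$counting), 4)
  expect_equal(ds$counting$interval_s, c(25, 35, 45, 100))
  s <- schandry_index(ds$counting)
  expect_equal(s$score, 0.8, tolerance = 0.03)
  expect_true(all(ds$counting$recorded >= 1))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(rho_meta_iacc = 1.5), "rho")
  expect_error(sim_config(sigma_meta = -1), "sigma_meta")
  expect_error(sim_config(n_trials = 31), "even")
  expect_error(sim_config(iacc_mean = 0.5, iacc_sd = 0.6), "Beta")
})

test_that("the fixture cohort reproduces the published group counts", {
  coh <- make_table1_cohort()
  expect_length(coh, 27)
  model <- build_chance_model(30, 0.5, 0.05)
  n_corr <- vapply(coh, function(d) sum(
    (d$trials$stimulus == "SELF_HEART" & d$trials$response == "SAYS_SELF") |
    (d$trials$stimulus == "OTHER_HEART" & d$trials$response == "SAYS_OTHER")),
    integer(1))
  groups <- classify_subject(n_corr, model)
  tab <- table(factor(groups, levels = c("SELF", "NON_DISCRIMINATOR",
                                         "OTHER")))
  expect_equal(as.integer(tab), c(17L, 7L, 3L))
  expect_equal(round_half_away(100 * as.integer(tab) / 27),
               c(63, 26, 11))
  expect_equal(round_half_away(gof_chi2(as.integer(tab))$chi2, 1), 11.6)

  beep <- make_table1_cohort("beep")
  expect_length(beep, 16)
  nb <- vapply(beep, function(d) sum(
    (d$trials$stimulus == "SELF_HEART" & d$trials$response == "SAYS_SELF") |
    (d$trials$stimulus == "OTHER_HEART" & d$trials$response == "SAYS_OTHER")),
    integer(1))
  tb <- table(factor(classify_subject(nb, model),
                     levels = c("SELF", "NON_DISCRIMINATOR", "OTHER")))
  expect_equal(as.integer(tb), c(3L, 11L, 2L))
})

test_that("cohort generation supports directional metacognition recovery", {
  # scaled-down latent-coupling recovery: estimated efficiency correlates
  # positively with counting accuracy when the generator couples them
  cfg <- sim_config(n_subjects = 60, n_trials = 400, d_prime_gen = 1.2,
                    sigma_meta = 1, rho_meta_iacc = 0.6, seed = 14)
  sim <- simulate_cohort(cfg, heterogeneity = list(sd_d_prime = 0.15,
                                                   sd_c = 0.1,
                                                   sigma_meta_sdlog = 0.6))
  mr <- vapply(seq_along(sim$cohort), function(i) {
    tr <- sim$cohort[[i]]$trials
    t1 <- type1_stats(tr)
    fit <- tryCatch(fit_meta_d(type2_counts(bin_confidence(tr, 4)), t1,
                               n_restarts = 4, seed = i),
                    error = function(e) NULL)
    if (is.null(fit)) NA_real_ else fit$m_ratio
  }, numeric(1))
  iacc <- sim$latent$iacc_true
  ok <- !is.na(mr)
  expect_gt(sum(ok), 50)
  expect_gt(cor(mr[ok], iacc[ok]), 0.1)
})
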