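test_that("type-1 statistics match hand-computed corrected rates", {
  tr <- make_trials(hits = 11, misses = 4, fas = 4, crs = 11)
  t1 <- type1_stats(tr, "loglin")
  expect_equal(t1$HR, 11.5 / 16)
  expect_equal(t1$FAR, 4.5 / 16)
  expect_equal(t1$d_prime, 1.159, tolerance = 2e-3)  # normal-table value
  expect_equal(t1$c, 0, tolerance = 1e-12)           # symmetric design

  # swapping hit and FA counts negates d' and c
  sw <- type1_stats(make_trials(4, 11, 11, 4), "loglin")
  expect_equal(sw$d_prime, -t1$d_prime, tolerance = 1e-12)

  # HR = FAR => d' = 0 and undefined relative criterion
  nd <- type1_stats(make_trials(8, 7, 8, 7), "loglin")
  expect_equal(nd$d_prime, 0)
  expect_true(is.na(nd$c_rel))
})

test_that("rate corrections behave at the boundaries", {
  perfect <- make_trials(15, 0, 0, 15)
  t_half <- type1_stats(perfect, "half_count")
  expect_equal(t_half$HR, 1 - 1 / 30)
  expect_equal(t_half$FAR, 1 / 30)
  t_log <- type1_stats(perfect, "loglin")
  expect_equal(t_log$HR, 15.5 / 16)
  t_raw <- type1_stats(perfect, "none")
  expect_true(is.infinite(t_raw$d_prime))
  only_self <- make_trials(15, 0, 15, 0)
  expect_error(type1_stats(only_self[only_self$stimulus == "SELF_HEART", ]),
               "both stimulus classes")
})

test_that("confidence binning is an equal-mass quantile split with ties down", {
  tr <- data.frame(confidence = (0:99) + 0.5)
  b <- bin_confidence(tr, 4)
  expect_equal(unname(table(b$trials$conf_level)), rep(25L, 4),
               ignore_attr = TRUE)
  expect_true(all(b$scheme$edges > 20 & b$scheme$edges < 80))
  expect_equal(length(b$scheme$edges), 3)

  # a value equal to a cut point goes to the lower level
  tr2 <- data.frame(confidence = c(1, 2, 2, 3))
  b2 <- bin_confidence(tr2, 2)
  expect_equal(b2$scheme$edges, 2)
  expect_equal(b2$trials$conf_level, c(1L, 1L, 1L, 2L))

  expect_error(bin_confidence(data.frame(confidence = rep(50, 30)), 4),
               "smaller K")
  expect_error(bin_confidence(data.frame(confidence = c(1, 2, 3)), 4),
               "smaller K")
})

test_that("type-2 counts conserve trials and pad only empty sides", {
  tr <- make_trials(11, 4, 4, 11)
  cts <- type2_counts(bin_confidence(tr, 4))
  expect_equal(cts$total, 30)
  expect_equal(sum(cts$raw$self) + sum(cts$raw$other), 30)

  # all responses on one side: the other side is all-zero and gets padded
  one_sided <- make_trials(15, 0, 15, 0)
  cts1 <- type2_counts(bin_confidence(one_sided, 4))
  expect_true(all(cts1$raw$other == 0))
  expect_true("SAYS_OTHER" %in% cts1$padded_sides)
  expect_true(all(cts1$other == 1 / 8))
})

test_that("observed cumulative type-2 rates match the generating model", {
  # ideal observer (no metacognitive noise): the analytic conditional
  # truncated-normal probabilities are known exactly
  d <- 1; cc <- 0.3
  cfg <- sim_config(n_trials = 10000, d_prime_gen = d, c_gen = cc,
                    sigma_meta = 0)
  ds <- simulate_subject(cfg, 21)
  b <- bin_confidence(ds$trials, 4)
  cts <- type2_counts(b)
  # invert the confidence map at the bin edges: conf = 100(2*Phi(t)-1)
  t_edges <- qnorm((b$scheme$edges / 100 + 1) / 2)
  mus <- c(d / 2, -d / 2)
  for (row in 1:2) {
    mu <- mus[row]
    obs_self <- rev(cumsum(rev(cts$self[row, ]))) / sum(cts$self[row, ])
    ana_self <- (1 - pnorm(cc + t_edges - mu)) / (1 - pnorm(cc - mu))
    expect_equal(obs_self[-1], ana_self, tolerance = 0.02,
                 ignore_attr = TRUE)
    obs_other <- rev(cumsum(rev(cts$other[row, ]))) / sum(cts$other[row, ])
    ana_other <- pnorm(cc - t_edges - mu) / pnorm(cc - mu)
    expect_equal(obs_other[-1], ana_other, tolerance = 0.02,
                 ignore_attr = TRUE)
  }
})

test_that("the SSE fit recovers model-generated counts exactly", {
  md <- 1.2; cr <- 0.2
  q <- cr * md + c(0.4, 0.9, 1.5)
  r <- cr * md - c(0.5, 1.0, 1.6)
  cts <- analytic_t2_counts(md, cr, q, r)
  t1 <- structure(list(d_prime = 1.0, c = cr, c_rel = cr),
                  class = "type1_stats")
  fit <- fit_meta_d(cts, t1, seed = 42)
  expect_equal(fit$meta_d, md, tolerance = 1e-3)
  expect_lt(fit$sse, 1e-4)
  expect_true(fit$converged)
  expect_equal(fit$m_ratio, fit$meta_d / t1$d_prime)
  # returned criteria keep the required ordering around meta_c
  expect_true(all(diff(fit$t2_criteria_self) > 0))
  expect_true(all(fit$t2_criteria_self >= fit$meta_c))
  expect_true(all(diff(fit$t2_criteria_other) < 0))
  expect_true(all(fit$t2_criteria_other <= fit$meta_c))
})

test_that("heavy metacognitive noise drives meta-d' below d'", {
  obs <- fit_observer(6000, d_prime = 1.5, sigma_meta = 2,
                      subject_seed = 7, fit_seed = 11)
  expect_lt(obs$fit$meta_d, obs$t1$d_prime - 0.5)
  # and the fitted model's cumulative type-2 probabilities are monotone
  pr <- metad_t2_probs(obs$fit$meta_d, obs$t1$c_rel,
                       obs$fit$t2_criteria_self, obs$fit$t2_criteria_other)
  expect_true(all(apply(pr$self, 1, function(x) all(diff(x) <= 1e-12))))
  expect_true(all(apply(pr$other, 1, function(x) all(diff(x) <= 1e-12))))
})

test_that("fit refuses degenerate type-1 input", {
  nd <- type1_stats(make_trials(8, 7, 8, 7), "loglin")
  cts <- type2_counts(bin_confidence(make_trials(8, 7, 8, 7), 4))
  expect_error(fit_meta_d(cts, nd), "nonzero")
})

test_that("meta_contrast does exact arithmetic and flags d' = 0", {
  t1 <- structure(list(d_prime = 0.80), class = "type1_stats")
  fit <- structure(list(meta_d = 0.30), class = "meta_fit")
  mc <- meta_contrast(t1, fit)
  expect_equal(mc$diff, -0.5)
  expect_equal(mc$m_ratio, 0.375)
  expect_false(mc$undefined)
  t0 <- structure(list(d_prime = 0), class = "type1_stats")
  expect_true(meta_contrast(t0, fit)$undefined)
})
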