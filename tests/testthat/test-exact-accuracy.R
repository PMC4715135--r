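test_that("exact OBP moments equal the enumeration oracle across prior parities", {
  set.seed(71)
  m <- random_model(1)
  # integer / non-integer alpha-beta combinations exercising the three
  # decomposition cases (equal, same fractional part, different parts)
  priors <- list(prior_spec(3, 3, c(1, 1), c(1, 1)),
                 prior_spec(2.5, 3.5, c(1.2, 0.8), c(0.7, 1.3)),
                 prior_spec(4.5, 2.5, c(1, 1), c(2, 1)),
                 prior_spec(2, 4, c(1, 2), c(1, 1)))
  for (pr in priors) {
    for (n in c(3, 5, 6)) {
      orc <- oracle_moments(m, pr, n)
      expect_equal(orc$prob_total, 1, tolerance = 1e-10)
      expect_equal(obp_first_moment(m, pr, n), orc$m1, tolerance = 1e-10)
      expect_equal(obp_second_moment(m, pr, n), orc$m2, tolerance = 1e-10)
    }
  }
})

test_that("the conditional decomposition partitions the sample space", {
  # with the integrand replaced by 1 the branch weights must sum to 1,
  # including the shared boundary value counted exactly once
  for (ab in list(c(3, 3), c(2, 4), c(2.5, 3.5), c(1.5, 4.5))) {
    for (n in 2:7) {
      m <- discrete_model(0.37, c(0.6, 0.4), c(0.4, 0.6))
      pr <- prior_spec(ab[1], ab[2], c(1, 1), c(1, 1))
      br <- codbayes:::obp_branches(m, pr, n)
      w <- sum(br$b0$w %||% 0) + sum(br$b1$w %||% 0)
      expect_equal(w, 1, tolerance = 1e-12)
      n0s <- c(br$b0$n0, br$b1$n0)
      expect_equal(sort(n0s), 0:n)  # each n0 exactly once
    }
  }
})

test_that("second moment dominates the squared first moment", {
  set.seed(72)
  for (rep in 1:6) {
    m <- random_model(1)
    pr <- random_valid_prior(1)
    n <- sample(2:10, 1)
    expect_gte(obp_second_moment(m, pr, n) + 1e-12,
               obp_first_moment(m, pr, n)^2)
  }
})

test_that("degenerate c = 1 reduces to the deterministic class-size path", {
  m <- discrete_model(1, c(0.6, 0.4), c(0.5, 0.5))
  pr <- prior_spec(3, 3, c(1, 1), c(1, 1))
  n <- 5
  # n0 = n surely: compute the conditional expectation directly
  mu1 <- obp_first_moment(m, pr, n)
  direct <- codbayes:::obp_cond_error_mean(m, pr, n, n) /
    min(n + pr$alpha, pr$beta)
  expect_equal(mu1, direct, tolerance = 1e-12)
  mu2 <- obp_second_moment(m, pr, n)
  direct2 <- codbayes:::obp_cond_error_sq(m, pr, n, n) /
    min(n + pr$alpha, pr$beta)^2
  expect_equal(mu2, direct2, tolerance = 1e-12)
})

test_that("accuracy report satisfies the RMS identity and matches the oracle", {
  m <- discrete_model(0.5, c(0.6, 0.4), c(0.4, 0.6))
  pr <- prior_spec(3, 3, c(1, 1), c(1, 1))
  rep4 <- obp_fixed_accuracy(m, pr, 4)
  expect_equal(rep4$rms^2, rep4$variance + rep4$bias^2, tolerance = 1e-10)
  orc <- oracle_moments(m, pr, 4)
  expect_equal(rep4$bias, (1 - orc$m1) - true_cod(m), tolerance = 1e-10)
  expect_equal(rep4$variance, orc$m2 - orc$m1^2, tolerance = 1e-10)
  expect_gte(rep4$variance, 0)
})

test_that("exact moments agree with direct Monte-Carlo sampling", {
  m <- discrete_model(0.45, c(0.7, 0.3), c(0.25, 0.75))
  pr <- prior_spec(4, 3, c(1, 2), c(1, 1))
  n <- 12
  M <- 20000
  vals <- codbayes:::with_seed(73, vapply(seq_len(M), function(i) {
    ct <- count_samples(sample_model(m, n))
    1 - obp_cod(pr, ct)$value
  }, 0))
  se <- sd(vals) / sqrt(M)
  expect_lt(abs(obp_first_moment(m, pr, n) - mean(vals)), 3 * se)
})

test_that("a matched low-variance prior beats a mismatched one in exact RMS", {
  t1 <- table1_models()$d1
  cc <- concentration_level(1, "low")
  matched <- build_prior(0.5, t1$base$matched$p0, t1$base$matched$q0,
                         cc$delta_c, cc$delta_p, cc$delta_q)
  mism <- build_prior(0.5, t1$base$mismatched$p0, t1$base$mismatched$q0,
                      cc$delta_c, cc$delta_p, cc$delta_q)
  for (n in c(10, 30)) {
    expect_lt(obp_fixed_accuracy(t1$model, matched, n)$rms,
              obp_fixed_accuracy(t1$model, mism, n)$rms)
  }
})

test_that("enumeration oracle enumerates the d = 1, n = 2 outcome set", {
  m <- discrete_model(0.5, c(0.6, 0.4), c(0.4, 0.6))
  orc <- enumerate_outcomes_oracle(m, worked_prior(), 2)
  # compositions: n0 = 0 gives 3 V-splits, n0 = 1 gives 2 x 2,
  # n0 = 2 gives 3 U-splits -> 10 outcomes in total
  expect_equal(nrow(orc), 10)
  expect_equal(sum(orc$prob), 1, tolerance = 1e-12)
  expect_error(enumerate_outcomes_oracle(m, worked_prior(), 2,
                                         max_outcomes = 5),
               class = "codbayes_domain_error")
})

test_that("global accuracy is reproducible and near-unbiased for MMSE", {
  pr <- flat_prior(1)
  r1 <- global_accuracy(pr, 1, 15, 300, seed = 74, estimator = "mmse")
  r2 <- global_accuracy(pr, 1, 15, 300, seed = 74, estimator = "mmse")
  expect_identical(r1$bias, r2$bias)
  expect_lt(abs(r1$bias), 3 * r1$se$bias)
  expect_equal(r1$rms^2, r1$variance + r1$bias^2, tolerance = 1e-10)
})
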