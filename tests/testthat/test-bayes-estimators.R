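test_that("closed-form MMSE matches the MC posterior oracle on the worked example", {
  est <- mmse_cod(worked_prior(), count_samples(worked_samples()))
  orc <- mc_posterior_oracle(worked_prior(), count_samples(worked_samples()),
                             reps = 2e5, seed = 17)
  expect_lt(abs(est$value - orc$mean), 3 * orc$se)
  expect_true(est$value >= 0 && est$value <= 1)
  expect_equal(est$diagnostics$method, "closed")
})

test_that("MMSE estimate is symmetric under exchanging class labels", {
  set.seed(51)
  for (rep in 1:5) {
    d <- sample(1:2, 1)
    b <- 2^d
    av <- sample(1:3, b, TRUE); bv <- sample(1:3, b, TRUE)
    pr <- prior_spec(sum(av) + 1, sum(bv) + 1, av, bv)
    ct <- random_counts(d, 8)
    sw_pr <- prior_spec(pr$beta, pr$alpha, pr$beta_vec, pr$alpha_vec)
    sw_ct <- sample_counts(ct$V, ct$U, d)
    expect_equal(mmse_cod(pr, ct)$value, mmse_cod(sw_pr, sw_ct)$value,
                 tolerance = 1e-10)
  }
})

test_that("closed form and MC fallback agree within 3 SE on random instances", {
  set.seed(52)
  for (rep in 1:8) {
    d <- sample(1:2, 1)
    pr <- random_valid_prior(d)
    ct <- random_counts(d, sample(2:10, 1))
    cf <- mmse_cod(pr, ct)$value
    mc <- mmse_cod_mc(pr, ct, reps = 1e5, seed = rep)
    expect_lt(abs(cf - mc$value), 3 * mc$diagnostics$se)
    expect_true(cf >= 0 && cf <= 1)
  }
})

test_that("invalid priors trigger the MC fallback automatically", {
  pr <- prior_spec(1, 1, c(1, 1), c(1, 1))  # uniform everywhere: invalid
  ct <- count_samples(worked_samples())
  est <- mmse_cod(pr, ct, reps = 5000, seed = 9)
  expect_equal(est$diagnostics$method, "mc")
  expect_true(est$diagnostics$fallback)
  expect_error(mmse_cod(pr, ct, method = "closed"),
               class = "codbayes_domain_error")
  # reps = 1 with a fixed seed is reproducible
  expect_equal(mmse_cod_mc(pr, ct, reps = 1, seed = 3)$value,
               mmse_cod_mc(pr, ct, reps = 1, seed = 3)$value)
})

test_that("with no data the posterior mean equals the prior-mean CoD", {
  pr <- worked_prior()
  ct <- sample_counts(c(0, 0), c(0, 0))
  est <- mmse_cod(pr, ct)
  # independent prior-expectation oracle
  orc <- mc_posterior_oracle(pr, ct, reps = 2e5, seed = 23)
  expect_lt(abs(est$value - orc$mean), 3 * orc$se)
})

test_that("the OBP predictor follows the posterior odds with ties to 0", {
  pr <- worked_prior()
  ct <- count_samples(worked_samples())
  # cell 1: E[c p_1|S] = 0.375 vs E[(1-c) q_1|S] = 0.125 -> predict 0
  expect_equal(obp_predict(pr, ct, 1), 0L)
  expect_equal(obp_predict(pr, ct, 2), 1L)
  # exact tie everywhere -> 0
  tie <- sample_counts(c(1, 1), c(1, 1))
  expect_equal(obp_predict(pr, tie), c(0L, 0L))
})

test_that("OBP CoD reproduces the worked example and its decomposition", {
  pr <- worked_prior()
  ct <- count_samples(worked_samples())
  est <- obp_cod(pr, ct)
  expect_equal(est$value, 0.5)  # 1 - (1/5)(min(15/4,5/4)+min(5/4,15/4))
  expect_equal(est$value,
               1 - obp_error(pr, ct) / obp_prior_error(pr, ct))
  # symmetric counts and prior give CoD 0
  expect_equal(obp_cod(pr, sample_counts(c(2, 1), c(2, 1)))$value, 0)
  set.seed(53)
  for (rep in 1:20) {
    d <- sample(1:3, 1)
    pr2 <- random_valid_prior(d)
    ct2 <- random_counts(d, sample(0:15, 1))
    v <- obp_cod(pr2, ct2)$value
    expect_true(v >= -1e-12 && v <= 1 + 1e-12)
    expect_equal(v, 1 - obp_error(pr2, ct2) / obp_prior_error(pr2, ct2),
                 tolerance = 1e-12)
  }
})

test_that("both Bayesian estimators are consistent at large n", {
  m <- discrete_model(0.5, c(0.75, 0.25), c(0.3, 0.7))
  pr <- flat_prior(1)
  # a single size-1e4 sample leaves ~0.01 sampling noise in any CoD
  # estimate, so consistency is asserted on the mean over 5 samples
  devs <- vapply(1:5, function(i) {
    ct <- count_samples(sample_model(m, 1e4, seed = 540 + i))
    c(mmse_cod(pr, ct, seed = 55)$value - true_cod(m),
      obp_cod(pr, ct)$value - true_cod(m))
  }, c(0, 0))
  expect_lt(abs(mean(devs[1, ])), 0.02)
  expect_lt(abs(mean(devs[2, ])), 0.02)
})

test_that("estimator evaluation stays sub-second at desk scale", {
  pr <- flat_prior(3)
  ct <- random_counts(3, 60)
  t0 <- proc.time()[["elapsed"]]
  suppressWarnings(mmse_cod(pr, ct))  # clamp warnings allowed at this scale
  obp_cod(pr, ct)
  expect_lt(proc.time()[["elapsed"]] - t0, 1)
})
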