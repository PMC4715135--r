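test_that("beta_fn matches known values and is symmetric", {
  expect_equal(beta_fn(1, 1), 1)
  expect_equal(beta_fn(2, 2), 1 / 6)
  set.seed(4)
  for (i in 1:10) {
    a <- runif(1, 0.5, 20); b <- runif(1, 0.5, 20)
    expect_equal(beta_fn(a, b), beta_fn(b, a))
  }
  expect_error(beta_fn(0, 1), class = "codbayes_domain_error")
  expect_error(beta_fn(2, -1), class = "codbayes_domain_error")
})

test_that("series coefficients match the finite closed form for integer b", {
  expect_equal(series_coeffs(2, 2), c(1 / 2, -1 / 3))
  expect_equal(series_coeffs(5, 1), 1 / 5)  # (1-u)^0 term only
  # closed form r_i = (-1)^i choose(b-1, i) / (a + i), i = 0..b-1
  set.seed(11)
  for (rep in 1:10) {
    a <- runif(1, 0.3, 15); b <- sample(1:12, 1)
    i <- 0:(b - 1)
    closed <- (-1)^i * choose(b - 1, i) / (a + i)
    got <- series_coeffs(a, b)
    expect_length(got, b)
    expect_equal(got, closed, tolerance = 1e-12)
    # the alternating sum cancels; accuracy is relative to term magnitude
    expect_lt(abs(sum(got) - beta_fn(a, b)), 1e-12 * sum(abs(got)))
  }
})

test_that("truncated series partial sums converge to the Beta function", {
  co <- series_coeffs(3, 2.5, tol = 1e-12)
  partial <- cumsum(co)
  target <- beta_fn(3, 2.5)
  # later partial sums approach the quadrature value monotonically closer
  gaps <- abs(partial - target)
  expect_lt(gaps[length(gaps)], 1e-8)
  expect_lt(gaps[length(gaps)], gaps[5])
  quad <- integrate(function(u) u^2 * (1 - u)^1.5, 0, 1,
                    rel.tol = 1e-12)$value
  expect_equal(target, quad, tolerance = 1e-10)
})

test_that("inc_beta reproduces known values and endpoint identities", {
  expect_equal(inc_beta(0.5, 2, 2), 0.5^2 / 2 - 0.5^3 / 3)  # 1/12
  expect_equal(inc_beta(0.3, 1, 1), 0.3)
  expect_equal(inc_beta(1, 4.5, 3.2), beta_fn(4.5, 3.2))
  expect_equal(inc_beta(0, 3, 3), 0)
  expect_error(inc_beta(1.2, 2, 2), class = "codbayes_domain_error")
  expect_error(inc_beta(-0.1, 2, 2), class = "codbayes_domain_error")
})

test_that("inc_beta agrees with the quadrature CDF oracle to 1e-9", {
  set.seed(21)
  for (rep in 1:50) {
    a <- runif(1, 0.5, 20); b <- runif(1, 0.5, 20); x <- runif(1)
    got <- inc_beta(x, a, b) / beta_fn(a, b)
    expect_equal(got, pbeta(x, a, b), tolerance = 1e-9)
  }
})

test_that("inc_beta is monotone nondecreasing in x", {
  xs <- seq(0, 1, by = 0.05)
  for (sh in list(c(2, 2), c(0.7, 3.3), c(6, 1.5))) {
    vals <- vapply(xs, inc_beta, 0, a = sh[1], b = sh[2])
    expect_true(all(diff(vals) >= -1e-12))
  }
})

test_that("truncated moments follow the incomplete-Beta identities", {
  expect_equal(truncated_moment(3, 4, 1, 0, 1), 3 / 7)       # E[X]
  expect_equal(truncated_moment(2, 2, 0, 0, 0.5), 0.5)       # median
  quad <- integrate(function(u)
    u^(3 + 2 - 1) * (1 - u)^(4 + 1 - 1) / beta_fn(3, 4), 0, 0.7,
    rel.tol = 1e-12)$value
  expect_equal(truncated_moment(3, 4, 2, 1, 0.7), quad, tolerance = 1e-10)
  # E[1/X] requires a > 1; full-range moment bound enforced
  expect_error(truncated_moment(0.8, 3, -1, 0, 1),
               class = "codbayes_domain_error")
  expect_error(truncated_moment(3, 0.8, 0, -1, 1),
               class = "codbayes_domain_error")
  expect_equal(truncated_moment(3, 2, -1, 0, 1), (3 + 2 - 1) / (3 - 1),
               tolerance = 1e-12)  # E[1/X] = (a+b-1)/(a-1)
})

test_that("Dirichlet marginals are Beta(a_i, Delta - a_i)", {
  m <- dirichlet_marginal(dirichlet_params(c(1, 1)), 1)
  expect_equal(c(m$a, m$b), c(1, 1))
  m <- dirichlet_marginal(dirichlet_params(c(3, 1)), 1)
  expect_equal(c(m$a, m$b), c(3, 1))
  m <- dirichlet_marginal(dirichlet_params(c(2, 3, 5)), 2)
  expect_equal(c(m$a, m$b), c(3, 7))
  expect_error(dirichlet_marginal(dirichlet_params(c(2, 3)), 3),
               class = "codbayes_domain_error")
})

test_that("samplers are reproducible and match Dirichlet moment formulas", {
  expect_identical(sample_beta(3, 3, 5, seed = 7),
                   sample_beta(3, 3, 5, seed = 7))
  x <- sample_beta(3, 3, 2e4, seed = 1)
  expect_equal(mean(x), 0.5, tolerance = 0.01)

  dd <- sample_dirichlet(c(2, 3, 5), 1e5, seed = 2)
  expect_true(all(dd >= 0))
  expect_true(max(abs(rowSums(dd) - 1)) < 1e-12)
  expect_equal(colMeans(dd), c(0.2, 0.3, 0.5), tolerance = 0.01)
  # Var(X_1) = a'(1-a')/(Delta+1) = 0.2*0.8/11
  expect_equal(var(dd[, 1]), 0.2 * 0.8 / 11, tolerance = 0.002)

  du <- sample_dirichlet(rep(1, 4), 2e4, seed = 3)
  expect_equal(colMeans(du), rep(0.25, 4), tolerance = 0.01)
})
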