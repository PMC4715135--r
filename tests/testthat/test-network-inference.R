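test_that("essential-function enumeration matches inclusion-exclusion counts", {
  # number with all k inputs essential: sum_j (-1)^j C(k,j) 2^(2^(k-j))
  ie_count <- function(k) sum((-1)^(0:k) * choose(k, 0:k) * 2^(2^(k:0)))
  expect_equal(nrow(enumerate_essential(1)), 2)
  expect_equal(nrow(enumerate_essential(2)), 10)
  expect_equal(nrow(enumerate_essential(3)), 218)
  for (k in 1:3) expect_equal(nrow(enumerate_essential(k)), ie_count(k))
  # every returned table passes the essentiality predicate; none repeat
  G <- enumerate_essential(3)
  expect_false(anyDuplicated(apply(G, 1, paste, collapse = "")) > 0)
  expect_true(all(apply(G, 1, codbayes:::is_essential)))
  expect_error(enumerate_essential(0), class = "codbayes_domain_error")
})

test_that("boolean regulations validate their wiring and essentiality", {
  reg <- boolean_regulation(c(0, 0, 0, 1), c(2, 5))  # AND of inputs 2, 5
  expect_equal(reg$k, 2)
  expect_error(boolean_regulation(c(0, 0, 1, 1), c(1, 2)),
               class = "codbayes_domain_error")  # input 2 inessential
  expect_error(boolean_regulation(c(0, 1), c(1, 1)),
               class = "codbayes_domain_error")
})

test_that("predictive power is the agreement frequency", {
  reg <- boolean_regulation(c(0, 0, 0, 1, 0, 1, 1, 1), 1:3)  # majority
  spec <- c(lapply(1:3, function(i) list(name = paste0("x", i), prob = 0.5)),
            list(list(name = "y", regulators = c("x1", "x2", "x3"),
                      table = reg$table, p = 1)))
  mat <- synth_expression(spec, n = 50, seed = 91)
  expect_equal(predictive_power(mat[, 1:3], mat[, 4], reg), 1)
  expect_equal(predictive_power(mat[, 1:3], 1 - mat[, 4], reg), 0)
  y2 <- mat[, 4]; y2[1:6] <- 1 - y2[1:6]
  expect_equal(predictive_power(mat[, 1:3], y2, reg), 44 / 50)
})

test_that("empirical hyperparameters follow the ceiling construction", {
  and3 <- c(rep(0, 7), 1)
  pr1 <- empirical_hyperparams(0.9, and3, delta = 1)
  expect_equal(c(pr1$alpha, pr1$beta), c(1, 1))   # ceil(0.8), ceil(0.2)
  expect_equal(pr1$alpha_vec, rep(1, 8))
  expect_equal(pr1$beta_vec, rep(1, 8))

  pr64 <- empirical_hyperparams(0.9, and3, delta = 64)
  expect_equal(pr64$alpha_vec, c(rep(9, 7), 1))   # ceil(0.140625 * 64) etc.
  expect_equal(pr64$beta_vec, c(rep(4, 7), 36))   # ceil(.0625*64), ceil(.5625*64)

  # pure noise: flat base measures, c_hat = 1/2
  pr_noise <- empirical_hyperparams(0.5, and3, delta = 8)
  expect_equal(pr_noise$p0, rep(1 / 8, 8))
  expect_equal(pr_noise$q0, rep(1 / 8, 8))
  expect_equal(pr_noise$c0, 0.5)

  # deterministic fit: zero-mass cells floored at shape 1
  pr_det <- empirical_hyperparams(1, and3, delta = 4)
  expect_true(all(pr_det$alpha_vec >= 1))
})

test_that("model selection recovers a known regulation from clean data", {
  spec <- c(lapply(1:6, function(i) list(name = paste0("x", i), prob = 0.5)),
            list(list(name = "y", regulators = c("x2", "x4", "x5"),
                      table = c(0, 0, 0, 1, 0, 1, 1, 1), p = 1)))
  mat <- synth_expression(spec, n = 200, seed = 92)
  for (est in c("obp", "resub")) {
    sel <- select_model(mat[, 1:6], mat[, 7], k = 3, estimator = est,
                        seed = 7)
    expect_equal(sel$regulation$wiring, c(2L, 4L, 5L))
    expect_equal(sel$regulation$table, c(0L, 0L, 0L, 1L, 0L, 1L, 1L, 1L))
    expect_equal(sel$regulation$p_hat, 1)
  }
  # pure function of (data, seed): repeated runs are identical
  s1 <- select_model(mat[, 1:6], mat[, 7], k = 3, seed = 3,
                     keep_scores = TRUE)
  s2 <- select_model(mat[, 1:6], mat[, 7], k = 3, seed = 3,
                     keep_scores = TRUE)
  expect_identical(s1$scores, s2$scores)
  expect_equal(nrow(s1$scores), 218 * choose(6, 3))
})

test_that("network inference respects conventions and degenerate targets", {
  mat <- synth_expression(example_network_spec(p = 0.95), n = 31, seed = 93)
  expect_equal(dim(mat), c(31L, 7L))
  net <- infer_network(mat, k = 3, estimator = "obp", seed = 11)
  expect_equal(nrow(net), 7)
  for (i in seq_len(nrow(net)))  # a gene never predicts itself
    expect_false(net$target[i] %in% strsplit(net$predictors[i], ",")[[1]])

  # permuting sample rows leaves the inferred network unchanged
  perm <- codbayes:::with_seed(94, sample(nrow(mat)))
  net_p <- infer_network(mat[perm, ], k = 3, estimator = "obp", seed = 11)
  expect_identical(net, net_p)

  # constant target: resubstitution CoD is 0 by the eps0 = 0 convention
  mat2 <- mat; mat2[, 2] <- 0L
  net2 <- infer_network(mat2, k = 3, estimator = "resub", seed = 11)
  expect_equal(net2$cod[net2$target == "g2"], 0)
})

test_that("synthetic expression honours the noise model", {
  # p = 1: targets are deterministic functions of their regulators
  mat <- synth_expression(example_network_spec(p = 1), n = 40, seed = 95)
  maj <- c(0, 0, 0, 1, 0, 1, 1, 1)
  cells <- cell_index(mat[, c("g1", "g2", "g3")])
  expect_equal(mat[, "g4"], maj[cells], ignore_attr = TRUE)

  # p = 0.5: target independent of predictors; inferred CoDs near 0
  spec <- c(lapply(1:3, function(i) list(name = paste0("x", i), prob = 0.5)),
            list(list(name = "y", regulators = c("x1", "x2", "x3"),
                      table = maj, p = 0.5)))
  m05 <- synth_expression(spec, n = 400, seed = 96)
  s <- binary_samples(m05[, 1:3], m05[, 4])
  expect_lt(resub_cod(s)$value, 0.15)

  cyc <- list(list(name = "a", regulators = "b", table = c(0, 1), p = 1),
              list(name = "b", regulators = "a", table = c(0, 1), p = 1))
  expect_error(synth_expression(cyc, n = 5, seed = 1),
               class = "codbayes_domain_error")
})

test_that("the regulation model maps consistently onto the joint CoD model", {
  # build (c, p, q) from a regulation via the flat-P(X) identities and
  # compare the implied CoD with direct simulation from the XOR model
  tab <- c(0, 1, 1, 0, 1, 0, 0, 1)  # parity
  p_pow <- 0.9
  w0 <- p_pow * (1 - tab) + (1 - p_pow) * tab
  w1 <- p_pow * tab + (1 - p_pow) * (1 - tab)
  m <- discrete_model(mean(w0), w0 / sum(w0), w1 / sum(w1))
  spec <- c(lapply(1:3, function(i) list(name = paste0("x", i), prob = 0.5)),
            list(list(name = "y", regulators = c("x1", "x2", "x3"),
                      table = tab, p = p_pow)))
  mat <- synth_expression(spec, n = 2e5, seed = 97)
  s <- binary_samples(mat[, 1:3], mat[, 4])
  expect_lt(abs(resub_cod(s)$value - true_cod(m)), 0.02)
})

test_that("expression matrices round-trip through TSV and CSV", {
  mat <- synth_expression(example_network_spec(), n = 12, seed = 98)
  for (ext in c("tsv", "csv")) {
    path <- file.path(tempdir(), paste0("expr.", ext))
    write_expression(mat, path)
    expect_equal(read_expression(path), mat)
  }
  net <- infer_network(mat, k = 3, estimator = "resub", seed = 1)
  tsv <- file.path(tempdir(), "net.tsv")
  dot <- file.path(tempdir(), "net.dot")
  write_network_tsv(net, tsv)
  write_network_dot(net, dot)
  back <- utils::read.table(tsv, header = TRUE, sep = "\t",
                            colClasses = c(table = "character"))
  expect_equal(back$cod, net$cod, tolerance = 1e-12)
  expect_equal(back$table, net$table)
  expect_match(readLines(dot)[1], "digraph")
  top <- top_relationships(net, 3, seed = 2)
  expect_equal(nrow(top), 3)
  expect_true(all(diff(top$cod) <= 0))
})
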