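#' Bayesian CoD estimators: MMSE and OBP
#'
#' Two Bayesian estimators of the discrete CoD under the Beta-Dirichlet
#' model. The MMSE estimator is the posterior expectation
#' \eqn{E[CoD | S_n]}, optimal in mean square over the joint law of
#' parameters and samples; it admits an exact finite-series expression when
#' the hyperparameters are integers (truncated series otherwise). The OBP
#' estimator plugs the optimal Bayesian predictor's posterior-expected
#' errors into the CoD ratio and is a simple O(2^d) formula.
#'
#' @name bayes-estimators
NULL

cod_estimate <- function(value, estimator, diagnostics = list()) {
  structure(list(value = value, estimator = estimator,
                 diagnostics = diagnostics),
            class = "cod_estimate")
}

#' @export
print.cod_estimate <- function(x, ...) {
  cat(sprintf("CoD estimate (%s): %.6g\n", x$estimator, x$value))
  if (length(x$diagnostics)) {
    dg <- x$diagnostics
    cat("  diagnostics:",
        paste(names(dg), vapply(dg, function(v)
          paste(format(v, digits = 4), collapse = ","), ""),
          sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Closed-form MMSE machinery.
#
# Per cell i, with posterior marginal shapes (a, abar) for p_i, (b, bbar)
# for q_i and (A, B) for c, the posterior mean of the cell's contribution to
# the unexplained-error ratio splits into four terms by the sign of c - 1/2
# and by which variable carries the leading factor. Each term reduces, via
# the incomplete-Beta power series and the truncated c-moments
#   g_lt(m) = E[(c/(1-c))^m I(c <= 1/2)] = IB(1/2; A+m, B-m) / B(A, B),
#   g_gt(m) = E[((1-c)/c)^m I(c >= 1/2)] = IB(1/2; B+m, A-m) / B(A, B),
# to the nested coefficient sums of the exact expression. The double sums
# are evaluated in signed log space.
# ---------------------------------------------------------------------------

# memoised g-functions for one posterior (A, B)
make_c_moments <- function(A, B) {
  lbAB <- lbeta(A, B)
  env_lt <- new.env(parent = emptyenv())
  env_gt <- new.env(parent = emptyenv())
  glt <- function(m) {
    key <- sprintf("%.12g", m)
    v <- env_lt[[key]]
    if (is.null(v)) {
      v <- inc_beta_log(0.5, A + m, B - m) - lbAB
      env_lt[[key]] <- v
    }
    v
  }
  ggt <- function(m) {
    key <- sprintf("%.12g", m)
    v <- env_gt[[key]]
    if (is.null(v)) {
      v <- inc_beta_log(0.5, B + m, A - m) - lbAB
      env_gt[[key]] <- v
    }
    v
  }
  list(glt = glt, ggt = ggt,
       P_lt = exp(inc_beta_log(0.5, A, B) - lbAB),
       P_gt = exp(inc_beta_log(0.5, B, A) - lbAB))
}

# log |C(second-1, k)| and signs for k = 0..K-1, derived from the series
# coefficients r_k(s0, second) by multiplying back the 1/(s0+k) factor.
binom_family <- function(s0, second, tol) {
  co <- series_coeffs_log(s0, second, tol = tol)
  k <- seq_along(co$log_abs) - 1
  list(lC = co$log_abs + log(s0 + k), sign = co$sign, K = co$terms)
}

# One cell's four-term posterior expectation; returns c(TA, TB, TC, TD).
mmse_cell_terms <- function(a, abar, b, bbar, cm, tol) {
  lb_a <- lbeta(a, abar)
  lb_b <- lbeta(b, bbar)
  mean_p <- a / (a + abar)
  mean_q <- b / (b + bbar)
  s0 <- a + b + 1

  r1 <- series_coeffs_log(a + 1, abar, tol = tol)   # p-moment series
  r2 <- series_coeffs_log(b + 1, bbar, tol = tol)   # q-moment series
  r3 <- series_coeffs_log(a, abar, tol = tol)       # p-CDF series
  r4 <- series_coeffs_log(b, bbar, tol = tol)       # q-CDF series
  fb <- binom_family(s0, bbar, tol)                 # k-family over bbar
  fa <- binom_family(s0, abar, tol)                 # k-family over abar

  j1 <- seq_len(r1$terms) - 1
  j2 <- seq_len(r2$terms) - 1
  j3 <- seq_len(r3$terms) - 1
  j4 <- seq_len(r4$terms) - 1
  kb <- seq_len(fb$K) - 1
  ka <- seq_len(fa$K) - 1

  glt_b <- vapply(b + kb, cm$glt, 0)    # g_lt(b + k)
  ggt_a <- vapply(a + ka, cm$ggt, 0)    # g_gt(a + k)

  # Term A: c < 1/2, p-led.  S1 double sum + mean_p * P(c<1/2) - S3.
  jk <- log(outer(j1, kb, "+") + s0)
  M <- outer(r1$log_abs - lb_a, fb$lC - lb_b + glt_b, "+") - jk
  S <- outer(r1$sign, fb$sign)
  S1 <- signed_log_sum(as.vector(M), as.vector(S))
  glt_b4 <- vapply(b + j4, cm$glt, 0)
  S3 <- mean_p * signed_log_sum(r4$log_abs - lb_b + glt_b4, r4$sign)
  TA <- S1 + mean_p * cm$P_lt - S3

  # Term B: c >= 1/2, p-led (single sum; q integrates to a full moment).
  ggt_aj <- vapply(a + j1, cm$ggt, 0)
  TB <- signed_log_sum(
    r1$log_abs - lb_a + lbeta(s0 + j1, bbar) - lb_b + ggt_aj, r1$sign)

  # Term C: c < 1/2, q-led.
  glt_bj <- vapply(b + j2, cm$glt, 0)
  TC <- signed_log_sum(
    r2$log_abs - lb_b + lbeta(s0 + j2, abar) - lb_a + glt_bj, r2$sign)

  # Term D: c >= 1/2, q-led (mirror of Term A).
  jk2 <- log(outer(j2, ka, "+") + s0)
  M2 <- outer(r2$log_abs - lb_b, fa$lC - lb_a + ggt_a, "+") - jk2
  S2m <- outer(r2$sign, fa$sign)
  S1p <- signed_log_sum(as.vector(M2), as.vector(S2m))
  ggt_a3 <- vapply(a + j3, cm$ggt, 0)
  S3p <- mean_q * signed_log_sum(r3$log_abs - lb_a + ggt_a3, r3$sign)
  TD <- S1p + mean_q * cm$P_gt - S3p

  c(TA, TB, TC, TD)
}

#' Bayesian MMSE CoD estimator
#'
#' Computes \eqn{E[CoD | S_n]}, the posterior expectation of the CoD. When
#' the prior satisfies the closed-form validity constraint
#' (\eqn{\alpha > \Delta_p - 1}, \eqn{\beta > \Delta_q - 1}; see
#' [check_mmse_validity()]) the exact series expression is used, summing
#' four truncated-moment terms per predictor cell; non-integer
#' hyperparameters are handled by tail-truncated series. Otherwise the
#' estimator falls back to Monte-Carlo posterior sampling
#' ([mmse_cod_mc()]), flagged in the diagnostics.
#'
#' @param prior a [prior_spec()].
#' @param counts a [count_samples()] result.
#' @param method `"auto"` (closed form when valid, else MC), `"closed"`, or
#'   `"mc"`.
#' @param reps Monte-Carlo replicates for the fallback.
#' @param seed seed for the fallback.
#' @param tol series tail tolerance.
#' @return A `cod_estimate` with value in \[0, 1\].
#' @examples
#' pr <- prior_spec(3, 3, c(1, 1), c(1, 1))
#' ct <- sample_counts(U = c(2, 0), V = c(0, 2))
#' mmse_cod(pr, ct)
#' @export
mmse_cod <- function(prior, counts, method = c("auto", "closed", "mc"),
                     reps = 20000, seed = NULL, tol = .SERIES_TOL) {
  method <- match.arg(method)
  valid <- check_mmse_validity(prior)
  if (method == "closed" && !valid)
    stop_domain("closed-form MMSE invalid for this prior: ",
                attr(valid, "message"))
  # the closed form costs O(n^2) coefficient pairs per cell; beyond desk
  # scale the Monte-Carlo route is both faster and accurate
  big_n <- counts$n0 + counts$n1 > 2000
  if (method == "mc" || (method == "auto" && (!valid || big_n))) {
    est <- mmse_cod_mc(prior, counts, reps = reps, seed = seed)
    est$diagnostics$fallback <- !valid
    return(est)
  }
  post <- posterior(prior, counts)
  cm <- make_c_moments(post$alpha_s, post$beta_s)
  b2 <- 2L^prior$d
  total <- 0
  clamped <- 0
  for (i in seq_len(b2)) {
    tt <- mmse_cell_terms(post$alpha_s_i[i], post$alpha_bar_s_i[i],
                          post$beta_s_i[i], post$beta_bar_s_i[i], cm, tol)
    dev <- max(c(0, -tt, tt - 1))
    if (dev > 1e-8)
      warning(sprintf(
        "MMSE series term outside [0,1] by %.3g in cell %d (cancellation)",
        dev, i))
    clamped <- max(clamped, dev)
    total <- total + sum(pmin(pmax(tt, 0), 1))
  }
  dev <- max(0, total - 1, -total)
  if (dev > 1e-8)
    warning(sprintf("MMSE error mass outside [0,1] by %.3g", dev))
  total <- min(max(total, 0), 1)
  cod_estimate(1 - total, "mmse",
               diagnostics = list(method = "closed", max_clamp = clamped))
}

#' Monte-Carlo posterior expectation of the CoD
#'
#' Draws \eqn{\theta = (c, p, q)} from the conjugate posterior and averages
#' the true CoD. Used as the fallback for [mmse_cod()] when the closed form
#' is invalid, and as an independent cross-check.
#'
#' @param prior a [prior_spec()].
#' @param counts a [count_samples()] result.
#' @param reps number of posterior draws (>= 1).
#' @param seed integer seed.
#' @return A `cod_estimate`; diagnostics carry the Monte-Carlo standard
#'   error (`se`) and `reps`.
#' @export
mmse_cod_mc <- function(prior, counts, reps = 20000, seed = NULL) {
  if (reps < 1) stop_domain("reps must be >= 1")
  post <- posterior(prior, counts)
  vals <- with_seed(seed, {
    cs <- stats::rbeta(reps, post$alpha_s, post$beta_s)
    ps <- sample_dirichlet(post$p_shapes, reps)
    qs <- sample_dirichlet(post$q_shapes, reps)
    true_cod_theta(cs, ps, qs)
  })
  cod_estimate(mean(vals), "mmse",
               diagnostics = list(
                 method = "mc", reps = reps,
                 se = stats::sd(vals) / sqrt(reps)))
}

#' Optimal Bayesian predictor (OBP)
#'
#' The predictor minimising posterior-expected error: label 1 for cell i
#' iff
#' \deqn{\frac{n_0+\alpha}{n+\alpha+\beta}\frac{U_i+\alpha_i}{n_0+\Delta_p}
#'   < \frac{n_1+\beta}{n+\alpha+\beta}\frac{V_i+\beta_i}{n_1+\Delta_q},}
#' with ties mapped to 0 (the strict inequality's "otherwise" branch).
#'
#' @param prior a [prior_spec()].
#' @param counts a [count_samples()] result.
#' @param i cell index (vectorised); defaults to all cells.
#' @return Integer label(s) in {0, 1}.
#' @export
obp_predict <- function(prior, counts, i = seq_len(2L^prior$d)) {
  s <- obp_cell_scores(prior, counts)
  if (any(i < 1 | i > 2L^prior$d)) stop_domain("cell index out of range")
  as.integer(s$m0[i] < s$m1[i])
}

# posterior-expected joint masses per cell:
#   m0_i = E[c p_i | S],  m1_i = E[(1-c) q_i | S]
obp_cell_scores <- function(prior, counts) {
  n <- counts$n0 + counts$n1
  dc <- n + prior$delta_c
  w0 <- (counts$n0 + prior$alpha) / dc
  w1 <- (counts$n1 + prior$beta) / dc
  list(
    m0 = w0 * (counts$U + prior$alpha_vec) / (counts$n0 + prior$delta_p),
    m1 = w1 * (counts$V + prior$beta_vec) / (counts$n1 + prior$delta_q),
    w0 = w0, w1 = w1)
}

#' Posterior-expected error of the OBP
#'
#' \eqn{\hat\varepsilon_{OBP} = \sum_i \min\{E[c p_i|S], E[(1-c) q_i|S]\}}.
#'
#' @param prior a [prior_spec()].
#' @param counts a [count_samples()] result.
#' @return Scalar error in \[0, 0.5\].
#' @export
obp_error <- function(prior, counts) {
  s <- obp_cell_scores(prior, counts)
  sum(pmin(s$m0, s$m1))
}

#' Posterior-expected error of the best constant predictor
#'
#' \eqn{\hat\varepsilon_{0,OBP} = \min\{E[c|S], 1 - E[c|S]\}
#'   = \min(n_0+\alpha, n_1+\beta)/(n+\alpha+\beta)}.
#'
#' @inheritParams obp_error
#' @return Scalar error in \[0, 0.5\].
#' @export
obp_prior_error <- function(prior, counts) {
  s <- obp_cell_scores(prior, counts)
  min(s$w0, s$w1)
}

#' OBP CoD estimator
#'
#' \eqn{\widehat{CoD}_{OBP} = 1 - \hat\varepsilon_{OBP} /
#' \hat\varepsilon_{0,OBP}}, always in \[0, 1\].
#'
#' @inheritParams obp_error
#' @return A `cod_estimate`.
#' @examples
#' pr <- prior_spec(3, 3, c(1, 1), c(1, 1))
#' ct <- sample_counts(U = c(2, 0), V = c(0, 2))
#' obp_cod(pr, ct)$value  # 0.5
#' @export
obp_cod <- function(prior, counts) {
  e <- obp_error(prior, counts)
  e0 <- obp_prior_error(prior, counts)
  cod_estimate(1 - e / e0, "obp",
               diagnostics = list(eps = e, eps0 = e0))
}
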