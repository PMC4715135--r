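#' Exact fixed-parameter accuracy of the OBP CoD estimator
#'
#' For a fixed model \eqn{\theta} and sample size n, the OBP CoD
#' estimator's sampling distribution depends on \eqn{(n_0, U, V)} only, so
#' its first two moments can be computed exactly: conditioning on
#' \eqn{n_0}, the normaliser \eqn{\hat\varepsilon_{0,OBP} =
#' \min(n_0+\alpha, n_1+\beta)/(n+\Delta_c)} is deterministic and the
#' per-cell error terms are expectations of minima of affine functions of
#' binomial counts. The decomposition follows the two-branch sum over the
#' index sets \eqn{L_0 = \{0, \ldots, \lfloor(n+\beta-\alpha)/2\rfloor\}}
#' (where \eqn{n_0+\alpha} is the smaller normaliser) and
#' \eqn{L_1 = \{0, \ldots, \lfloor(n+\alpha-\beta)/2\rfloor\}} (mirror
#' branch, with the shared boundary term counted once). Bias, variance and
#' RMS follow from the two moments.
#'
#' @name exact-accuracy
NULL

accuracy_report <- function(estimator, n, bias, variance, rms, method,
                            reps = NA_real_, se = NULL) {
  structure(list(estimator = estimator, n = n, bias = bias,
                 variance = variance, rms = rms, method = method,
                 reps = reps, se = se),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "%s accuracy (%s, n = %d): bias = %+.5g, variance = %.5g, rms = %.5g\n",
    x$estimator, x$method, x$n, x$bias, x$variance, x$rms))
  invisible(x)
}

# The two (branch, n0) grids of the conditional decomposition. Each row:
# n0 value, normaliser offset (alpha or beta), binomial weight.
obp_branches <- function(model, prior, n) {
  a <- prior$alpha; b <- prior$beta; c <- model$c
  hi0 <- floor((n + b - a) / 2); hi1 <- floor((n + a - b) / 2)
  r0 <- if (hi0 >= 0) 0:hi0 else integer(0)      # branch: min = n0 + alpha
  r1 <- if (hi1 >= 0) 0:hi1 else integer(0)      # branch: min = n1 + beta
  tie <- (n + a - b) / 2
  r1 <- r1[abs(r1 - tie) > 1e-9]                 # tie counted in branch 0
  list(
    b0 = if (length(r0)) data.frame(n0 = r0, M = r0 + a,
                                    w = stats::dbinom(r0, n, c)) else NULL,
    b1 = if (length(r1)) data.frame(n0 = n - r1, M = r1 + b,
                                    w = stats::dbinom(n - r1, n, c)) else NULL)
}

# E[(n+Delta_c) * eps_hat | n0] summed per cell: for cell i,
# E[min{A(U_i), B(V_i)}] with U_i ~ Bin(n0, p_i), V_i ~ Bin(n1, q_i).
obp_cond_error_mean <- function(model, prior, n, n0) {
  n1 <- n - n0
  tot <- 0
  for (i in seq_along(model$p)) {
    av <- (n0 + prior$alpha) * (0:n0 + prior$alpha_vec[i]) /
      (n0 + prior$delta_p)
    bv <- (n1 + prior$beta) * (0:n1 + prior$beta_vec[i]) /
      (n1 + prior$delta_q)
    pu <- stats::dbinom(0:n0, n0, model$p[i])
    pv <- stats::dbinom(0:n1, n1, model$q[i])
    tot <- tot + drop(pu %*% outer(av, bv, pmin) %*% pv)
  }
  tot
}

#' First moment of the OBP error ratio
#'
#' \eqn{E_{S_n|\theta}[\hat\varepsilon_{OBP} / \hat\varepsilon_{0,OBP}]},
#' computed exactly by the conditional decomposition over \eqn{n_0}.
#'
#' @param model a [discrete_model()].
#' @param prior a [prior_spec()].
#' @param n sample size (n >= 1).
#' @return Scalar expectation.
#' @export
obp_first_moment <- function(model, prior, n) {
  if (n < 1) stop_domain("n must be >= 1")
  br <- obp_branches(model, prior, n)
  tot <- 0
  for (bb in br) {
    if (is.null(bb)) next
    for (j in seq_len(nrow(bb))) {
      if (bb$w[j] == 0) next
      tot <- tot + bb$w[j] *
        obp_cond_error_mean(model, prior, n, bb$n0[j]) / bb$M[j]
    }
  }
  tot
}

# joint trinomial pmf matrix P(X1 = 0..m, X2 = 0..m | m, p1, p2), zero
# where X1 + X2 > m
trinom_matrix <- function(m, p1, p2) {
  k <- 0:m
  p3 <- max(1 - p1 - p2, 0)
  lp1 <- if (p1 > 0) log(p1) else -Inf
  lp2 <- if (p2 > 0) log(p2) else -Inf
  lp3 <- if (p3 > 0) log(p3) else -Inf
  lk <- outer(k, k, function(x, y) {
    r <- m - x - y
    out <- lgamma(m + 1) - lgamma(x + 1) - lgamma(y + 1) - lgamma(r + 1) +
      ifelse(x == 0, 0, x * lp1) + ifelse(y == 0, 0, y * lp2) +
      ifelse(r == 0, 0, r * lp3)
    out[r < 0] <- -Inf
    out
  })
  exp(lk)
}

# E[(n+Delta_c)^2 eps_hat^2 | n0]: diagonal terms E[m_i^2] plus cross terms
# E[m_i m_j] with the joint trinomial law of (U_i, U_j) and (V_i, V_j).
obp_cond_error_sq <- function(model, prior, n, n0) {
  n1 <- n - n0
  b2 <- length(model$p)
  av <- lapply(seq_len(b2), function(i)
    (n0 + prior$alpha) * (0:n0 + prior$alpha_vec[i]) / (n0 + prior$delta_p))
  bv <- lapply(seq_len(b2), function(i)
    (n1 + prior$beta) * (0:n1 + prior$beta_vec[i]) / (n1 + prior$delta_q))
  pu <- lapply(seq_len(b2), function(i) stats::dbinom(0:n0, n0, model$p[i]))
  pv <- lapply(seq_len(b2), function(i) stats::dbinom(0:n1, n1, model$q[i]))
  tot <- 0
  for (i in seq_len(b2)) {   # diagonal: E[min^2]
    Mi <- outer(av[[i]], bv[[i]], pmin)
    tot <- tot + drop(pu[[i]] %*% (Mi * Mi) %*% pv[[i]])
  }
  if (b2 > 1) {
    for (i in seq_len(b2 - 1)) {
      for (j in (i + 1):b2) {
        PU <- trinom_matrix(n0, model$p[i], model$p[j])
        PV <- trinom_matrix(n1, model$q[i], model$q[j])
        Fi <- outer(av[[i]], bv[[i]], pmin)   # (U_i + 1) x (V_i + 1)
        Hj <- outer(av[[j]], bv[[j]], pmin)
        # E[m_i m_j] = sum_{k,r} PU[k,r] * (F[k,] %*% PV %*% H[r,]^T)
        Q <- Fi %*% PV %*% t(Hj)
        tot <- tot + 2 * sum(PU * Q)
      }
    }
  }
  tot
}

#' Second moment of the OBP error ratio
#'
#' \eqn{E_{S_n|\theta}[(\hat\varepsilon_{OBP}/\hat\varepsilon_{0,OBP})^2]},
#' exact via per-pair joint trinomial sums. Cost grows as
#' \eqn{O(4^d n^4)}; intended for desk scale (n <= 60, d <= 3).
#'
#' @inheritParams obp_first_moment
#' @return Scalar expectation (always >= the first moment squared).
#' @export
obp_second_moment <- function(model, prior, n) {
  if (n < 1) stop_domain("n must be >= 1")
  br <- obp_branches(model, prior, n)
  tot <- 0
  for (bb in br) {
    if (is.null(bb)) next
    for (j in seq_len(nrow(bb))) {
      if (bb$w[j] == 0) next
      tot <- tot + bb$w[j] *
        obp_cond_error_sq(model, prior, n, bb$n0[j]) / bb$M[j]^2
    }
  }
  tot
}

#' Exact fixed-parameter accuracy of the OBP CoD estimator
#'
#' Assembles bias, variance and RMS of \eqn{\widehat{CoD}_{OBP}} at a fixed
#' model from the exact first and second moments of the error ratio:
#' \eqn{Bias = E[\widehat{CoD}] - CoD}, \eqn{Variance = Var[\widehat{CoD}]},
#' \eqn{RMS = \sqrt{Variance + Bias^2}}.
#'
#' @inheritParams obp_first_moment
#' @return An `accuracy_report` (method `"exact"`).
#' @export
obp_fixed_accuracy <- function(model, prior, n) {
  mu1 <- obp_first_moment(model, prior, n)    # E[eps/eps0]
  mu2 <- obp_second_moment(model, prior, n)   # E[(eps/eps0)^2]
  cod <- true_cod(model)
  bias <- (1 - mu1) - cod
  variance <- max(mu2 - mu1^2, 0)
  accuracy_report("obp", n, bias, variance,
                  sqrt(variance + bias^2), "exact")
}

#' Exhaustive sampling distribution of the OBP CoD estimator
#'
#' Enumerates all outcomes \eqn{(n_0, U, V)} of an i.i.d. sample of size n
#' with their exact multinomial probabilities and the OBP CoD value of
#' each. A brute-force oracle for the exact moment formulas; limited to
#' small multinomial outcome counts.
#'
#' @inheritParams obp_first_moment
#' @param max_outcomes guard on the enumeration size.
#' @return A data.frame with columns `value` and `prob` (probabilities sum
#'   to 1).
#' @export
enumerate_outcomes_oracle <- function(model, prior, n,
                                      max_outcomes = 1e6) {
  b2 <- length(model$p)
  n_out <- sum(vapply(0:n, function(r)
    choose(r + b2 - 1, b2 - 1) * choose(n - r + b2 - 1, b2 - 1), 0))
  if (n_out > max_outcomes)
    stop_domain("enumeration budget exceeded: ", n_out, " outcomes")
  lp <- log(ifelse(model$p > 0, model$p, 1))
  lq <- log(ifelse(model$q > 0, model$q, 1))
  lmult <- function(w, m, lpr, pr) {
    if (any(w > 0 & pr == 0)) return(-Inf)
    lgamma(m + 1) - sum(lgamma(w + 1)) + sum(ifelse(w == 0, 0, w * lpr))
  }
  vals <- numeric(0); probs <- numeric(0)
  for (r in 0:n) {
    wU <- compositions(r, b2)
    wV <- compositions(n - r, b2)
    lpU <- apply(wU, 1, lmult, m = r, lpr = lp, pr = model$p)
    lpV <- apply(wV, 1, lmult, m = n - r, lpr = lq, pr = model$q)
    lw <- stats::dbinom(r, n, model$c, log = TRUE)
    for (iu in seq_len(nrow(wU))) {
      for (iv in seq_len(nrow(wV))) {
        ct <- sample_counts(wU[iu, ], wV[iv, ], d = log2(b2))
        vals <- c(vals, obp_cod(prior, ct)$value)
        probs <- c(probs, exp(lw + lpU[iu] + lpV[iv]))
      }
    }
  }
  data.frame(value = vals, prob = probs)
}

#' Global (prior-averaged) accuracy by Monte Carlo
#'
#' Draws \eqn{\theta} from the prior and a size-n sample from each draw,
#' applies an estimator, and summarises the deviations
#' \eqn{\widehat{CoD} - CoD}: global bias (their mean), global variance
#' (their variance), and global RMS (root mean square), with Monte-Carlo
#' standard errors. The identity \eqn{RMS^2 = Variance + Bias^2} holds for
#' these definitions.
#'
#' @param prior a [prior_spec()].
#' @param d number of predictors (must match the prior).
#' @param n sample size.
#' @param M number of Monte-Carlo replicates.
#' @param seed integer seed.
#' @param estimator either a tag in
#'   `c("mmse", "obp", "resub", "loo", "b632", "cv10x2")` or a function
#'   `(samples, prior) -> cod_estimate`.
#' @return An `accuracy_report` (method `"monte-carlo"`) whose `se` field
#'   holds standard errors for bias and rms.
#' @export
global_accuracy <- function(prior, d, n, M, seed = NULL,
                            estimator = "mmse") {
  if (M < 1) stop_domain("M must be >= 1")
  if (d != prior$d) stop_domain("d inconsistent with prior")
  fn <- estimator_fn(estimator)
  dev <- with_seed(seed, {
    vapply(seq_len(M), function(rep) {
      th <- draw_model_from_prior(prior)
      s <- sample_model(th, n)
      fn(s, prior)$value - true_cod(th)
    }, 0)
  })
  summarize_deviations(dev, estimator_name(estimator), n, M)
}

# theta ~ prior (uses the ambient RNG stream; callers seed)
draw_model_from_prior <- function(prior) {
  c <- stats::rbeta(1, prior$alpha, prior$beta)
  p <- drop(sample_dirichlet(prior$alpha_vec, 1))
  q <- drop(sample_dirichlet(prior$beta_vec, 1))
  discrete_model(c, p, q)
}

estimator_name <- function(estimator) {
  if (is.character(estimator)) estimator else "custom"
}

# resolve an estimator tag to a function (samples, prior) -> cod_estimate.
# Resampling-based estimators consume the ambient RNG stream so that a
# single outer seed reproduces a whole experiment.
estimator_fn <- function(estimator) {
  if (is.function(estimator)) return(estimator)
  switch(estimator,
    mmse = function(s, pr) mmse_cod(pr, count_samples(s)),
    obp = function(s, pr) obp_cod(pr, count_samples(s)),
    resub = function(s, pr) resub_cod(s),
    loo = function(s, pr) loo_cod(s),
    b632 = function(s, pr) b632_cod(s),
    cv10x2 = function(s, pr) cv10x2_cod(s),
    stop_domain("unknown estimator tag: ", estimator))
}

summarize_deviations <- function(dev, name, n, M) {
  bias <- mean(dev)
  variance <- mean((dev - bias)^2)  # population form: rms^2 = var + bias^2
  ms <- mean(dev^2)
  rms <- sqrt(ms)
  se_bias <- stats::sd(dev) / sqrt(M)
  se_rms <- if (rms > 0) stats::sd(dev^2) / sqrt(M) / (2 * rms) else 0
  accuracy_report(name, n, bias, variance, rms, "monte-carlo", reps = M,
                  se = list(bias = se_bias, rms = se_rms))
}
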