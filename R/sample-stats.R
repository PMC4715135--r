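#' Sufficient statistics and the conjugate Beta-Dirichlet prior
#'
#' An i.i.d. binary sample is summarised by the counts
#' \eqn{n_0, n_1} (targets equal to 0 and 1) and the per-cell counts
#' \eqn{U_i} (samples with \eqn{X = x^i, Y = 0}) and \eqn{V_i}
#' (\eqn{X = x^i, Y = 1}). Under the standard conjugate prior
#' \eqn{c \sim Beta(\alpha, \beta)}, \eqn{p \sim Dirichlet(\alpha_1, \ldots,
#' \alpha_{2^d})}, \eqn{q \sim Dirichlet(\beta_1, \ldots, \beta_{2^d})},
#' the posterior is of the same family with the counts added to the shapes.
#'
#' @name sample-stats
NULL

#' Tally sufficient statistics of a binary sample
#'
#' @param samples a `binary_samples` object (see [binary_samples()]).
#' @return A `sample_counts` object: list with `d`, `n0`, `n1`, `U`, `V`
#'   (dense length-`2^d` count vectors, `sum(U) = n0`, `sum(V) = n1`).
#' @export
count_samples <- function(samples) {
  if (!inherits(samples, "binary_samples"))
    stop_domain("count_samples expects a binary_samples object")
  b <- 2L^samples$d
  if (length(samples$cells) &&
      (any(samples$cells < 1L) || any(samples$cells > b)))
    stop_domain("malformed sample: cell index out of range")
  U <- tabulate(samples$cells[samples$y == 0L], nbins = b)
  V <- tabulate(samples$cells[samples$y == 1L], nbins = b)
  sample_counts(U, V, samples$d)
}

#' @rdname count_samples
#' @param U,V per-cell count vectors for Y = 0 and Y = 1.
#' @param d number of predictors; defaults to `log2(length(U))`.
#' @export
sample_counts <- function(U, V, d = log2(length(U))) {
  U <- as.numeric(U); V <- as.numeric(V)
  if (length(U) != length(V) || length(U) != 2^round(d))
    stop_domain("U and V must both have length 2^d")
  if (any(U < 0) || any(V < 0) || any(U != round(U)) || any(V != round(V)))
    stop_domain("counts must be nonnegative integers")
  structure(list(d = as.integer(round(d)), n0 = sum(U), n1 = sum(V),
                 U = U, V = V),
            class = "sample_counts")
}

#' Specify a Beta-Dirichlet prior
#'
#' @param alpha,beta positive shapes of the Beta prior on `c = P(Y = 0)`.
#' @param alpha_vec,beta_vec positive length-`2^d` shape vectors of the
#'   Dirichlet priors on `p` and `q`.
#' @return A `prior_spec` object carrying the shapes together with the
#'   derived concentrations (`delta_c`, `delta_p`, `delta_q`) and base
#'   measures (`c0`, `p0`, `q0`).
#' @examples
#' prior_spec(3, 3, c(1, 1), c(1, 1))  # the flat d = 1 reference prior
#' @export
prior_spec <- function(alpha, beta, alpha_vec, beta_vec) {
  if (any(!is.finite(c(alpha, beta, alpha_vec, beta_vec))) ||
      alpha <= 0 || beta <= 0 || any(alpha_vec <= 0) || any(beta_vec <= 0))
    stop_domain("prior hyperparameters must be positive")
  if (length(alpha_vec) != length(beta_vec))
    stop_domain("alpha_vec and beta_vec must have equal length")
  d <- log2(length(alpha_vec))
  if (abs(d - round(d)) > 1e-9)
    stop_domain("alpha_vec must have length 2^d")
  dp <- sum(alpha_vec); dq <- sum(beta_vec)
  structure(list(d = as.integer(round(d)),
                 alpha = alpha, beta = beta,
                 alpha_vec = as.numeric(alpha_vec),
                 beta_vec = as.numeric(beta_vec),
                 delta_c = alpha + beta, delta_p = dp, delta_q = dq,
                 c0 = alpha / (alpha + beta),
                 p0 = alpha_vec / dp, q0 = beta_vec / dq),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf(
    "Beta-Dirichlet prior: d = %d, alpha = %.4g, beta = %.4g\n",
    x$d, x$alpha, x$beta))
  cat("  alpha_vec:", format(x$alpha_vec, digits = 4), "\n")
  cat("  beta_vec :", format(x$beta_vec, digits = 4), "\n")
  cat(sprintf("  concentrations: Delta_c = %.4g, Delta_p = %.4g, Delta_q = %.4g\n",
              x$delta_c, x$delta_p, x$delta_q))
  invisible(x)
}

#' Conjugate posterior update
#'
#' Given prior shapes and sample counts, the posterior is
#' \eqn{c | S \sim Beta(n_0 + \alpha, n_1 + \beta)},
#' \eqn{p | S \sim Dirichlet(U + \alpha_{vec})},
#' \eqn{q | S \sim Dirichlet(V + \beta_{vec})}. The marginal Beta shapes of
#' each cell probability are recorded as well: for cell i,
#' \eqn{p_i | S \sim Beta(\alpha_i^s, \bar\alpha_i^s)} with
#' \eqn{\alpha_i^s = U_i + \alpha_i} and
#' \eqn{\bar\alpha_i^s = n_0 - U_i + \Delta_p - \alpha_i} (and analogously
#' for \eqn{q_i}).
#'
#' @param prior a [prior_spec()].
#' @param counts a [count_samples()] result.
#' @return A `posterior_spec` object with fields `alpha_s`, `beta_s`,
#'   `alpha_s_i`, `alpha_bar_s_i`, `beta_s_i`, `beta_bar_s_i`, plus the
#'   updated Dirichlet shape vectors `p_shapes`, `q_shapes`.
#' @export
posterior <- function(prior, counts) {
  if (prior$d != counts$d)
    stop_domain("prior and counts have different d")
  a_s <- counts$n0 + prior$alpha
  b_s <- counts$n1 + prior$beta
  as_i <- counts$U + prior$alpha_vec
  abar_i <- counts$n0 - counts$U + prior$delta_p - prior$alpha_vec
  bs_i <- counts$V + prior$beta_vec
  bbar_i <- counts$n1 - counts$V + prior$delta_q - prior$beta_vec
  structure(list(d = prior$d,
                 alpha_s = a_s, beta_s = b_s,
                 alpha_s_i = as_i, alpha_bar_s_i = abar_i,
                 beta_s_i = bs_i, beta_bar_s_i = bbar_i,
                 p_shapes = counts$U + prior$alpha_vec,
                 q_shapes = counts$V + prior$beta_vec),
            class = "posterior_spec")
}

#' Closed-form MMSE validity check
#'
#' The exact series expression for the MMSE CoD estimator requires
#' \eqn{\alpha > \Delta_p - 1} and \eqn{\beta > \Delta_q - 1} (otherwise a
#' Beta shape in one of its truncated c-moments would be nonpositive). In
#' particular, if the priors on `p` or `q` are uniform, the prior on `c`
#' cannot be uniform. The check is evaluated on the prior hyperparameters.
#'
#' @param prior a [prior_spec()].
#' @return Logical scalar with attribute `message` explaining a failure;
#'   `FALSE` triggers the Monte-Carlo fallback in [mmse_cod()].
#' @export
check_mmse_validity <- function(prior) {
  ok_p <- prior$alpha > prior$delta_p - 1
  ok_q <- prior$beta > prior$delta_q - 1
  ok <- ok_p && ok_q
  msg <- if (ok) "closed form valid" else paste0(
    "closed form requires alpha > Delta_p - 1 and beta > Delta_q - 1; ",
    sprintf("got alpha = %.4g (Delta_p = %.4g), beta = %.4g (Delta_q = %.4g)",
            prior$alpha, prior$delta_p, prior$beta, prior$delta_q))
  structure(ok, message = msg)
}
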