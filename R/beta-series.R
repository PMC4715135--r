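#' Beta and Dirichlet numerics via the incomplete-Beta power series
#'
#' The Bayesian CoD estimators in this package reduce to truncated moments of
#' Beta posteriors, which in turn reduce to evaluations of the incomplete
#' Beta function \eqn{IB(x;a,b) = \int_0^x u^{a-1}(1-u)^{b-1}\,du}. These
#' routines implement \eqn{IB} as the power series
#' \deqn{IB(x;a,b) = \sum_{i=0}^{P} r_i(a,b)\, x^{a+i},}
#' with \eqn{r_i(a,b) = \frac{(-1)^i}{a+i}\binom{b-1}{i}}. The series is
#' finite (exactly \eqn{b} terms, \eqn{P = b-1}) when \eqn{b} is a positive
#' integer and infinite otherwise, in which case it is truncated to a
#' requested tail tolerance. Coefficients are generated by the recurrence
#' \eqn{r_i = -r_{i-1}\,\frac{(b-i)}{i}\,\frac{(a+i-1)}{(a+i)}} (numerically
#' stable; no factorials), carried in log magnitude plus sign so that
#' posterior shapes of order \eqn{10^3} do not overflow.
#'
#' @name beta-series
#' @keywords internal
NULL

.SERIES_TOL <- 1e-12
.SERIES_CAP <- 10000L

#' Validate Beta shape parameters
#'
#' @param a,b positive shape parameters.
#' @return A list with elements `a` and `b`, invisibly classed `beta_params`.
#' @export
beta_params <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L ||
      !is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    stop_domain("Beta shapes must be finite positive scalars")
  structure(list(a = a, b = b), class = "beta_params")
}

#' Validate Dirichlet shape parameters
#'
#' Records the concentration \eqn{\Delta = \sum_i a_i} and the base measure
#' \eqn{a' = a / \Delta} alongside the shape vector.
#'
#' @param a vector of K >= 2 positive shapes.
#' @return A list with elements `a`, `K`, `delta`, `base`, classed
#'   `dirichlet_params`.
#' @export
dirichlet_params <- function(a) {
  if (!is.numeric(a) || length(a) < 2L || any(!is.finite(a)) || any(a <= 0))
    stop_domain("Dirichlet shapes must be >= 2 finite positive numbers")
  structure(list(a = as.numeric(a), K = length(a), delta = sum(a),
                 base = a / sum(a)),
            class = "dirichlet_params")
}

#' Beta function B(a, b)
#'
#' \eqn{B(a,b)=\int_0^1 u^{a-1}(1-u)^{b-1}du}; symmetric in its arguments.
#' Computed in log space.
#'
#' @param a,b positive shapes.
#' @return The value of B(a, b).
#' @examples
#' beta_fn(1, 1)  # 1
#' beta_fn(2, 2)  # 1/6
#' @export
beta_fn <- function(a, b) {
  if (any(!is.finite(c(a, b))) || any(c(a, b) <= 0))
    stop_domain("beta_fn requires positive shapes")
  exp(lbeta(a, b))
}

# Coefficient generator. Returns log|r_i| and sign(r_i) for i = 0,1,...
# truncated by the rule: for integer b, exactly b terms (r_b = 0); otherwise
# stop once i >= ceil(b) and the next term's contribution at x = `x` falls
# below tol * |running sum|, with a hard cap of `cap` terms.
series_coeffs_log <- function(a, b, tol = .SERIES_TOL, cap = .SERIES_CAP,
                              x = 1) {
  if (!is.finite(a) || a <= 0) stop_domain("series shapes: a must be > 0")
  int_b <- b > 0 && abs(b - round(b)) < 1e-9
  nmax <- if (int_b) as.integer(round(b)) else cap
  log_abs <- numeric(nmax)
  sgn <- integer(nmax)
  log_abs[1L] <- -log(a)
  sgn[1L] <- 1L
  lx <- if (x > 0) log(x) else -Inf
  run <- exp(log_abs[1L] + a * lx)  # |running sum| proxy at evaluation point
  i <- 1L
  while (i < nmax) {
    d <- b - i
    if (int_b && i >= round(b)) break
    log_abs[i + 1L] <- log_abs[i] + log(abs(d)) - log(i) +
      log(a + i - 1) - log(a + i)
    sgn[i + 1L] <- sgn[i] * (if (d > 0) -1L else 1L)
    term <- exp(log_abs[i + 1L] + (a + i) * lx)
    i <- i + 1L
    if (!int_b && i >= ceiling(b) + 2L && term < tol * max(run, 1e-300)) {
      break
    }
    run <- run + term
  }
  list(log_abs = log_abs[seq_len(i)], sign = sgn[seq_len(i)], terms = i,
       truncated = !int_b && i >= cap)
}

#' Series coefficients of the incomplete Beta expansion
#'
#' Returns the coefficients \eqn{r_0(a,b), r_1(a,b), \ldots} such that
#' \eqn{IB(x;a,b) = \sum_i r_i(a,b) x^{a+i}}. For positive integer `b` the
#' sequence has exactly `b` terms and the expansion is exact; otherwise the
#' infinite series is truncated so that the neglected contribution at
#' \eqn{x = 1} is below `tol` relative to the running sum (hard cap 10000
#' terms). Their sum converges to `beta_fn(a, b)`.
#'
#' @param a,b positive shapes.
#' @param tol relative tail tolerance for non-integer `b`.
#' @return Numeric vector of coefficients.
#' @examples
#' series_coeffs(2, 2)   # 1/2, -1/3
#' series_coeffs(3, 1)   # 1/3
#' @export
series_coeffs <- function(a, b, tol = .SERIES_TOL) {
  if (any(!is.finite(c(a, b))) || a <= 0 || b <= 0)
    stop_domain("series_coeffs requires positive shapes")
  co <- series_coeffs_log(a, b, tol = tol)
  co$sign * exp(co$log_abs)
}

# log IB(x; a, b), x in [0, 1). `b` may be <= 0 here (the integrand is still
# integrable on [0, x] for x < 1); callers from the MMSE assembly rely on
# this. Returns -Inf for x <= 0.
#
# Evaluation strategy: the power series is the primary route. Two
# numerical safeguards keep it accurate over the full shape range:
# (i) past the distribution's bulk (x above the mean-like point
# (a+1)/(a+b+2)) the complement identity IB(x;a,b) = B(a,b) -
# IB(1-x;b,a) is used, so the series argument stays small; (ii) if the
# alternating partial sums are detected to cancel by more than ~4 digits,
# the sum is recomputed through its all-positive hypergeometric
# resummation IB = x^a (1-x)^b / a * 2F1(a+b, 1; a+1; x), which carries
# no cancellation at any x < 1.
inc_beta_log <- function(x, a, b, tol = .SERIES_TOL, cap = .SERIES_CAP) {
  if (x <= 0) return(-Inf)
  if (x >= 1) return(lbeta(a, b))
  if (b > 0 && x > (a + 1) / (a + b + 2)) {
    lb <- lbeta(a, b)
    l2 <- ib_direct_log(1 - x, b, a, tol, cap)
    d <- l2 - lb
    if (d >= 0) return(-Inf)
    return(lb + log1p(-exp(d)))
  }
  ib_direct_log(x, a, b, tol, cap)
}

ib_direct_log <- function(x, a, b, tol, cap) {
  out <- ib_theorem_sum(x, a, b, tol, cap)
  if (!is.finite(out$log_value) || out$cancel > 1e4)
    return(ib_hyp_log(x, a, b, tol, cap))
  out$log_value
}

# signed Theorem-1 power-series sum with dynamic rescaling; reports the
# cancellation ratio (sum of magnitudes over |signed sum|)
ib_theorem_sum <- function(x, a, b, tol, cap) {
  lx <- log(x)
  int_b <- b > 0 && abs(b - round(b)) < 1e-9
  nmax <- if (int_b) as.integer(round(b)) else cap
  lr <- -log(a); sg <- 1
  scale <- lr + a * lx
  pos <- 1; neg <- 0
  i <- 1L
  while (i < nmax) {
    d <- b - i
    lr <- lr + log(abs(d)) - log(i) + log(a + i - 1) - log(a + i)
    sg <- sg * (if (d > 0) -1 else 1)
    lt <- lr + (a + i) * lx
    if (lt - scale > 200) {        # rescale before the accumulator overflows
      f <- exp(scale - lt)
      pos <- pos * f; neg <- neg * f
      scale <- lt
    }
    t_scaled <- exp(lt - scale)
    if (sg > 0) pos <- pos + t_scaled else neg <- neg + t_scaled
    i <- i + 1L
    # past the sign-alternating phase (i > b) the term ratio is below x,
    # so the neglected tail is bounded by term * x / (1 - x)
    if (!int_b && i >= max(ceiling(b) + 2L, 2L) &&
        t_scaled * x / (1 - x) < tol * max(abs(pos - neg), 1e-300)) break
  }
  s <- pos - neg
  cancel <- (pos + neg) / max(abs(s), 1e-300)
  list(log_value = if (s <= 0) -Inf else log(s) + scale, cancel = cancel)
}

# all-positive resummation: IB = x^a (1-x)^b / a * sum_n (a+b)_n/(a+1)_n x^n
ib_hyp_log <- function(x, a, b, tol, cap) {
  lpre <- a * log(x) + b * log1p(-x) - log(a)
  t <- 1; s <- 1
  ladj <- 0
  n <- 1L
  nmin <- max(2, ceiling(1 - a - b) + 1)  # terms are positive from here on
  while (n < cap) {
    t <- t * (a + b + n - 1) / (a + n) * x
    s <- s + t
    if (n >= nmin && abs(t) * x / (1 - x) < tol * abs(s)) break
    if (s > 1e250) { ladj <- ladj + log(s); t <- t / s; s <- 1 }
    n <- n + 1L
  }
  lpre + ladj + log(s)
}

#' Incomplete Beta function IB(x; a, b)
#'
#' Power-series evaluation of \eqn{IB(x;a,b)=\int_0^x u^{a-1}(1-u)^{b-1}du}.
#' Monotone nondecreasing in `x`, with `IB(1; a, b) = beta_fn(a, b)`.
#'
#' @param x evaluation point in \[0, 1\].
#' @param a positive shape.
#' @param b shape; must be positive unless `x < 1` (for `x < 1` the integral
#'   converges for any real `b`).
#' @return Nonnegative value of the incomplete Beta integral.
#' @examples
#' inc_beta(0.5, 2, 2)  # 1/12
#' inc_beta(0.3, 1, 1)  # 0.3
#' @export
inc_beta <- function(x, a, b) {
  if (!is.finite(x) || x < 0 || x > 1) stop_domain("inc_beta: x must be in [0,1]")
  if (!is.finite(a) || a <= 0) stop_domain("inc_beta: a must be > 0")
  if (x == 1) {
    if (!is.finite(b) || b <= 0)
      stop_domain("inc_beta: b must be > 0 when x = 1")
    return(beta_fn(a, b))
  }
  exp(inc_beta_log(x, a, b))
}

#' Truncated Beta moments
#'
#' For \eqn{X \sim Beta(a, b)}, computes
#' \eqn{E[X^k (1-X)^l I_{X \le x}]}, equal to
#' \eqn{IB(x; a+k, b+l)/B(a,b)} for \eqn{x < 1} and
#' \eqn{B(a+k, b+l)/B(a,b)} for \eqn{x \ge 1}.
#'
#' @param a,b positive shapes.
#' @param k exponent on X; requires `k > -a`.
#' @param l exponent on (1 - X); requires `l > -b` when `x >= 1` (for
#'   `x < 1` the truncated integral exists for any `l`).
#' @param x truncation point in \[0, 1\].
#' @return The truncated moment.
#' @examples
#' truncated_moment(3, 4, 1, 0, 1)    # E[X] = 3/7
#' truncated_moment(2, 2, 0, 0, 0.5)  # P(X <= 1/2) = 1/2
#' @export
truncated_moment <- function(a, b, k, l, x) {
  if (any(!is.finite(c(a, b))) || a <= 0 || b <= 0)
    stop_domain("truncated_moment requires positive shapes")
  if (!is.finite(x) || x < 0 || x > 1)
    stop_domain("truncated_moment: x must be in [0,1]")
  if (k <= -a)
    stop_domain("truncated_moment: moment does not exist (k <= -a)")
  if (x >= 1) {
    if (l <= -b)
      stop_domain("truncated_moment: moment does not exist (l <= -b)")
    return(exp(lbeta(a + k, b + l) - lbeta(a, b)))
  }
  exp(inc_beta_log(x, a + k, b + l) - lbeta(a, b))
}

#' Marginal of one Dirichlet component
#'
#' If \eqn{X \sim Dirichlet(a_1, \ldots, a_K)} with concentration
#' \eqn{\Delta}, then \eqn{X_i \sim Beta(a_i, \Delta - a_i)}.
#'
#' @param params a [dirichlet_params()] object (or bare shape vector).
#' @param i component index.
#' @return A [beta_params()] object.
#' @export
dirichlet_marginal <- function(params, i) {
  if (!inherits(params, "dirichlet_params")) params <- dirichlet_params(params)
  if (!is.numeric(i) || length(i) != 1L || i < 1 || i > params$K ||
      i != round(i))
    stop_domain("dirichlet_marginal: index out of range")
  beta_params(params$a[i], params$delta - params$a[i])
}

#' Reproducible Beta draws
#'
#' @param a,b positive shapes.
#' @param n number of draws.
#' @param seed integer seed; the caller's RNG state is untouched.
#' @return Numeric vector of draws in (0, 1).
#' @export
sample_beta <- function(a, b, n, seed = NULL) {
  beta_params(a, b)
  with_seed(seed, stats::rbeta(n, a, b))
}

#' Reproducible Dirichlet draws
#'
#' Gamma-normalisation sampler; each row lies on the simplex.
#'
#' @param a shape vector (K >= 2).
#' @param n number of draws.
#' @param seed integer seed.
#' @return An `n x K` matrix with rows summing to one.
#' @export
sample_dirichlet <- function(a, n, seed = NULL) {
  pp <- if (inherits(a, "dirichlet_params")) a else dirichlet_params(a)
  with_seed(seed, {
    g <- matrix(stats::rgamma(n * pp$K, shape = rep(pp$a, each = n)),
                nrow = n)
    sw <- rowSums(g)
    zero <- sw == 0  # only possible for extreme shapes; resolve to base
    if (any(zero)) {
      g[zero, ] <- matrix(pp$base, sum(zero), pp$K, byrow = TRUE)
      sw[zero] <- 1
    }
    g / sw
  })
}
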