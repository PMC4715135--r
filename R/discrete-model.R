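#' The binary predictor/target joint model and the true CoD
#'
#' The joint law of a binary predictor vector
#' \eqn{X = (X_1, \ldots, X_d) \in \{0,1\}^d} and a binary target
#' \eqn{Y \in \{0,1\}} is parameterised by \eqn{\theta = (c, p, q)}:
#' \eqn{c = P(Y = 0)}, \eqn{p_i = P(X = x^i | Y = 0)} and
#' \eqn{q_i = P(X = x^i | Y = 1)} over an enumeration \eqn{x^1, \ldots,
#' x^{2^d}} of the predictor states. This package fixes the enumeration as
#' the binary expansion of \eqn{i - 1} with the most significant bit equal
#' to \eqn{X_1}, so that e.g. for d = 2: \eqn{x^1 = 00}, \eqn{x^2 = 01},
#' \eqn{x^3 = 10}, \eqn{x^4 = 11}. All modules share this convention.
#'
#' @name discrete-model
NULL

#' Construct a discrete joint model
#'
#' @param c probability P(Y = 0), in \[0, 1\].
#' @param p,q probability vectors of length `2^d` over predictor cells,
#'   conditional on Y = 0 and Y = 1 respectively; each must sum to 1.
#' @return An object of class `discrete_model` with fields `d`, `c`, `p`,
#'   `q`.
#' @examples
#' m <- discrete_model(0.5, c(0.6, 0.4), c(0.4, 0.6))
#' true_cod(m)
#' @export
discrete_model <- function(c, p, q) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c < 0 || c > 1)
    stop_domain("c must be a probability")
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q)) stop_domain("p and q must have equal length")
  d <- log2(length(p))
  if (abs(d - round(d)) > 1e-9 || d < 1)
    stop_domain("p and q must have length 2^d with d >= 1")
  if (any(p < -1e-12) || any(q < -1e-12) ||
      abs(sum(p) - 1) > 1e-12 || abs(sum(q) - 1) > 1e-12)
    stop_domain("p and q must be probability vectors summing to 1")
  structure(list(d = as.integer(round(d)), c = c,
                 p = pmax(p, 0), q = pmax(q, 0)),
            class = "discrete_model")
}

#' @export
print.discrete_model <- function(x, ...) {
  cat(sprintf("discrete CoD model: d = %d, c = %.4g\n", x$d, x$c))
  cat("  p:", format(x$p, digits = 4), "\n")
  cat("  q:", format(x$q, digits = 4), "\n")
  cat(sprintf("  true CoD = %.6g (eps = %.6g, eps0 = %.6g)\n",
              true_cod(x), optimal_error(x), prior_error(x)))
  invisible(x)
}

#' Cell index of a binary predictor pattern
#'
#' Maps a 0/1 vector of length d to its cell index in `1..2^d` (binary
#' expansion, most significant bit first). `cell_pattern()` is the inverse.
#'
#' @param x binary vector of length d (or a matrix with one pattern per
#'   row).
#' @return Integer index (or vector of indices for a matrix input).
#' @examples
#' cell_index(c(0, 0))  # 1
#' cell_index(c(1, 1))  # 4
#' @export
cell_index <- function(x) {
  if (is.matrix(x)) {
    if (any(x != 0 & x != 1)) stop_domain("cell_index: entries must be 0/1")
    d <- ncol(x)
    return(as.integer(x %*% 2^((d - 1):0)) + 1L)
  }
  if (any(x != 0 & x != 1)) stop_domain("cell_index: entries must be 0/1")
  sum(x * 2^((length(x) - 1):0)) + 1L
}

#' @rdname cell_index
#' @param i cell index in `1..2^d`.
#' @param d number of binary predictors.
#' @export
cell_pattern <- function(i, d) {
  if (any(i < 1L | i > 2^d)) stop_domain("cell_pattern: index out of range")
  out <- vapply(i, function(ii) as.integer(intToBits(ii - 1L))[d:1],
                integer(d))
  if (d == 1L) matrix(out, ncol = 1L) else t(out)
}

#' Optimal prediction error with observations
#'
#' The Bayes error of predicting Y from X,
#' \eqn{\varepsilon = \sum_i \min\{c\,p_i, (1-c)\,q_i\}}, attained by the
#' predictor that outputs 1 when \eqn{c\,p_i < (1-c)\,q_i} (ties mapped to
#' 0).
#'
#' @param model a [discrete_model()].
#' @return \eqn{\varepsilon \in [0, 0.5]}.
#' @export
optimal_error <- function(model) {
  sum(pmin(model$c * model$p, (1 - model$c) * model$q))
}

#' Optimal prediction error without observations
#'
#' \eqn{\varepsilon_0 = \min\{c, 1-c\}}, the error of the best constant
#' predictor.
#'
#' @param model a [discrete_model()].
#' @return \eqn{\varepsilon_0 \in [0, 0.5]}.
#' @export
prior_error <- function(model) {
  min(model$c, 1 - model$c)
}

#' True coefficient of determination
#'
#' \eqn{CoD = (\varepsilon_0 - \varepsilon)/\varepsilon_0}: the relative
#' decrease in optimal prediction error when the predictors are observed.
#' Returns 0 by convention when \eqn{\varepsilon_0 = 0} (degenerate target).
#'
#' @param model a [discrete_model()].
#' @return CoD in \[0, 1\].
#' @export
true_cod <- function(model) {
  e0 <- prior_error(model)
  if (e0 == 0) return(0)
  1 - optimal_error(model) / e0
}

# Vectorised true CoD over parameter draws: cs length-M, ps/qs M x 2^d.
# Used by Monte-Carlo posterior/prior expectation routines.
true_cod_theta <- function(cs, ps, qs) {
  e0 <- pmin(cs, 1 - cs)
  err <- rowSums(pmin(cs * ps, (1 - cs) * qs))
  ifelse(e0 == 0, 0, 1 - err / e0)
}

#' Draw an i.i.d. sample from a discrete joint model
#'
#' Y = 0 with probability c; X is then drawn from `p` or `q` accordingly.
#'
#' @param model a [discrete_model()].
#' @param n sample size (n >= 0).
#' @param seed integer seed for reproducibility.
#' @return A `binary_samples` object: list with `cells` (cell indices in
#'   `1..2^d`), `y` (0/1 target values) and `d`.
#' @export
sample_model <- function(model, n, seed = NULL) {
  if (n < 0) stop_domain("n must be >= 0")
  b <- 2L^model$d
  with_seed(seed, {
    y <- stats::rbinom(n, 1L, 1 - model$c)
    cells <- integer(n)
    n1 <- sum(y == 1L)
    if (n - n1 > 0)
      cells[y == 0L] <- sample.int(b, n - n1, replace = TRUE, prob = model$p)
    if (n1 > 0)
      cells[y == 1L] <- sample.int(b, n1, replace = TRUE, prob = model$q)
    binary_samples_cells(cells, y, model$d)
  })
}

#' Bundle binary samples
#'
#' @param x 0/1 matrix of predictor values, one sample per row.
#' @param y 0/1 target vector.
#' @return A `binary_samples` object (cell-coded).
#' @export
binary_samples <- function(x, y) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  if (nrow(x) != length(y)) stop_domain("x and y sizes differ")
  if (any(x != 0 & x != 1) || any(y != 0 & y != 1))
    stop_domain("binary_samples: entries must be 0/1")
  binary_samples_cells(cell_index(x), as.integer(y), ncol(x))
}

binary_samples_cells <- function(cells, y, d) {
  structure(list(cells = as.integer(cells), y = as.integer(y),
                 d = as.integer(d)),
            class = "binary_samples")
}

#' Serialise / deserialise a model to a flat config
#'
#' @param model a [discrete_model()].
#' @return `model_to_config()`: a named list with keys `d`, `c`, `p`, `q`
#'   (probability vectors comma-joined); `model_from_config()` inverts it.
#' @export
model_to_config <- function(model) {
  list(d = model$d, c = model$c,
       p = paste(model$p, collapse = ","),
       q = paste(model$q, collapse = ","))
}

#' @rdname model_to_config
#' @param config named list with keys `d`, `c`, `p`, `q`.
#' @export
model_from_config <- function(config) {
  p <- as.numeric(strsplit(as.character(config$p), ",")[[1]])
  q <- as.numeric(strsplit(as.character(config$q), ",")[[1]])
  m <- discrete_model(as.numeric(config$c), p, q)
  if (!is.null(config$d) && as.integer(config$d) != m$d)
    stop_domain("config d inconsistent with length of p")
  m
}
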