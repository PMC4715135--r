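# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Signed log-sum: given log|x_i| and sign(x_i), return sum(x_i) as a double.
# Positive and negative masses are accumulated separately at a common scale;
# this keeps intermediate magnitudes bounded even when individual terms
# overflow double range.
signed_log_sum <- function(log_abs, sign) {
  keep <- is.finite(log_abs) & sign != 0
  log_abs <- log_abs[keep]
  sign <- sign[keep]
  if (!length(log_abs)) return(0)
  m <- max(log_abs)
  s <- sum(sign * exp(log_abs - m))
  s * exp(m)
}

# All compositions of `n` into `k` nonnegative parts, as a matrix with one
# composition per row (choose(n + k - 1, k - 1) rows).
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, nrow = 1L))
  out <- vector("list", n + 1L)
  for (first in 0:n) {
    rest <- compositions(n - first, k - 1L)
    out[[first + 1L]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

# Vectorised binomial log-pmf robust to p = 0/1 endpoints.
log_dbinom <- function(x, size, prob) {
  stats::dbinom(x, size, prob, log = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) {
  stop(structure(class = c("codbayes_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
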