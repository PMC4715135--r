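#' Nonparametric CoD estimators
#'
#' Classical baselines built on the plug-in (sample-frequency) predictor:
#' resubstitution, leave-one-out, 0.632 bootstrap, and 10-repeated twofold
#' cross-validation. The plug-in rule predicts, for each predictor cell,
#' the majority target label among training samples in the cell; cells
#' never seen in training, and within-cell ties, predict the training-set
#' majority class (overall ties predict 0). In every scheme the
#' no-observation error is estimated by full-sample class frequencies,
#' \eqn{\hat\varepsilon_0 = \min(n_0, n_1)/n}, and
#' \eqn{\widehat{CoD} = 1 - \hat\varepsilon / \hat\varepsilon_0} (0 when
#' \eqn{\hat\varepsilon_0 = 0}). Cross-validated estimates can be negative;
#' the primary value is clipped to \[0, 1\] with the raw value kept in the
#' diagnostics.
#'
#' @name classical-estimators
NULL

# plug-in predictions per cell from count vectors (U, V): 1 where V > U,
# 0 where U > V, majority class on ties/unseen cells (0 on an overall tie).
plugin_rule <- function(U, V) {
  maj <- if (sum(V) > sum(U)) 1L else 0L
  pred <- rep(maj, length(U))
  pred[U > V] <- 0L
  pred[V > U] <- 1L
  pred
}

# training error of `pred` evaluated on counts (U, V)
plugin_error <- function(pred, U, V) {
  n <- sum(U) + sum(V)
  if (n == 0) return(0)
  sum(ifelse(pred == 1L, U, V)) / n
}

classical_result <- function(raw, e, e0, name, extra = list()) {
  cod_estimate(min(max(raw, 0), 1), name,
               diagnostics = c(list(raw = raw, eps = e, eps0 = e0), extra))
}

#' Resubstitution CoD estimator
#'
#' Trains the plug-in rule on the full sample and evaluates it on the same
#' sample (the original sample-frequency CoD estimator; optimistically
#' biased).
#'
#' @param samples a `binary_samples` object.
#' @return A `cod_estimate` tagged `"resub"`.
#' @export
resub_cod <- function(samples) {
  ct <- count_samples(samples)
  n <- ct$n0 + ct$n1
  if (n < 1) stop_domain("resub_cod needs n >= 1")
  e0 <- min(ct$n0, ct$n1) / n
  if (e0 == 0) return(classical_result(0, 0, 0, "resub"))
  pred <- plugin_rule(ct$U, ct$V)
  e <- plugin_error(pred, ct$U, ct$V)
  classical_result(1 - e / e0, e, e0, "resub")
}

#' Leave-one-out CoD estimator
#'
#' Each sample point is held out in turn; the plug-in rule trained on the
#' remaining n - 1 points predicts it. Grouping identical (cell, label)
#' points makes the loop O(2^{d+1}) rather than O(n).
#'
#' @param samples a `binary_samples` object (n >= 2).
#' @return A `cod_estimate` tagged `"loo"`.
#' @export
loo_cod <- function(samples) {
  ct <- count_samples(samples)
  n <- ct$n0 + ct$n1
  if (n < 2) stop_domain("loo_cod needs n >= 2")
  e0 <- min(ct$n0, ct$n1) / n
  if (e0 == 0) return(classical_result(0, 0, 0, "loo"))
  errs <- 0
  for (i in seq_along(ct$U)) {
    if (ct$U[i] > 0) {           # hold out one (cell i, y = 0) point
      U <- ct$U; U[i] <- U[i] - 1
      p <- plugin_rule(U, ct$V)[i]
      errs <- errs + ct$U[i] * (p == 1L)
    }
    if (ct$V[i] > 0) {           # hold out one (cell i, y = 1) point
      V <- ct$V; V[i] <- V[i] - 1
      p <- plugin_rule(ct$U, V)[i]
      errs <- errs + ct$V[i] * (p == 0L)
    }
  }
  e <- errs / n
  classical_result(1 - e / e0, e, e0, "loo")
}

#' 0.632 bootstrap CoD estimator
#'
#' \eqn{\hat\varepsilon = 0.632\,\hat\varepsilon_{boot} +
#' 0.368\,\hat\varepsilon_{resub}}, where the bootstrap component averages
#' out-of-bag errors over `B` resamples (resamples with an empty out-of-bag
#' set are skipped).
#'
#' @param samples a `binary_samples` object (n >= 2).
#' @param B number of bootstrap resamples.
#' @param seed integer seed.
#' @return A `cod_estimate` tagged `"b632"`.
#' @export
b632_cod <- function(samples, B = 100, seed = NULL) {
  ct <- count_samples(samples)
  n <- ct$n0 + ct$n1
  if (n < 2) stop_domain("b632_cod needs n >= 2")
  if (B < 1) stop_domain("B must be >= 1")
  e0 <- min(ct$n0, ct$n1) / n
  if (e0 == 0) return(classical_result(0, 0, 0, "b632"))
  pred_full <- plugin_rule(ct$U, ct$V)
  e_resub <- plugin_error(pred_full, ct$U, ct$V)
  b2 <- 2L^samples$d
  oob_err <- with_seed(seed, {
    vapply(seq_len(B), function(rep) {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), idx)
      if (!length(oob)) return(NA_real_)
      cells_b <- samples$cells[idx]; y_b <- samples$y[idx]
      U <- tabulate(cells_b[y_b == 0L], nbins = b2)
      V <- tabulate(cells_b[y_b == 1L], nbins = b2)
      pred <- plugin_rule(U, V)
      mean(pred[samples$cells[oob]] != samples$y[oob])
    }, 0)
  })
  e_boot <- mean(oob_err, na.rm = TRUE)
  if (is.nan(e_boot)) e_boot <- e_resub
  e <- 0.632 * e_boot + 0.368 * e_resub
  classical_result(1 - e / e0, e, e0, "b632",
                   extra = list(B = B, e_boot = e_boot))
}

#' 10-repeated twofold cross-validation CoD estimator
#'
#' Ten repetitions of a random class-stratified split into halves; the
#' plug-in rule trained on each half is tested on the other, and the 20
#' fold errors are averaged.
#'
#' @param samples a `binary_samples` object (n >= 2).
#' @param reps number of repetitions.
#' @param seed integer seed.
#' @return A `cod_estimate` tagged `"cv10x2"`.
#' @export
cv10x2_cod <- function(samples, reps = 10, seed = NULL) {
  ct <- count_samples(samples)
  n <- ct$n0 + ct$n1
  if (n < 2) stop_domain("cv10x2_cod needs n >= 2")
  e0 <- min(ct$n0, ct$n1) / n
  if (e0 == 0) return(classical_result(0, 0, 0, "cv10x2"))
  b2 <- 2L^samples$d
  idx0 <- which(samples$y == 0L); idx1 <- which(samples$y == 1L)
  fold_errs <- with_seed(seed, {
    unlist(lapply(seq_len(reps), function(rep) {
      half <- c(sample(idx0, floor(length(idx0) / 2)),
                sample(idx1, ceiling(length(idx1) / 2)))
      other <- setdiff(seq_len(n), half)
      vapply(list(c(1, 2), c(2, 1)), function(o) {
        tr <- if (o[1] == 1) half else other
        te <- if (o[1] == 1) other else half
        U <- tabulate(samples$cells[tr][samples$y[tr] == 0L], nbins = b2)
        V <- tabulate(samples$cells[tr][samples$y[tr] == 1L], nbins = b2)
        pred <- plugin_rule(U, V)
        mean(pred[samples$cells[te]] != samples$y[te])
      }, 0)
    }))
  })
  e <- mean(fold_errs)
  classical_result(1 - e / e0, e, e0, "cv10x2", extra = list(reps = reps))
}
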