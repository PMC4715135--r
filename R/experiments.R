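#' Simulation designs: global and fixed-parameter benchmarks
#'
#' Two benchmark designs. The *global* design draws the model parameters
#' from the prior in every replicate (so the MMSE estimator is exactly
#' unbiased and RMS-optimal on average) and compares all estimators over a
#' grid of sample sizes. The *fixed-parameter* design freezes the model at
#' one of three reference distributions (d = 1, 2, 3) and evaluates the
#' Bayesian estimators under flat, matched, poorly matched and mismatched
#' prior base measures at three concentration levels; the OBP entries are
#' computed exactly, the rest by Monte Carlo.
#'
#' @name experiments
NULL

#' Reference fixed-parameter models and prior base measures
#'
#' For each d in 1..3: the true conditional distribution `p_star` (with
#' `q_star` its left-right flip and `c_star = 0.5`) and the three nonflat
#' prior base measures (`matched` = the true distribution, `poor`,
#' `mismatched`), with `q0` again the flip of `p0` for matched/poor and as
#' tabulated for mismatched.
#'
#' @return Named list (`d1`, `d2`, `d3`), each with elements `model` (a
#'   [discrete_model()]), `c0`, and `base` — a named list of
#'   `matched`/`poor`/`mismatched` entries, each a list with `p0`, `q0`.
#' @export
table1_models <- function() {
  specs <- list(
    d1 = list(
      p_star = c(0.6, 0.4),
      matched = c(0.6, 0.4),
      poor = c(0.5, 0.5),
      mismatched = c(0.4, 0.6)),
    d2 = list(
      p_star = c(0.2, 0.3, 0.1, 0.4),
      matched = c(0.2, 0.3, 0.1, 0.4),
      poor = c(0.3, 0.2, 0.2, 0.3),
      mismatched = c(0.4, 0.1, 0.3, 0.2)),
    d3 = list(
      p_star = c(0.1, 0.15, 0.05, 0.2, 0.15, 0.1, 0.1, 0.15),
      matched = c(0.1, 0.15, 0.05, 0.2, 0.15, 0.1, 0.1, 0.15),
      poor = c(0.15, 0.1, 0.1, 0.15, 0.1, 0.05, 0.15, 0.2),
      mismatched = c(0.2, 0.05, 0.15, 0.1, 0.05, 0.2, 0.2, 0.05)))
  lapply(specs, function(s) {
    list(model = discrete_model(0.5, s$p_star, rev(s$p_star)),
         c0 = 0.5,
         base = lapply(s[c("matched", "poor", "mismatched")], function(p0)
           list(p0 = p0, q0 = rev(p0))))
  })
}

#' Concentration levels for the fixed-parameter design
#'
#' Maps a level tag to the concentration triple
#' \eqn{\Delta_c/2 = \Delta_p = \Delta_q}: per d,
#' high-variance / medium / low-variance correspond to
#' d = 1: 5/25/50, d = 2: 10/50/100, d = 3: 20/100/200.
#'
#' @param d number of predictors (1..3).
#' @param level one of `"high"`, `"medium"`, `"low"` (prior variance).
#' @return List with `delta_c`, `delta_p`, `delta_q`.
#' @export
concentration_level <- function(d, level = c("high", "medium", "low")) {
  level <- match.arg(level)
  tab <- list(`1` = c(high = 5, medium = 25, low = 50),
              `2` = c(high = 10, medium = 50, low = 100),
              `3` = c(high = 20, medium = 100, low = 200))
  dd <- tab[[as.character(d)]]
  if (is.null(dd)) stop_domain("concentration levels defined for d in 1..3")
  v <- dd[[level]]
  list(delta_c = 2 * v, delta_p = v, delta_q = v)
}

#' Build a prior from base measures and concentrations
#'
#' \eqn{\alpha = c_0 \Delta_c}, \eqn{\beta = (1 - c_0)\Delta_c},
#' \eqn{\alpha_{vec} = p_0 \Delta_p}, \eqn{\beta_{vec} = q_0 \Delta_q}.
#' Products are kept exact (possibly non-integer), which routes the MMSE
#' closed form through its truncated-series path.
#'
#' @param c0 base measure for `c`.
#' @param p0,q0 base-measure probability vectors.
#' @param delta_c,delta_p,delta_q positive concentrations.
#' @return A [prior_spec()].
#' @export
build_prior <- function(c0, p0, q0, delta_c, delta_p, delta_q) {
  prior_spec(c0 * delta_c, (1 - c0) * delta_c, p0 * delta_p, q0 * delta_q)
}

#' The flat reference prior
#'
#' \eqn{\alpha = \beta = 2^d + 1} (peaking the `c`-prior around 0.5 just
#' enough to keep the closed form valid against uniform Dirichlets) and
#' \eqn{\alpha_i = \beta_i = 1}.
#'
#' @param d number of predictors.
#' @return A [prior_spec()].
#' @export
flat_prior <- function(d) {
  prior_spec(2^d + 1, 2^d + 1, rep(1, 2^d), rep(1, 2^d))
}

#' Configure an experiment
#'
#' @param d number of predictors (1..3).
#' @param n_grid sample sizes.
#' @param estimators estimator tags (see [global_accuracy()]).
#' @param scenario prior scenario for the fixed design:
#'   `"flat"`, `"matched"`, `"poor"`, or `"mismatched"`.
#' @param level concentration level for nonflat scenarios.
#' @param M Monte-Carlo replicates.
#' @param seed integer seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(d = 1, n_grid = seq(10, 60, by = 10),
                              estimators = c("mmse", "obp", "resub", "loo",
                                             "b632", "cv10x2"),
                              scenario = c("flat", "matched", "poor",
                                           "mismatched"),
                              level = c("high", "medium", "low"),
                              M = 1000, seed = 1) {
  scenario <- match.arg(scenario)
  level <- match.arg(level)
  structure(list(d = d, n_grid = n_grid, estimators = estimators,
                 scenario = scenario, level = level, M = M, seed = seed),
            class = "experiment_config")
}

# prior implied by a config's scenario/level for the fixed design
scenario_prior <- function(config) {
  if (config$scenario == "flat") return(flat_prior(config$d))
  t1 <- table1_models()[[paste0("d", config$d)]]
  base <- t1$base[[config$scenario]]
  conc <- concentration_level(config$d, config$level)
  build_prior(t1$c0, base$p0, base$q0,
              conc$delta_c, conc$delta_p, conc$delta_q)
}

#' Global benchmark over a sample-size grid
#'
#' For each n in the grid and each estimator, runs [global_accuracy()]
#' under the flat reference prior (parameters redrawn from the prior each
#' replicate). Each (n, estimator) pair uses an independent substream
#' derived from `config$seed`, so results are reproducible and
#' per-estimator comparisons at one n share nothing but the design.
#'
#' @param config an [experiment_config()] (default `M = 1000`; the
#'   headline study in this package's documentation uses `M = 2000`).
#' @param prior optional [prior_spec()] overriding the flat default.
#' @return A tidy data.frame: `n`, `estimator`, `bias`, `variance`, `rms`,
#'   `se_bias`, `se_rms`, `M`.
#' @export
run_global <- function(config, prior = NULL) {
  prior <- prior %||% flat_prior(config$d)
  rows <- list()
  for (ni in seq_along(config$n_grid)) {
    n <- config$n_grid[ni]
    for (ei in seq_along(config$estimators)) {
      est <- config$estimators[ei]
      sub_seed <- (config$seed * 1000L + ni * 100L + ei) %% .Machine$integer.max
      rep <- global_accuracy(prior, config$d, n, config$M,
                             seed = sub_seed, estimator = est)
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, estimator = est, bias = rep$bias, variance = rep$variance,
        rms = rep$rms, se_bias = rep$se$bias, se_rms = rep$se$rms,
        M = config$M)
    }
  }
  do.call(rbind, rows)
}

#' Shared-sample global benchmark
#'
#' Like [run_global()] but evaluates every estimator on the *same*
#' simulated data sets, which removes between-estimator Monte-Carlo noise
#' from ordering comparisons (paired design).
#'
#' @inheritParams run_global
#' @return A tidy data.frame as in [run_global()].
#' @export
run_global_paired <- function(config, prior = NULL) {
  prior <- prior %||% flat_prior(config$d)
  fns <- lapply(config$estimators, estimator_fn)
  rows <- list()
  for (ni in seq_along(config$n_grid)) {
    n <- config$n_grid[ni]
    devs <- with_seed((config$seed * 1000L + ni) %% .Machine$integer.max, {
      out <- matrix(0, config$M, length(fns))
      for (m in seq_len(config$M)) {
        th <- draw_model_from_prior(prior)
        s <- sample_model(th, n)
        cod <- true_cod(th)
        for (k in seq_along(fns)) out[m, k] <- fns[[k]](s, prior)$value - cod
      }
      out
    })
    for (k in seq_along(fns)) {
      rep <- summarize_deviations(devs[, k], config$estimators[k], n,
                                  config$M)
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, estimator = config$estimators[k], bias = rep$bias,
        variance = rep$variance, rms = rep$rms, se_bias = rep$se$bias,
        se_rms = rep$se$rms, M = config$M)
    }
  }
  do.call(rbind, rows)
}

#' Fixed-parameter benchmark
#'
#' Evaluates estimators at the frozen reference model for `config$d` under
#' the configured prior scenario. OBP rows are computed exactly
#' ([obp_fixed_accuracy()]); all other estimators are approximated by
#' averaging over `config$M` Monte-Carlo samples drawn from the fixed
#' model.
#'
#' @inheritParams run_global
#' @param model optional [discrete_model()] overriding the reference model.
#' @return A tidy data.frame: `n`, `estimator`, `scenario`, `level`,
#'   `bias`, `variance`, `rms`, `method`, `se_bias`, `se_rms`.
#' @export
run_fixed <- function(config, model = NULL, prior = NULL) {
  model <- model %||% table1_models()[[paste0("d", config$d)]]$model
  prior <- prior %||% scenario_prior(config)
  cod <- true_cod(model)
  rows <- list()
  for (ni in seq_along(config$n_grid)) {
    n <- config$n_grid[ni]
    for (ei in seq_along(config$estimators)) {
      est <- config$estimators[ei]
      if (identical(est, "obp")) {
        rep <- obp_fixed_accuracy(model, prior, n)
        se_b <- 0; se_r <- 0
      } else {
        fn <- estimator_fn(est)
        sub_seed <- (config$seed * 1000L + ni * 100L + ei) %%
          .Machine$integer.max
        dev <- with_seed(sub_seed, vapply(seq_len(config$M), function(m) {
          s <- sample_model(model, n)
          fn(s, prior)$value - cod
        }, 0))
        rep <- summarize_deviations(dev, est, n, config$M)
        se_b <- rep$se$bias; se_r <- rep$se$rms
      }
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, estimator = est, scenario = config$scenario,
        level = config$level, bias = rep$bias, variance = rep$variance,
        rms = rep$rms, method = rep$method, se_bias = se_b, se_rms = se_r)
    }
  }
  do.call(rbind, rows)
}
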