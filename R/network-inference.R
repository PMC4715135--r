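#' Boolean gene-regulatory-network inference via Bayesian CoD estimation
#'
#' The regulation model ties a binary target expression Y to binary
#' predictor expressions X through \eqn{Y = f(X) \oplus N}, where f is a
#' Boolean function of k essential inputs chosen from the candidate genes
#' (its *wiring*), \eqn{\oplus} is XOR, and N is Bernoulli noise with
#' \eqn{P(N = 0) = p} (the *predictive power*). Inference proceeds per
#' target gene by a two-step empirical-Bayes model selection: for every
#' candidate Boolean function g of exactly k essential variables, score all
#' wirings with a Bayesian CoD estimate under hyperparameters centred on
#' the sample-estimated regulation (step 1, best wiring per g), then pick
#' the (g, wiring) pair with the largest predictive-power estimate
#' \eqn{\hat p} (step 2). Ties are broken uniformly at random under the
#' run's seed.
#'
#' @name network-inference
NULL

#' Enumerate Boolean functions with all variables essential
#'
#' A variable is *essential* if flipping it changes the function output for
#' at least one input pattern; constants and functions reducible to fewer
#' inputs are excluded. Counts: k = 1 gives 2, k = 2 gives 10, k = 3 gives
#' 218 of the 256 three-input functions.
#'
#' @param k number of inputs (1..4).
#' @return A 0/1 matrix, one truth table per row, columns in logic-table
#'   order (row index of pattern = [cell_index()] of the inputs; e.g. AND
#'   for k = 3 is `00000001`).
#' @export
enumerate_essential <- function(k) {
  if (k < 1 || k > 4) stop_domain("enumerate_essential supports k in 1..4")
  nc <- 2L^k
  patterns <- cell_pattern(seq_len(nc), k)
  tables <- as.matrix(expand.grid(rep(list(0:1), nc))[, nc:1, drop = FALSE])
  colnames(tables) <- NULL
  # pair each pattern with its flip along every variable
  flip_idx <- vapply(seq_len(k), function(v) {
    flipped <- patterns
    flipped[, v] <- 1L - flipped[, v]
    cell_index(flipped)
  }, integer(nc))
  essential <- vapply(seq_len(nrow(tables)), function(f) {
    tab <- tables[f, ]
    all(vapply(seq_len(k), function(v)
      any(tab != tab[flip_idx[, v]]), TRUE))
  }, TRUE)
  tables[essential, , drop = FALSE]
}

#' Construct a Boolean regulation
#'
#' @param table 0/1 truth table of length `2^k` in logic-table order.
#' @param wiring ordered (ascending) distinct predictor indices.
#' @param p_hat predictive-power estimate in \[0, 1\] (optional).
#' @param require_essential validate that all inputs are essential.
#' @return A `boolean_regulation` object.
#' @export
boolean_regulation <- function(table, wiring, p_hat = NA_real_,
                               require_essential = TRUE) {
  table <- as.integer(table)
  k <- log2(length(table))
  if (abs(k - round(k)) > 1e-9 || any(table != 0 & table != 1))
    stop_domain("truth table must be a 0/1 vector of length 2^k")
  k <- as.integer(round(k))
  wiring <- as.integer(wiring)
  if (length(wiring) != k || anyDuplicated(wiring) || any(wiring < 1))
    stop_domain("wiring must be k distinct positive indices")
  if (require_essential && !is_essential(table))
    stop_domain("truth table has non-essential inputs")
  structure(list(k = k, table = table, wiring = sort(wiring),
                 p_hat = p_hat),
            class = "boolean_regulation")
}

is_essential <- function(table) {
  k <- as.integer(round(log2(length(table))))
  patterns <- cell_pattern(seq_len(2L^k), k)
  all(vapply(seq_len(k), function(v) {
    flipped <- patterns
    flipped[, v] <- 1L - flipped[, v]
    any(table != table[cell_index(flipped)])
  }, TRUE))
}

#' @export
print.boolean_regulation <- function(x, ...) {
  cat(sprintf("Boolean regulation: k = %d, table = %s, wiring = {%s}",
              x$k, paste(x$table, collapse = ""),
              paste(x$wiring, collapse = ",")))
  if (is.finite(x$p_hat)) cat(sprintf(", p_hat = %.4g", x$p_hat))
  cat("\n")
  invisible(x)
}

#' Predictive-power estimate
#'
#' The sample frequency of agreement between the regulation's noiseless
#' output and the observed target:
#' \eqn{\hat p = n^{-1} \sum_j I(f(X_j) = Y_j)}.
#'
#' @param x 0/1 matrix of predictor expressions (samples x genes).
#' @param y 0/1 target vector.
#' @param regulation a [boolean_regulation()] whose wiring indexes columns
#'   of `x`.
#' @return \eqn{\hat p \in [0, 1]}.
#' @export
predictive_power <- function(x, y, regulation) {
  if (!nrow(x)) stop_domain("predictive_power needs n >= 1")
  cells <- cell_index(x[, regulation$wiring, drop = FALSE])
  mean(regulation$table[cells] == y)
}

#' Empirical-Bayes hyperparameters from a fitted regulation
#'
#' Under the XOR-noise regulation model with a flat predictor distribution
#' \eqn{P(X = x^i) = 2^{-k}}, the implied cell probabilities are
#' \eqn{\hat p_i \propto \hat p(1 - f(x^i)) + (1-\hat p) f(x^i)} (Y = 0
#' side), \eqn{\hat q_i \propto \hat p f(x^i) + (1-\hat p)(1 - f(x^i))},
#' and \eqn{\hat c = 2^{-k} \sum_i (\hat p(1-f(x^i)) + (1-\hat p) f(x^i))}.
#' These normalised estimates become the prior base measure; the
#' hyperparameters are their ceilings after scaling by the concentration
#' \eqn{\Delta}: \eqn{\alpha_i = \lceil \hat p_i \Delta \rceil}, etc.
#' Cells with exactly zero mass (only when \eqn{\hat p} is exactly 0 or 1)
#' are floored at shape 1 to keep the prior proper.
#'
#' @param p_hat predictive-power estimate in \[0, 1\].
#' @param table 0/1 truth table (or a [boolean_regulation()]).
#' @param delta concentration parameter (> 0).
#' @return A [prior_spec()].
#' @export
empirical_hyperparams <- function(p_hat, table, delta = 1) {
  if (inherits(table, "boolean_regulation")) table <- table$table
  if (p_hat < 0 || p_hat > 1) stop_domain("p_hat must be in [0,1]")
  if (delta <= 0) stop_domain("delta must be > 0")
  f <- as.numeric(table)
  w0 <- p_hat * (1 - f) + (1 - p_hat) * f
  w1 <- p_hat * f + (1 - p_hat) * (1 - f)
  c_hat <- mean(w0)
  p_i <- if (sum(w0) > 0) w0 / sum(w0) else rep(1 / length(f), length(f))
  q_i <- if (sum(w1) > 0) w1 / sum(w1) else rep(1 / length(f), length(f))
  # tolerance shields the ceiling from floating error in the products
  # (e.g. (0.9/1.6)*64 must ceil to 36, not 37)
  ceil1 <- function(z) pmax(ceiling(z - 1e-9), 1)
  prior_spec(ceil1(c_hat * delta), ceil1((1 - c_hat) * delta),
             ceil1(p_i * delta), ceil1(q_i * delta))
}

# CoD of one candidate (counts already tallied for its wiring)
candidate_cod <- function(estimator, prior, counts, samples, mmse_reps) {
  switch(estimator,
    obp = obp_cod(prior, counts)$value,
    mmse = mmse_cod(prior, counts, reps = mmse_reps)$value,
    stop_domain("unknown Bayesian estimator: ", estimator))
}

#' Two-step Bayesian model selection for one target gene
#'
#' Step 1: for each Boolean function g of exactly k essential variables,
#' score every \eqn{\binom{d}{k}} wiring with the chosen CoD estimator
#' under [empirical_hyperparams()] and keep the best wiring (random
#' tie-break). Step 2: among the per-function winners, select the pair
#' with the largest \eqn{\hat p} (random tie-break). With
#' `estimator = "resub"` the standard procedure is used instead: the
#' wiring with the largest resubstitution CoD is selected and the fitted
#' plug-in predictor provides the logic.
#'
#' @param x 0/1 matrix of candidate predictor expressions (the target must
#'   not be among its columns).
#' @param y 0/1 target vector.
#' @param k number of essential inputs (k < ncol(x) + 1).
#' @param delta concentration for the empirical-Bayes prior.
#' @param estimator `"obp"`, `"mmse"`, or `"resub"`.
#' @param seed integer seed (drives tie-breaks and any MC fallback).
#' @param mmse_reps Monte-Carlo replicates for the MMSE fallback (the
#'   delta = 1 default always routes MMSE through the fallback, since its
#'   flat ceiling priors violate the closed-form constraint).
#' @param keep_scores also return the full candidate score table.
#' @return List with `regulation` (a [boolean_regulation()] with `p_hat`
#'   set), `cod`, `estimator`, and optionally `scores`.
#' @export
select_model <- function(x, y, k = 3, delta = 1,
                         estimator = c("obp", "mmse", "resub"),
                         seed = NULL, mmse_reps = 20000,
                         keep_scores = FALSE) {
  estimator <- match.arg(estimator)
  if (!is.matrix(x)) x <- as.matrix(x)
  d <- ncol(x)
  if (k > d) stop_domain("k exceeds the number of candidate predictors")
  wirings <- utils::combn(d, k)
  nw <- ncol(wirings)
  with_seed(seed, {
    # per-wiring cell codes and (U, V) counts are shared by all functions
    wiring_cells <- lapply(seq_len(nw), function(w)
      cell_index(x[, wirings[, w], drop = FALSE]))
    wiring_counts <- lapply(wiring_cells, function(cl)
      count_samples(binary_samples_cells(cl, y, k)))

    if (estimator == "resub") {
      cods <- vapply(seq_len(nw), function(w)
        resub_cod(binary_samples_cells(wiring_cells[[w]], y, k))$value, 0)
      best <- random_argmax(cods)
      ct <- wiring_counts[[best]]
      tab <- plugin_rule(ct$U, ct$V)
      reg <- boolean_regulation(tab, wirings[, best],
                                p_hat = mean(tab[wiring_cells[[best]]] == y),
                                require_essential = FALSE)
      return(list(regulation = reg, cod = cods[best], estimator = "resub",
                  scores = if (keep_scores)
                    data.frame(wiring = apply(wirings, 2, paste,
                                              collapse = ","),
                               cod = cods) else NULL))
    }

    G <- enumerate_essential(k)
    ng <- nrow(G)
    win_w <- integer(ng); win_cod <- numeric(ng); win_p <- numeric(ng)
    scores <- if (keep_scores)
      vector("list", ng) else NULL
    for (gi in seq_len(ng)) {
      tab <- G[gi, ]
      p_hats <- vapply(seq_len(nw), function(w)
        mean(tab[wiring_cells[[w]]] == y), 0)
      cods <- vapply(seq_len(nw), function(w) {
        pr <- empirical_hyperparams(p_hats[w], tab, delta)
        candidate_cod(estimator, pr, wiring_counts[[w]], NULL, mmse_reps)
      }, 0)
      bw <- random_argmax(cods)                      # step 1
      win_w[gi] <- bw; win_cod[gi] <- cods[bw]; win_p[gi] <- p_hats[bw]
      if (keep_scores)
        scores[[gi]] <- data.frame(
          g = paste(tab, collapse = ""),
          wiring = apply(wirings, 2, paste, collapse = ","),
          cod = cods, p_hat = p_hats)
    }
    bg <- random_argmax(win_p)                       # step 2
    reg <- boolean_regulation(G[bg, ], wirings[, win_w[bg]],
                              p_hat = win_p[bg])
    list(regulation = reg, cod = win_cod[bg], estimator = estimator,
         scores = if (keep_scores) do.call(rbind, scores) else NULL)
  })
}

# index of the maximum, ties resolved uniformly at random (ambient RNG)
random_argmax <- function(v, tol = 1e-12) {
  cand <- which(v >= max(v) - tol)
  if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
}

#' Infer a Boolean regulatory network from a binarized expression matrix
#'
#' Considers each gene in turn as the target with all remaining genes as
#' candidate predictors (a gene never predicts itself) and runs
#' [select_model()].
#'
#' @param mat 0/1 expression matrix, samples in rows, genes in columns
#'   (column names used as gene names).
#' @param k predictors per target.
#' @param delta concentration for the empirical-Bayes prior.
#' @param estimator `"obp"`, `"mmse"`, or `"resub"`.
#' @param seed integer seed.
#' @param mmse_reps see [select_model()].
#' @return A `cod_network`: data.frame with one row per target — `target`,
#'   `predictors` (comma-joined gene names), `table` (truth-table
#'   bitstring in logic-table order), `cod`, `p_hat`, `estimator`.
#' @export
infer_network <- function(mat, k = 3, delta = 1,
                          estimator = c("obp", "mmse", "resub"),
                          seed = NULL, mmse_reps = 20000) {
  estimator <- match.arg(estimator)
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (any(mat != 0 & mat != 1)) stop_domain("expression matrix must be 0/1")
  g <- ncol(mat)
  if (g < k + 1) stop_domain("need at least k + 1 genes")
  genes <- colnames(mat) %||% paste0("g", seq_len(g))
  colnames(mat) <- genes
  rows <- with_seed(seed, lapply(seq_len(g), function(j) {
    sel <- select_model(mat[, -j, drop = FALSE], mat[, j], k = k,
                        delta = delta, estimator = estimator,
                        mmse_reps = mmse_reps)
    pred_names <- genes[-j][sel$regulation$wiring]
    data.frame(target = genes[j],
               predictors = paste(pred_names, collapse = ","),
               table = paste(sel$regulation$table, collapse = ""),
               cod = sel$cod, p_hat = sel$regulation$p_hat,
               estimator = estimator)
  }))
  structure(do.call(rbind, rows), class = c("cod_network", "data.frame"))
}

#' Top regulatory relationships by CoD magnitude
#'
#' @param network a `cod_network`.
#' @param top number of relationships to keep.
#' @param seed seed for random tie-breaks in the ranking.
#' @return The top rows of the network, ordered by decreasing CoD.
#' @export
top_relationships <- function(network, top = 3, seed = NULL) {
  with_seed(seed, {
    ord <- order(-network$cod, sample.int(nrow(network)))
    network[ord[seq_len(min(top, nrow(network)))], ]
  })
}

#' Generate a synthetic binarized expression matrix
#'
#' Simulates the XOR-noise regulation model over an acyclic network
#' specification: root genes are independent Bernoulli, regulated genes
#' are their Boolean function of already-generated regulators, flipped
#' with probability 1 - p. Emulates the shape of a small binarized
#' expression study (defaults elsewhere: n = 31 samples, 7 genes).
#'
#' @param spec a list of per-gene specs, each a list with `name` and
#'   either `prob` (root: P(expression = 1)) or `regulators` (character
#'   names, ascending order defines the truth-table input order), `table`
#'   (0/1 of length `2^k`), and `p` (predictive power).
#' @param n number of samples.
#' @param seed integer seed.
#' @return An `n x length(spec)` 0/1 matrix with gene-name columns.
#' @export
synth_expression <- function(spec, n = 31, seed = NULL) {
  names <- vapply(spec, function(s) s$name, "")
  if (anyDuplicated(names)) stop_domain("duplicate gene names in spec")
  with_seed(seed, {
    mat <- matrix(NA_integer_, n, length(spec),
                  dimnames = list(NULL, names))
    done <- rep(FALSE, length(spec))
    repeat {
      progressed <- FALSE
      for (j in seq_along(spec)) {
        if (done[j]) next
        s <- spec[[j]]
        if (!is.null(s$prob)) {
          mat[, j] <- stats::rbinom(n, 1L, s$prob)
        } else {
          ridx <- match(s$regulators, names)
          if (anyNA(ridx)) stop_domain("unknown regulator in spec: ",
                                       paste(s$regulators, collapse = ","))
          if (!all(done[ridx])) next
          cells <- cell_index(mat[, ridx, drop = FALSE])
          f <- as.integer(s$table)[cells]
          noise <- stats::rbinom(n, 1L, 1 - s$p)
          mat[, j] <- bitwXor(f, noise)
        }
        done[j] <- TRUE; progressed <- TRUE
      }
      if (all(done)) break
      if (!progressed)
        stop_domain("cyclic network spec without initialization rule")
    }
    mat
  })
}

#' A reference synthetic 7-gene network specification
#'
#' A fixed acyclic ground truth used in examples and benchmarks: three
#' Bernoulli(0.5) root genes and four targets, each regulated by three
#' essential inputs (majority, parity, and two mixed AND/OR logics) with
#' the given predictive power. This is a synthetic stand-in with the shape
#' of a small binarized melanoma expression study; it does not reproduce
#' any real network.
#'
#' @param p predictive power shared by all regulated genes.
#' @return A spec list for [synth_expression()].
#' @export
example_network_spec <- function(p = 0.95) {
  list(
    list(name = "g1", prob = 0.5),
    list(name = "g2", prob = 0.5),
    list(name = "g3", prob = 0.5),
    # majority(g1, g2, g3)
    list(name = "g4", regulators = c("g1", "g2", "g3"),
         table = c(0, 0, 0, 1, 0, 1, 1, 1), p = p),
    # parity(g1, g2, g4)
    list(name = "g5", regulators = c("g1", "g2", "g4"),
         table = c(0, 1, 1, 0, 1, 0, 0, 1), p = p),
    # g2 AND (g3 OR g5)
    list(name = "g6", regulators = c("g2", "g3", "g5"),
         table = c(0, 0, 0, 0, 0, 1, 1, 1), p = p),
    # (g1 OR g4) AND NOT g6
    list(name = "g7", regulators = c("g1", "g4", "g6"),
         table = c(0, 0, 1, 0, 1, 0, 1, 0), p = p))
}

#' Read / write a binarized expression matrix
#'
#' Plain TSV or CSV with a header row of gene names; rows are samples,
#' entries 0/1. The separator is chosen from the file extension
#' (`.csv` = comma, otherwise tab).
#'
#' @param path file path.
#' @return A 0/1 integer matrix with gene-name columns.
#' @export
read_expression <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  mat <- as.matrix(df)
  if (any(mat != 0 & mat != 1))
    stop_domain("expression matrix entries must be 0/1")
  storage.mode(mat) <- "integer"
  mat
}

#' @rdname read_expression
#' @param mat 0/1 matrix with gene-name columns.
#' @export
write_expression <- function(mat, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(mat, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an inferred network as an edge-list TSV / DOT file
#'
#' @param network a `cod_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(network, path) {
  utils::write.table(as.data.frame(network), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
write_network_dot <- function(network, path) {
  lines <- c("digraph cod_network {")
  for (i in seq_len(nrow(network))) {
    preds <- strsplit(network$predictors[i], ",")[[1]]
    for (pp in preds)
      lines <- c(lines, sprintf(
        "  \"%s\" -> \"%s\" [label=\"CoD=%.3f\"];",
        pp, network$target[i], network$cod[i]))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
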