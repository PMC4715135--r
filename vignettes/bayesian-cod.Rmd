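---
title: "Bayesian inference of the discrete coefficient of determination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian inference of the discrete coefficient of determination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codbayes)
```

## The model

A binary target $Y \in \{0,1\}$ and binary predictors
$X = (X_1,\dots,X_d) \in \{0,1\}^d$ have joint law parameterised by
$\theta = (c, p, q)$ with $c = P(Y=0)$,
$p_i = P(X = x^i \mid Y=0)$ and $q_i = P(X = x^i \mid Y=1)$ over the
$2^d$ predictor cells. Throughout the package the cell enumeration is
fixed: cell $i$ is the binary expansion of $i-1$ with the most
significant bit equal to $X_1$. The discrete coefficient of
determination is
$$\mathrm{CoD} = \frac{\varepsilon_0 - \varepsilon}{\varepsilon_0},
\qquad
\varepsilon_0 = \min\{c, 1-c\}, \qquad
\varepsilon = \sum_i \min\{c\,p_i,\,(1-c)\,q_i\},$$
with $\mathrm{CoD} = 0$ by convention when $\varepsilon_0 = 0$
(a degenerate target; `true_cod()` applies this convention exactly).

Inference is Bayesian under the standard conjugate prior
$c \sim \mathrm{Beta}(\alpha,\beta)$,
$p \sim \mathrm{Dirichlet}(\alpha_1,\dots,\alpha_{2^d})$,
$q \sim \mathrm{Dirichlet}(\beta_1,\dots,\beta_{2^d})$, assumed
independent. A prior is conveniently described by its *base measure*
(the normalised shape vector — the prior mean) and its *concentration*
($\Delta_c = \alpha+\beta$, $\Delta_p = \sum_j \alpha_j$,
$\Delta_q = \sum_j \beta_j$): large concentrations peak the prior at the
base measure (component variance $a'_i(1-a'_i)/(\Delta+1)$), and
$\Delta = K$ with a uniform base measure is the flat prior.

## The two Bayesian estimators

**MMSE.** `mmse_cod()` returns the posterior expectation
$E[\mathrm{CoD} \mid S_n]$, which minimises mean-square error over the
joint law of parameters and samples and is globally unbiased. Splitting
the expectation by the sign of $c - 1/2$ and by which conditional
carries the leading factor gives, per cell, four terms; each is a
product of truncated Beta moments, and every truncated moment reduces to
incomplete-Beta evaluations
$IB(x;a,b) = \int_0^x u^{a-1}(1-u)^{b-1}\,du$ through
$$E\!\left[X^k(1-X)^l\, I_{X \le x}\right]
  = \frac{IB(x;\,a+k,\,b+l)}{B(a,b)}.$$
The package assembles these terms from the power-series representation
$IB(x;a,b) = \sum_i r_i(a,b)\,x^{a+i}$, where
$r_i(a,b) = \frac{(-1)^i}{a+i}\binom{b-1}{i}$ — a finite sum of exactly
$b$ terms when $b$ is a positive integer, an infinite (truncated) series
otherwise. The closed form requires $\alpha > \Delta_p - 1$ and
$\beta > \Delta_q - 1$ (otherwise one of the truncated $c$-moments has a
nonpositive shape at full depth); `check_mmse_validity()` tests this on
the prior, and `mmse_cod()` falls back automatically to Monte-Carlo
posterior sampling (`mmse_cod_mc()`) when it fails, flagging the
fallback in the diagnostics. In particular a uniform prior on $c$
cannot be combined with uniform Dirichlets on $p$ and $q$; the flat
reference prior `flat_prior(d)` therefore uses
$\alpha = \beta = 2^d + 1$ against unit Dirichlet shapes.

**OBP.** The optimal Bayesian predictor labels cell $i$ with 1 exactly
when the posterior-expected joint mass
$E[c\,p_i \mid S_n]$ is below $E[(1-c)\,q_i \mid S_n]$ (ties to 0), and
its CoD estimator is the plug-in ratio of posterior-expected errors,
$$\widehat{\mathrm{CoD}}_{\mathrm{OBP}}
 = 1 - \frac{1}{\min\{n_0+\alpha,\, n_1+\beta\}}
   \sum_i \min\!\left\{\tfrac{n_0+\alpha}{n_0+\Delta_p}(U_i+\alpha_i),\;
                       \tfrac{n_1+\beta}{n_1+\Delta_q}(V_i+\beta_i)\right\},$$
always in $[0,1]$ and computable in $O(2^d)$. It is not MMSE-optimal,
but under peaked priors centred near the true distribution its
fixed-parameter RMS can beat the MMSE estimator's.

## Exact fixed-parameter accuracy of the OBP estimator

At a fixed $\theta$ the OBP estimate is a function of $(n_0, U, V)$
only, so its sampling moments admit exact computation. Conditionally on
$n_0$, the normaliser $\min(n_0+\alpha, n_1+\beta)$ is deterministic and
the per-cell error terms are expectations of minima of affine functions
of independent binomial counts; the unconditional moments follow by a
two-branch sum over the values of the normaliser (the branch grids share
one boundary point when $n + \alpha - \beta$ is even, which is counted
once). The second moment needs, per ordered cell pair, joint trinomial
probabilities; these are evaluated as three matrix products per
$(i,j,n_0)$ triple, giving exact results for $n \le 60$, $d \le 3$ in
seconds. `obp_fixed_accuracy()` assembles bias, variance and RMS; the
identity $\mathrm{RMS}^2 = \mathrm{Variance} + \mathrm{Bias}^2$ holds to
$10^{-10}$ and everything is validated against
`enumerate_outcomes_oracle()`, an exhaustive enumeration of all sample
outcomes with exact multinomial probabilities.

The printed second-moment auxiliary-variable notation in the source
literature for this decomposition is internally inconsistent; the
package instead computes the pairwise expectations directly from the
per-cell min terms and exact joint probabilities, with the enumeration
oracle as the arbiter of correctness.

Analogous closed forms for the MMSE estimator are substantially harder;
its fixed-parameter accuracy is estimated by Monte Carlo, as is all
*global* (prior-averaged) accuracy (`global_accuracy()`).

## Numerical choices

* **Series truncation.** For non-integer $b$ the coefficient sequence is
  truncated once the next term's contribution at $x = 1$ falls below
  $10^{-12}$ of the running sum (hard cap $10^4$ terms); convergence is
  guaranteed (the term ratio tends to $x < 1$ beyond the alternating
  phase).
* **Stability.** All Beta-function arithmetic is carried in log space
  (posterior shapes reach $10^3$ without overflow), coefficient sums are
  accumulated as signed log-magnitudes, and two safeguards keep
  `inc_beta()` accurate to $\sim 10^{-12}$ over the full shape range:
  above the distribution bulk the complement identity
  $IB(x;a,b) = B(a,b) - IB(1-x;b,a)$ keeps the series argument small,
  and if the alternating partial sums are detected to cancel by more
  than four digits the sum is recomputed through its all-positive
  hypergeometric resummation
  $IB = \frac{x^a(1-x)^b}{a}\,{}_2F_1(a+b, 1; a+1; x)$.
* **Clamping.** Each of the four per-cell MMSE terms is clamped to
  $[0,1]$ and the total error mass to $[0,1]$; deviations beyond
  $10^{-8}$ raise a numerical warning (alternating-series cancellation
  is the only source).
* **Large samples.** The closed-form MMSE costs $O(n^2)$ coefficient
  pairs per cell; above $n = 2000$ the automatic path switches to the
  Monte-Carlo posterior estimate, which at that scale is both faster and
  accurate to the posterior's (tiny) spread.
* **Ties and degenerate inputs.** The OBP maps exact posterior ties to
  label 0 (the strict-inequality branch). All CoD estimators return 0
  when the relevant no-observation error is 0. The nonparametric
  plug-in rule predicts, per cell, the majority label; unseen cells and
  within-cell ties predict the training-set majority, and an overall tie
  predicts 0 — a fixed convention documented here because the classical
  schemes do not specify one.
* **Ceiling guard.** The empirical-Bayes map
  $\alpha_i = \lceil \hat p_i \Delta \rceil$ subtracts $10^{-9}$ before
  the ceiling so that exact products (e.g. $0.5625 \times 64 = 36$) are
  not pushed up by floating error, and floors every shape at 1 (shapes
  must be positive; a zero base-measure cell occurs only when
  $\hat p \in \{0, 1\}$ exactly).

## Classical baselines

Resubstitution (`resub_cod()`), leave-one-out (`loo_cod()`), 0.632
bootstrap (`b632_cod()`, default $B = 100$ resamples — the conventional
choice) and 10-repeated twofold cross-validation (`cv10x2_cod()`, with
class-stratified halving so small samples keep both classes in each
training fold) all use the plug-in rule above, with the no-observation
error estimated from full-sample class frequencies in every scheme (an
alternative would re-estimate it within each resampling scheme; the
full-sample version is used uniformly so that the schemes differ only in
how $\hat\varepsilon$ is estimated). Cross-validated CoD values can be
negative; the primary value is clipped to $[0,1]$ with the raw value
kept in the diagnostics.

## Simulation designs and problem sizes

`run_global()` redraws $\theta$ from the prior in every replicate —
under this design the MMSE estimator is exactly unbiased and
RMS-optimal, which the benchmark reproduces. `run_global_paired()`
evaluates all estimators on identical data sets, removing
between-estimator Monte-Carlo noise from ordering comparisons.
`run_fixed()` freezes $\theta$ at one of three reference models
($d = 1$: $p^* = (0.6, 0.4)$; $d = 2$: $p^* = (0.2,0.3,0.1,0.4)$;
$d = 3$: an eight-cell analogue; always $c^* = 0.5$ and $q^*$ the
left-right flip of $p^*$) and evaluates matched / poorly matched /
mismatched prior base measures at three concentration levels
($\Delta_c/2 = \Delta_p = \Delta_q \in \{5, 25, 50\}$ for $d=1$,
scaled up proportionally for $d = 2, 3$). Base-measure-times-
concentration products are kept exact even when non-integer — rounding
them would change the prior — which exercises the truncated-series path
of the closed form.

Default problem sizes are chosen at desk scale: $M = 1000$ replicates
for fixed-parameter Monte Carlo, $M = 2000$ for the headline global
benchmark, and a sample-size grid $n \in \{10, 20, \dots, 60\}$. The
qualitative conclusions (MMSE globally unbiased with least RMS, OBP
second, sharp RMS gains from peaked matched priors, resubstitution
optimism) are stable across seeds at these sizes; the grids and
replicate counts are configurable through `experiment_config()`.

## Network inference

For a target gene, the regulation model is $Y = f(X) \oplus N$ with
$f$ a Boolean function of $k$ essential inputs (a *wiring* of $k$ of the
candidate genes) and $P(N = 0) = p$ the predictive power.
`enumerate_essential(k)` lists all truth tables whose inputs are all
essential (2, 10 and 218 functions for $k = 1, 2, 3$). For each
candidate function the hyperparameters are set empirically: $\hat p$ is
the sample agreement frequency, $P(X)$ is taken flat
($1/2^k$ — frequency estimates of $P(X)$ are unreliable at these sample
sizes), the implied cell probabilities become the base measure, and a
concentration $\Delta$ scales them into (ceiled) shapes. Step 1 keeps,
per function, the wiring with the largest Bayesian CoD; step 2 selects
across functions by the largest $\hat p$; ties are broken uniformly at
random under the run's seed, and the whole selection is a pure function
of (data, seed). With the default $\Delta = 1$ every shape ceils to 1
(flat priors), which violates the MMSE closed-form constraint, so the
MMSE variant routes through the Monte-Carlo fallback; the OBP variant is
the fast default. Wirings are stored in ascending gene order and truth
tables are read in logic-table order with that input order (AND =
`00000001`) — one fixed convention shared by the generator, the
estimators, and the writers.

`synth_expression()` simulates this model over an acyclic network
specification and is the source of all benchmark fixtures, emulating the
*shape* of a small binarized expression study (31 samples, 7 genes, one
three-input regulation per non-root gene). What it does **not** emulate:
real binarization noise and thresholding artefacts, dependent predictor
distributions, feedback loops, or temporal dynamics. Passing benchmarks
on these fixtures therefore demonstrates correctness of the estimators
and of the selection procedure under the stated model — not biological
validity of any inferred network on real data.

## Known limitations

* Exact OBP second moments are gated to $n \le 60$, $d \le 3$ by cost
  (the worst case grows like $O(4^d n^4)$); beyond that use the
  Monte-Carlo route, which reports standard errors.
* The closed-form MMSE loses digits to alternating-sum cancellation as
  posterior shapes grow; terms are clamped and warnings raised beyond
  $10^{-8}$, and the Monte-Carlo route takes over automatically for
  $n > 2000$.
* The melanoma-style benchmarks use synthetic stand-ins generated by
  `synth_expression()`; no real expression data ships with the package.
* Multi-level (non-binary) targets, dependent priors across
  $(c, p, q)$, and bolstered error estimators are out of scope.
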