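---
title: "Estimating odds ratios from sparse data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating odds ratios from sparse data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparselogit)
```

## The problem

Logistic regression odds ratios estimated by maximum likelihood (ML) are
biased — sometimes wildly — when few subjects occupy some combination of
outcome and covariate levels. This *sparse data bias* is a function of
the cell structure, not the total sample size: a cohort of thousands with
17 events and a rare exposure is sparse. In the limit, *separation* (a
covariate or linear combination perfectly predicting the outcome) makes
the ML estimate infinite. `sparselogit` implements eight estimation
strategies for the model

$$\mathrm{logit}\,\pi_i = \beta^T x_i, \qquad
  Y_i \sim \mathrm{Bernoulli}(\pi_i),$$

with $x_i = (1, x_{i1}, \dots, x_{ik})^T$, all sharing one formula-level
interface, plus a simulation harness for comparing them on replicated
sparse designs.

## The estimators

**ML (`"ML"`).** Newton–Raphson with step-halving on the weighted
log-likelihood $l(\beta)$; intervals by profile-likelihood inversion
(the set of values not rejected by the likelihood-ratio test), since the
Wald interval's normal approximation fails in sparse cells. Wald
intervals remain available for comparison (`ci = "wald"`).

**Firth (`"FIR"`).** Maximizes the Jeffreys-prior penalized likelihood
$l^*(\beta) = l(\beta) + \tfrac12 \log |I(\beta)|$, which removes the
leading term of the ML bias and keeps estimates finite under complete
separation. The modified score uses the hat-diagonal form
$U^*_j = \sum_i [w_i(y_i - \pi_i) + h_i(\tfrac12 - \pi_i)] x_{ij}$.
On a saturated 2×2 table this is exactly the add-½-to-every-cell
cross-product ratio, which the tests exploit as an oracle. Intervals
invert the penalized profile likelihood and are always finite. Note
that Firth's estimate is *not* uniformly shrunk toward zero: with a
small exposed group the half-cell corrections can push the odds ratio
above the ML value, occasionally far above it (these artifact estimates
matter when averaging over replications; see "Simulation accounting").

**Exact conditional (`"EX"`) and mid-P (`"MDP"`).** For a coefficient
$\beta_j$ with sufficient statistic $T_j = \sum_i y_i x_{ij}$, the
conditional likelihood given the observed values of all other sufficient
statistics (including the event total) is free of nuisance parameters.
The package enumerates the conditional support and counts by a forward
dynamic program over groups of identical covariate rows — a group of
size $s$ contributing $r$ events multiplies the count by
$\binom{s}{r}$ — so counts are exact without visiting the $2^n$ outcome
vectors. Counts are carried in log scale; for small problems they
exponentiate back to exact integers, which the test suite checks against
brute-force enumeration at $n \le 12$. The point estimate maximizes the
conditional likelihood (tilted-mean root); when the observed statistic
sits at the edge of its support the conditional MLE is infinite and the
*median-unbiased* estimate (tail probability ½) is substituted, with a
note. Interval bounds invert the exact tail probabilities
($\Pr(T_j \ge t_j \mid \beta_-) = \alpha/2$, and symmetrically above);
mid-P bounds give the observed point mass half weight, yielding a
strictly narrower interval. A bound at the support edge is reported as
an open (infinite) bound. The state space is capped (default
5×10⁷ states) and a capacity error names the cap rather than
approximating: there is deliberately no Monte Carlo fallback.

**Normal-prior and hyper-g Bayes (`"NP"`, `"HG"`).** Posterior medians
and equal-tailed credible intervals. `"NP"` uses independent
N(0, 100) priors. `"HG"` places $\beta \sim N(0, g\Sigma)$ with
$\Sigma = \mathrm{diag}(1/2)$ and the hyper-prior
$f(g) = \frac{a-2}{2} (1+g)^{-a/2}$, $a = 4$, under which the shrinkage
factor $g/(1+g)$ is uniform, the prior median of $g$ is 1, and
$F(g) = g/(1+g)$ in closed form (`hyper_g_cdf()`). The sampler is an
adaptive random-walk Metropolis chain on $\beta$ (proposal shape from
the penalized-likelihood covariance, which exists even under separation;
scale adapted during burn-in only), with a slice-sampling update of
$\log g$ between $\beta$ updates for the hyper-g prior. The algorithm is
a contract detail: any sampler passing the seeded-determinism and
prior-recovery properties in the test suite is equivalent. Defaults are
4 chains × 10,000 retained draws after 2,000 burn-in; the simulation
harness defaults to much shorter chains (one chain, 2,000 draws) because
replicate-level Monte Carlo noise averages out across replications.

*Prior scope.* Whether the prior covers the intercept was genuinely
open; both conventions are implemented
(`prior_spec(include_intercept = )`). The default includes the
intercept: on the bundled case-study table this convention yields the
posterior median the acceptance test asserts (a hyper-g odds ratio near
9.6), while restricting the prior to non-intercept coefficients shrinks
the same odds ratio by roughly an order of magnitude. Users analyzing data whose intercept is far from
zero should be aware the hyper-g scale $g$ then adapts mostly to the
intercept.

**Log-F augmentation (`"F1"`, `"F2"`, arbitrary `m`).** A log
F($m$, $m$) prior on a coefficient adds
$m\beta_j/2 - m\log\{1+\exp(\beta_j)\}$ to the log-likelihood — exactly
the likelihood contribution of $m$ pseudo-trials with $m/2$ events on
that coefficient's own column (intercept 0 elsewhere). The package
implements both representations and asserts their equality to 1e-10;
fitting runs the plain ML machinery on the pseudo-record-augmented data,
so the point estimate is the posterior mode and the intervals are
profile inversions of the augmented likelihood (this reproduces the
characteristic asymmetric intervals; a Wald-on-augmented-data option was
considered and rejected because it cannot). Priors go on all
non-intercept coefficients and never on the intercept. `m = 0` is
plain ML; `m` of 1 and 2 correspond to 95% prior odds-ratio intervals of
about (1/648, 648) and (1/39, 39) (`logf_prior_interval()`), narrowing
as `m` grows.

## Numerical choices

* Newton–Raphson: tolerance 1e-8 on the score sup-norm, at most 50
  iterations, step-halving (up to 25 halvings) guaranteeing ascent.
* For unpenalized ML only, a relative-gradient criterion
  $g^T H^{-1} g / (|l| + 10^{-6}) < 10^{-8}$ also stops the iteration,
  followed by one polishing step. This mirrors the convergence
  declaration of standard commercial optimizers on likelihood plateaus
  (quasi-separation), where the score never reaches the absolute
  tolerance because the optimum is at infinity. Penalized fits have
  interior optima and use the absolute criterion alone.
* Profile intervals: bisection (`uniroot`, tolerance 1e-6) on the signed
  deviance difference, with a geometrically widened bracket; an endpoint
  the deviance never reaches within 80 coefficient units is reported as
  an open bound.
* Exact-method roots (tilted mean, tail inversions): monotone
  root-finding with geometric bracket expansion, tolerance 1e-8.
* The Jeffreys determinant is computed from a Cholesky factorization;
  indefiniteness raises a clear error rather than a silent `NaN`.
* Degenerate inputs: an all-event or all-non-event outcome is flagged
  as non-convergence, not an exception; a structurally singular design
  (constant or collinear column) is an error naming the column; a
  conditional distribution whose constraints force a unique outcome
  vector reports "inestimable".

## The scenario generator

`scenario_config()` defines one cell of a six-scenario simulation design
for a rare exposure $x_1$ with prevalence parameter
$\pi_{x1} \in \{0.05, 0.1, 0.2\}$ and true odds ratio in
$\{1, 4, 16\}$:

1. $x_1$ alone;
2. plus independent $x_2 \sim \mathrm{Bern}(0.5)$;
3. correlated pair: $x_1 \mid x_2 \sim
   \mathrm{Bern}(\tfrac{x_2+1}{2}\pi_{x1})$, so the exposure is rarer
   when $x_2 = 0$ and the marginal prevalence is $0.75\,\pi_{x1}$;
4. the correlated pair plus $x_3 \sim \mathrm{Bern}(0.3)$,
   $x_4 \sim \mathrm{Bern}(0.1)$;
5. eight covariates: the correlated pair, five further Bernoulli
   covariates (0.3, 0.1, 0.5, 0.3, 0.1) and a trinomial score
   (0.8, 0.1, 0.1) coded 0/1/2;
6. a case-study-like cohort: eight covariates with fixed coefficient
   vector ($\beta_0 = -6.40$, $\beta_2 \dots \beta_8$ = 0.57, 0.96,
   2.09, 1.24, 1.52, 0.99, −0.64) and multinomial scores entered as
   quantitative variables. Its sample size defaults to 3,000 (the
   nearest design value to the case-study cohort) and is configurable,
   since the design grid for this scenario is not fully crossed.

Non-exposure odds ratios default to 2 (scenarios 2–5). For scenarios
1–5 the intercept is calibrated so the *expected* number of events is
exactly `n_e`: the event probability is averaged over the fully
enumerated covariate support (384 combinations at most, honoring the
scenario-3 dependence) and solved to 1e-10 by bisection — a Monte Carlo
oracle over 10⁶ draws confirms the calibration in the tests. Replicates
are generated from per-replicate substream seeds derived from one master
seed, so any single replicate is reproducible in isolation; degenerate
replicates (no events, constant covariate column) are passed through on
purpose — classifying them is the estimators' and the filter's job.

The generator emulates categorical sparse-data structure only: no
continuous covariates, no covariate measurement error, no real-world
dependence beyond the scenario-3 pair. Passing tests therefore
demonstrate correct behaviour under the stated laws, not performance on
any particular real cohort.

## Simulation accounting

`run_scenario()` fits the requested methods to each replicate and
`summarize_metrics()` reports, per method: the average odds ratio
$\exp(\mathrm{mean}\ \widehat{\log \mathrm{OR}})$, the bias of the log
odds ratio, the coverage of the 95% intervals (an open bound covers on
its side), the convergence rate, and the effective replicate count.

A fit attempt counts as a *convergence success* when the optimizer
reports convergence and the exposure odds ratio lies in the
estimability window $[0.001, 999]$ (`convergence_filter()`). Headline
tables are restricted, for every method, to exactly the replicates
where the ML fit succeeded — the convention that keeps methods
comparable on sparse cells — with unrestricted summaries available via
`restrict_to_ml_success = FALSE`.

A known limitation: on extremely sparse cells the restricted averages
are sensitive to how degenerate replicates (e.g. zero exposed events
with additional quasi-separated covariates) are classified. Under the
relative-gradient rule such replicates can stall at a finite,
essentially arbitrary exposure estimate inside the window and enter the
restricted set, where Firth's artifact estimates on them are large and
positive; a stricter separation rule excludes them and shifts every
method's average upward. Both behaviours are defensible; the package
implements the relative-gradient rule and exposes the raw per-replicate
records (`$replicates`) so users can apply their own classification.

`required_replications(sigma2, rho, ratio)` gives the smallest
replication count at which the 95% interval for a between-method
difference in mean log odds ratio has half-width below `log(ratio)`
under correlation `rho` — the design calculation behind a
1,000-replicate default.

## Problem sizes in the tests

The test suite and acceptance script use: the two bundled 2×2 tables
for all deterministic reproductions; 4 × 10,000 MCMC draws for the
case-study posteriors; 1,000 replicates for the sparse scenario-4 cell
(ML, Firth and log-F only — exact and full-length MCMC per replicate
are out of proportion there); and 200 replicates at $n = 10^5$ with
2,000 expected events for the large-sample recovery property, where all
eight methods must land within 5% of a true odds ratio of 4. Exhaustive
enumeration oracles run at $n \le 12$.
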