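---
title: "Pooling randomized and non-randomized evidence: models and methods"
author: "bfmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling randomized and non-randomized evidence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfmeta)
```

# The problem

Meta-analyses of binary outcomes frequently combine randomized controlled
trials (RCT) with non-randomized studies (NRS).  The NRS add sample size
and apparent precision, but their confounding can bias the pooled effect,
and a frequentist random-effects analysis pools them *naively*: every
study is exchangeable regardless of design.  `bfmeta` implements a
principled alternative — a Bayesian hierarchical model whose marginal
likelihoods let the data themselves arbitrate, through Bayes factors,
between one common effect for both designs and separate effects per
design — alongside the standard frequentist estimators, so the two
paradigms can be compared dataset by dataset.

# The normal-normal hierarchical model

All effects live on the natural-log scale (log-OR or log-RR); the
normality assumptions below are about log effects, and exponentiation to
the ratio scale happens only in the print/serialization methods.  For
studies $i = 1, \dots, k$ with observed log effects $y_i$ and standard
errors $\sigma_i$ (treated as known, the usual meta-analytic convention):

$$y_i \mid \theta_i \sim N(\theta_i, \sigma_i^2), \qquad
  \theta_i \mid \mu, \tau \sim N(\mu, \tau^2),$$

with priors $\mu \sim N(m_0, s_0^2)$ and $\tau$ half-normal or half-Cauchy
with scale $s$.

## Priors and their defaults

* **Effect prior** $N(0, 2^2)$ (log scale).  With an sd of 2 the central
  95% prior interval on the ratio scale spans roughly $1/50$ to $50$ —
  vague for any realistic intervention effect, but proper, which marginal
  likelihoods require.  Both parameters are user-settable via
  `effect_prior()`.
* **Heterogeneity prior**, `het_prior()`: half-normal or half-Cauchy with
  scale 0.5 (dimensionless, same scale as the log effect).  If $\tau$
  between 0.1 and 0.5 is read as small-to-moderate heterogeneity, these
  scales are weakly informative: the mass below $\tau = 0.4$ is
  `r round(100 * phet(het_prior("half-cauchy", 0.5), 0.4))`% for the
  half-Cauchy and
  `r round(100 * phet(het_prior("half-normal", 0.5), 0.4))`% for the
  half-normal (both computable in closed form, and both asserted in the
  test suite).  The half-Cauchy's heavier tail concedes more mass to large
  heterogeneity; running both families (`run_both_priors()`) is the
  intended sensitivity analysis, and in well-behaved data the two give
  nearly identical point estimates.

## Computation: quadrature, not MCMC

Conditional on $\tau$ the model is conjugate: $\mu \mid \tau, y$ is normal
with precision $\sum_i (\sigma_i^2+\tau^2)^{-1} + s_0^{-2}$, and the
integrated-over-$\mu$ likelihood $p(y \mid \tau)$ is a multivariate normal
with covariance $\mathrm{diag}(\sigma_i^2+\tau^2) + s_0^2 J$.  Its
diagonal-plus-rank-one structure gives the determinant and quadratic form
without matrix inversion, so each evaluation is $O(k)$ and stable for
$k$ up to the dozens seen in practice.  The only numerical integral is
one-dimensional:

$$p(y \mid M) = \int_0^\infty p(y \mid \tau)\, p(\tau)\, d\tau.$$

Numerical choices, all in `nnhm_control()`:

* substitution $u = \tau/(\tau+s)$ maps $[0, \infty)$ to $[0, 1)$ with the
  prior scale $s$ as the natural pivot (half the $u$ grid falls below
  $\tau = s$); the integrand vanishes at both ends;
* adaptive quadrature (`stats::integrate`) at relative tolerance
  $10^{-10}$, with the integrand exponentiated around its maximum so that
  only ratios are formed — likelihood products for $k$ up to 60 underflow
  otherwise, hence everything is carried in log space and combined by
  log-sum-exp;
* a fixed grid of 401 $u$ midpoints stores the discretized posterior
  $p(\tau \mid y)$; the marginal posterior of $\mu$ is then the exact
  normal mixture $\sum_j w_j\, N(m(\tau_j), s^2(\tau_j))$ over that grid;
* if the quadrature reports an estimated relative error above $10^{-6}$,
  the fit is flagged (`diagnostics$converged = FALSE`) and a warning
  raised, rather than silently accepted — the analogue of a reference
  analysis reporting an estimate as incomputable;
* $k = 1$ subgroups are fitted, not refused: the prior dominates, which is
  exactly the behaviour model comparison needs when a design is
  represented by a single study.

The test suite validates the marginal likelihood against brute-force
Monte-Carlo integration over $(\mu, \tau)$ drawn from the priors (up to
$10^6$ draws, agreement within 3 Monte-Carlo standard errors on 3-study
data) and the rank-one likelihood against a dense-matrix multivariate
normal density.

## Credible intervals

Reported intervals are the *shortest* intervals containing 95% posterior
mass, computed by one-dimensional optimization of
$Q(a + 0.95) - Q(a)$ over the lower tail mass $a$, with $Q$ the mixture
quantile function (inverted by root-finding at tolerance $10^{-10}$).  For
the unimodal posteriors that arise here this equals the highest posterior
density interval; genuinely multimodal mixtures (possible under model
averaging when designs conflict strongly) get the shortest *single*
interval plus a multimodality flag, since the true HPD region would be a
union of intervals.  The point estimate reported is the posterior median,
with the mean also stored.

# Pooled versus separate: Bayes factors

Two data models are compared with identical priors:

* **pooled** $M_1$: one NNHM over all $k$ studies;
* **separate** $M_0$: independent NNHMs for the RCT and NRS subgroups, so
  $p(y \mid M_0) = p(y_{\mathrm{RCT}}) \cdot p(y_{\mathrm{NRS}})$.

$\mathrm{BF}_{10} = p(y \mid M_1)/p(y \mid M_0)$; the package reports both
it and its exact reciprocal.  The decision rule accepts pooling for
$\mathrm{BF} > 3$ and separation for $\mathrm{BF} < 1/3$; the band is open
at both ends, so an exact boundary value is classified indeterminate —
with printed 3-decimal BFs this matters, and the strict reading matches
the rule as usually stated.  Posterior model probabilities use prior model
probabilities of 0.5 (configurable), giving
$p(M_1 \mid y) = \mathrm{BF}/(\mathrm{BF}+1)$; these are *within-model*
priors' complements — the probability that the model as a whole holds —
and are independent of the parameter priors.

## The model-averaged posterior

The reported posterior is the mixture of the conditional posteriors
weighted by the posterior model probabilities.  Under the separate model
there is no single pooled effect, so a choice is unavoidable: which
posterior represents "the" effect in that component?  The package defaults
to the RCT-subgroup posterior, on the view that the randomized estimate is
the inferential target and the NRS are co-data whose influence should
vanish when the designs conflict; that yields adaptive information
sharing — strong borrowing from NRS when the designs agree (the pooled
component dominates), fading to an RCT-only analysis when they disagree.
Because this was a genuinely open design choice, `separate_target` exposes
the alternatives (`"nrs"`, or an equal `"mixture"` of both subgroup
posteriors) and the choice is recorded in the returned object.

# Frequentist estimators

Three estimators are implemented exactly, each checked against an
independent formula-by-formula oracle to $10^{-10}$ and (for DSL and HKSJ)
against `metafor`:

* **DSL**: moment estimator
  $\hat\tau^2 = \max\{0, (Q - (k-1))/(\sum w_i - \sum w_i^2/\sum w_i)\}$,
  random-effects weights, $z$-based CI.
* **HKSJ**: same point estimate; the CI variance is the weighted dispersion
  $\sum w_i^*(y_i-\hat\mu)^2 / ((k-1)\sum w_i^*)$ with $t_{k-1}$ quantiles.
  The plain (unmodified) correction is used — no small-sample truncation —
  matching the method as originally proposed.  $k = 2$ is computable but
  flagged `unstable`: the $t_1$ quantile of 12.7 makes the interval valid
  yet enormous, which is presumably why reference analyses sometimes
  report it as incomputable.
* **IVhet**: fixed-effect (inverse-variance) weights for the point
  estimate with variance $\sum \hat w_i^2(\sigma_i^2 + \hat\tau^2)$,
  $z$-based CI.  Its $\hat\tau^2$ is the DSL moment estimate, the
  conventional pairing; at $\hat\tau^2 = 0$ the fit collapses exactly onto
  the fixed-effect analysis.

Design resolutions worth stating: CIs are $z$-based except HKSJ
($t_{k-1}$), matching the conventional implementations being compared;
$I^2 = \max\{0, (Q-(k-1))/Q\}$ with the $Q = 0$ case resolved to 0;
"significance" on both sides of the package means interval-excludes-null
(OR/RR = 1), never a p-value.

# Effect sizes and data handling

`log_odds_ratio()` and `log_risk_ratio()` use the standard large-sample
formulas.  Zero cells get a continuity correction of 0.5 added to **all
four** cells of the affected study — never selectively — the convention of
the RevMan/metan programs; for tables with no zero cell the correction
parameter provably has no effect.  How the original published analyses
handled zero cells is generally unstated, so the 0.5 convention is an
assumption, kept configurable.  Tables carrying no information about the
ratio (zero events in both arms; all events in both arms) are dropped from
a dataset with a warning and counted, mirroring meta-analytic practice,
rather than failing the whole dataset.  The CSV schema
(`read_meta_csv()`/`write_meta_csv()`) round-trips all fields at full
double precision, accepts mixed rows (precomputed effects and 2x2 counts),
and raises parse errors that name the offending row and column.

# The synthetic-data generator

`synth_config()`/`generate_cohort()` emulate the *statistical structure*
of published RCT+NRS cohorts in critical care: per-meta study counts with
median 9 clamped to 2–60 (rounded lognormal, sdlog 0.65), RCT share about
one third (binomial, clamped so both designs are always present), control
risks uniform on 0.05–0.40, arm sizes uniform on 25–400, true log effect
$\log 0.7$ (a moderate protective effect), heterogeneity SD 0.25, and an
optional additive NRS bias `delta_nrs` on the log scale.  Binomial mode
maps study effects onto treatment probabilities through the metric's link
(logit for OR, log for RR) and draws real 2x2 tables; normal mode bypasses
the binomial layer for speed and exactness.  A master seed spawns
per-dataset child seeds by fixed arithmetic, so any dataset is
reproducible in isolation; the global RNG stream is left untouched.

What it deliberately does **not** emulate: confounding mechanisms inside
NRS (bias enters only as a mean shift), publication/selection bias,
correlated arms, non-binary outcomes, and metric mixtures within a cohort.
Passing tests on these cohorts therefore demonstrate the estimators'
internal correctness and the directional behaviour of the methods (e.g.
Bayesian intervals excluding the null less often than DSL under a null
effect), not performance under realistic confounding.

# Problem sizes and test design

The suite favours small, deep checks: 3–5-study toys against hand
computations and dense oracles; 100 seeded replicates per scenario for the
BF decision directions (concordant data should pool, data with an NRS
shift of 2 should separate); 200 replicates for the null-cohort
conservatism comparison; 20 replicates of $k = 50$ for posterior
recovery of $(\mu, \tau)$ within 3 Monte-Carlo standard errors; and a
$10^6$-draw Monte-Carlo check of the marginal likelihood.  These sizes
give stable verdicts at the stated tolerances while keeping the full suite
fast.

# Known limitations

* Study standard errors are treated as known; very sparse tables make
  that approximation poor regardless of continuity convention.
* The separate-model "reported effect" is a modelling choice (see above);
  conclusions about the averaged *point estimate* under strong conflict
  depend on it, though the Bayes factor itself does not.
* Bayes factors are sensitive to the within-model priors, in particular
  the effect-prior sd: vaguer priors penalize the more complex separate
  model more.  The default $N(0,2)$ should be varied in sensitivity
  analyses when BFs sit near the decision boundaries.
* The quadrature assumes the integrand over $\tau$ is smooth and
  effectively single-peaked, which holds for the NNHM; exotic priors
  supplied by users are not validated beyond the convergence diagnostic.
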