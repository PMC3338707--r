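---
title: "Simulating power for cluster-randomized and crossover designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating power for cluster-randomized and crossover designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crxopower)
```

## The problem

Cluster-randomized trials (CRTs) randomize intact groups — hospital units,
clinics, health plans — rather than individuals, and a cluster-randomized
crossover (CRXO) additionally has every cluster receive both conditions in
successive periods, so that inference rests on within-cluster contrasts.
Closed-form power formulas cover only fragments of this design space, and no
single formula spans both CRT and CRXO with continuous, binary and count
outcomes. `crxopower` instead estimates power empirically: simulate many
hypothetical trials under a specified alternative, analyze each one exactly as
the real trial would be analyzed, and report the fraction of replicates in
which the null hypothesis of no treatment effect is rejected.

## Data-generating model

All three outcome families share the cluster-level linear predictor

$$\eta_{ijk} = \pi_j + \theta X_{jk} + b_k,$$

for individual $i$ in cluster $k = 1,\dots,K$ during period
$j = 1,\dots,J$, where $X_{jk} \in \{0,1\}$ indicates treatment,
$\theta$ is the treatment effect on the link scale, and
$b_k \sim N(0, \sigma_b^2)$ are random cluster intercepts that induce the
within-cluster correlation. The period effects $\pi_j$ are drawn from
$N(\texttt{period\_effect}, \texttt{period\_var})$; with
`period_var = 0` they are fixed, and a vector-valued `period_effect` expresses
a secular trend (e.g. a baseline event rate that declines from period 1 to
period 2). No individual-level covariates enter the model — powering on
cluster-level quantities is standard design-stage practice, and crossover
designs balance individual covariates across arms by construction.

The families are:

* **Gaussian** — $Y = \eta + e$, $e \sim N(0, \sigma_w^2)$. The intraclass
  correlation is $\mathrm{ICC} = \sigma_b^2 / (\sigma_b^2 + \sigma_w^2)$; any
  two of $\{\mathrm{ICC}, \sigma_b^2, \sigma_w^2\}$ determine the third
  (`complete_variances()`).
* **Binomial** — $Y \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}\eta)$. All
  fixed effects and $\sigma_b^2$ live on the log-odds scale. (A control-arm
  probability is converted by the user, e.g. a 50% rate is
  `period_effect = 0`.)
* **Poisson** — $Y \sim \mathrm{Poisson}(T_{ijk} e^{\eta})$ with at-risk time
  $T_{ijk}$, so $\theta$ is a log rate ratio. At-risk times are either a fixed
  constant per participant or negative-binomial with mean $\mu_T$ and size $s$
  (variance $\mu_T + \mu_T^2/s$), letting the user tune exposure variability.

A design decision on the binary family: the period effects of the logistic
model are interpreted on the log-odds scale (the natural parameter of the
model), even though applied descriptions of adherence or prevalence are
usually on the probability scale.

Individual outcomes are generated and then reduced to cluster-period
summaries by `aggregate()`. For counts this is distributionally identical to
a single Poisson draw with the summed exposure, but the individual-level
representation keeps the door open for individual-level extensions.
Negative-binomial at-risk draws of zero are replaced by 1 — the smallest
positive support value — because a participant with no at-risk time
contributes no information and would break the log-exposure offset; the
number of replacements is recorded on the simulated trial.

## Analysis models and the rejection rule

Power is a property of design *and* analysis, so the analysis model is
explicit and swappable:

* `fixed.effect.cluster.level` (crossover designs, $J \ge 2$): a cluster-period
  level GLM with one fixed intercept per cluster, the treatment indicator,
  and — in the `.period` variant — $J-1$ period indicators. For counts this is
  a Poisson regression with a log-exposure offset; for binary outcomes a
  logistic model on (successes, denominator); for continuous outcomes a
  weighted linear model on cluster-period means. Cluster intercepts absorb all
  between-cluster variation, which is precisely the CRXO inferential logic.
* `single_period` ($J = 1$): for binary outcomes a pooled fixed-effects
  logistic regression of outcome on treatment — kept deliberately simple, and
  only calibrated when the between-cluster variance is negligible, since
  pooling ignores clustering. For continuous and count outcomes the analysis
  is a between-cluster comparison of cluster summaries (size-weighted cluster
  means; exposure-weighted cluster log incidence rates) with a Student-t
  interval on $K - 2$ degrees of freedom, which respects clustering.
* `glmm_random_intercept`: a random-intercept GLMM fit of the generating
  model (via lme4), provided as an optional alternative.
* Any user function `(trial, alpha) -> effect_estimate` can be registered
  with `register_estimator()` and used everywhere a name is accepted.

The null is rejected when the two-sided $(1-\alpha)$ confidence interval for
$\theta$ excludes zero. Intervals are Wald on the link scale, with normal
quantiles where the dispersion is fixed (Poisson, binomial) and Student-t
quantiles where it is estimated (the Gaussian fits): with ten clusters the
Gaussian fit has single-digit residual degrees of freedom, and a normal
reference there would inflate the type-I error to roughly 0.08. A confidence
bound exactly at zero counts as covering zero (no rejection) — a
measure-zero convention fixed for determinism.

Degenerate data never raise: estimators return `converged = FALSE` (for
example when a cluster has zero events in every period, making its intercept
diverge to $-\infty$; a single zero cell is fine and is fit normally). Failed
replicates are excluded from the power denominator — a failed fit yields no
test decision, and counting failures as non-rejections would bias power
downward — but the failure rate is always reported and a warning is raised
when it exceeds 1%.

## The power engine

`estimate_power()` runs the simulate–aggregate–fit–decide loop. Each
replicate draws a fresh randomization of the allocation (clusters permuted
among the two crossover sequences, or among arms for $J=1$) and runs on its
own RNG substream: the master seed seeds a stream from which one substream
seed per replicate is drawn, so results are bit-reproducible and independent
of execution order. Empirical power gets a 95% Wilson score interval — with
1000 replicates the Monte-Carlo standard error near 50% power is about
0.016, and near 90% about 0.009.

`power_sweep()` re-estimates power along a grid of one parameter
(`n_clusters`, `cluster_size`, `effect_size`, `btw_clust_var`, or `icc` for
the Gaussian family), each grid point on an independent substream; per-point
failures are recorded without aborting the sweep. For cluster-count and
cluster-size sweeps the summary includes an isotonic
(pool-adjacent-violators) smoothing of the power curve: true power is
nondecreasing in those parameters, and isotonic regression is a deterministic,
assumption-light way to remove Monte-Carlo wiggles before thresholding.
`min_clusters_for_power()` returns the smallest grid value whose smoothed
power reaches the target, and flags — never extrapolates past — an exhausted
grid. Because the smoother acts on a discrete grid of noisy points, the
returned count is honest to about one grid step.

## Worked example

A two-period crossover in 10 intensive-care units, 210 participants per
cluster-period with 10 at-risk days each, baseline infection rate 4 per 1000
at-risk days, a 25% rate reduction under treatment, and between-cluster
variance 0.5 on the log-rate scale — chosen (to the nearest 0.1, via
`calibrate_btw_cluster_var(0.004, 0.010)`) so that 9 in 10 clusters have
baseline rates below 10 per 1000 at-risk days:

```{r example-a, eval = FALSE}
design <- make_design(n_clusters = 10, n_periods = 2, cluster_size = 210)
params <- poisson_params(period_effect = log(0.004),
                         effect_size = log(0.75),
                         btw_clust_var = 0.5, at_risk = 10)
estimate_power(design, params, "fixed.effect.cluster.level",
               n_sim = 1000, master_seed = 17)
```

This prints an empirical power just above 50%: the design as stated is
underpowered, and sweeping `n_clusters` shows roughly 22 clusters are needed
for 80% power. Adding a declining baseline (4 then 3 infections per 1000
at-risk days, `period_effect = log(c(0.004, 0.003))`) and adjusting the
analysis for period (`"fixed.effect.cluster.level.period"`) costs power at
every cluster count — about two extra clusters at the 80% threshold.

## Numerical and design choices

* **Allocation.** Balanced crossover allocation requires an even cluster
  count; an odd count is rejected rather than silently unbalanced. For
  $J > 2$ the two alternating sequences are tiled across periods — a
  convention of this package, since multi-period sequence construction is not
  otherwise standardized.
* **Gaussian variance completion** is exact (closed form), validated to
  1e-12 in a round-trip property test; over-specified, inconsistent triples
  are rejected.
* **Seeds.** Every function that consumes randomness takes a `master_seed`;
  derived substream seeds stay below $2^{31}$.
* **Configs.** YAML/JSON run configurations use snake_case parameter names
  with the traditional dotted spellings accepted as aliases; keys are checked
  against the outcome family (`icc`/`indiv_var` are Gaussian-only,
  `at_risk_params` count-only) and unknown keys are errors. All defaulted
  fields are logged, and output files embed the resolved configuration and
  master seed so any result can be reproduced bit-for-bit.

## What the simulations do and do not show

The generator emulates cluster-level heterogeneity (random intercepts),
secular trends (fixed or random period effects) and exposure-time
variability. It does not emulate individual-level risk factors, carryover
between crossover periods (washout is assumed effective), overdispersed
counts beyond what exposure variation induces, informative cluster sizes, or
missingness. Power estimates carry those caveats to real trials: a passing
calibration test here says the estimator is calibrated *under this model*,
not under arbitrary misspecification — the pooled single-period logistic
model is the clearest example, being anticonservative whenever
between-cluster variance is material.

Test-suite problem sizes are the package's own choices: power checks run
1000 replicates (Monte-Carlo SE about 0.016 at 50% power), calibration
checks 2000 (3 Monte-Carlo SEs around $\alpha = 0.05$ span about $\pm$0.015),
moment checks use $10^4$–$10^5$ draws with 4-standard-error bands, and the
minimum-cluster searches use even grids of 10–30 and 10–32 clusters at 1000
replicates per point.
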