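---
title: "Comparing causal forests and IPTW under cluster-level confounding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing causal forests and IPTW under cluster-level confounding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In surgical and medical-device epidemiology, treatment allocation is driven
not only by patient characteristics but also by the hospital or surgeon:
expertise, policies, volume.  These cluster-level covariates confound
observational treatment comparisons in a way that is harder to handle than
ordinary patient-level confounding, because a single cluster draw is shared
by hundreds of patients.  `clustercf` provides the machinery to study, by
Monte Carlo simulation, how two families of estimators behave under this
kind of confounding:

* **PS--IPTW** — a logistic propensity-score model over patient- and
  cluster-level confounders, stabilized inverse-probability-of-treatment
  weights, and a weighted random-intercept logistic outcome model whose
  treatment coefficient is the estimate (log odds ratio scale);
* **Causal forests** — honest double-sample causal trees on orthogonalized
  data with doubly robust (AIPW) averaging, in three variants: internal
  forest propensities (`CF`), cluster-level subsampling
  (`CF-clusterID`), and externally supplied logistic propensities
  (`CF-PS`).

## The parametric generator

Each cohort has a fixed total of 10 000 patients in `m` clusters whose
sizes are Poisson with mean `n` (the five canonical structures are
10×1000, 50×200, 100×100, 200×50, 500×20; zero sizes are bumped to one
patient and single patients are randomly added or removed until the total
is exact, so both the Poisson shape and the fixed total hold).  Two
cluster-level confounders are shared by all patients of a cluster:
`z1 ~ N(0,1)` and `z2 ~ Bernoulli(0.5)`.  Patient-level covariates are
three Bernoulli confounders (`x1..x3`, probabilities 0.4/0.45/0.5), two
standard-normal confounders (`x4`, `x5`), an outcome-only risk factor
`x6` and a treatment-only instrument `x7` (both Bernoulli 0.5).

Treatment and outcome are logistic:

* `logit P(T=1) = alpha0 + (0.35, 0.4, 0.45, 0.55, 0) · x1..x5 + 0.5 x7 +
  gamma_z (z1 + z2) + 0.4055 z1 x1`
* `logit P(Y=1) = lambda0 + 0.4055 T + (0.35, 0.4, 0.45, 0.55, 0) · x1..x5 +
  0.5 x6 + 0.4055 (z1 + z2)`

`gamma_z` is the design knob: 0.01, 0.2231, 0.4055, 0.9163 (odds ratios
1.01–2.5) crossed with the five structures give the canonical 20-scenario
grid (`make_scenario_grid()`).  The true conditional treatment effect is a
log odds ratio of 0.4055 (OR 1.5) everywhere.

Three generator choices deserve comment:

* **Intercepts.**  No intercept values are part of the design; the slopes
  are what matters.  We calibrate `alpha0` and `lambda0` by monotone
  root-finding on a 200 000-draw Monte Carlo sample of the intercept-free
  linear predictor so that treatment and outcome prevalences hit 50% (both
  targets are configurable).  The outcome calibration includes the
  `0.4055 T` term with `T` drawn from the calibrated treatment model.
* **The fifth confounder.**  Only four effect values are attached to the
  five patient-level confounders, so `x5` carries coefficient 0 on both
  models by default (a pure noise covariate); the vectors are exposed in
  the configuration for sensitivity work.
* **The interaction.**  The cross-level term `z1·x1` (log-odds 0.4055)
  enters the treatment model only, using the raw `z1`.  Because the
  default propensity model is main-effects-only, this term is exactly the
  misspecification whose consequences grow with `gamma_z`.

A degenerate draw (single treatment arm or constant outcome) triggers one
reseeded redraw and then a hard error; at the canonical scenario sizes
this is never exercised.

## The plasmode generator

The plasmode arm resamples covariates of a base cohort with replacement
(whole patient rows, so the joint covariate distribution and the
hospital nesting are preserved) and then generates exposure and outcome
from the same logistic machinery with a known true effect.  The package
ships a *synthetic* base cohort shaped like a US hospital pancreatectomy
cohort — 9981 patients in 341 hospitals, about 30 patients per hospital;
age truncated-normal (65, 12) floored at 18; a Charlson-style comorbidity
count rank-correlated about 0.3 with age; hospital teaching status, size
class and yearly procedure volume mutually positively associated — because
the real cohort it emulates sits in a proprietary database.  Any CSV with
the same schema can be substituted (`read_base_cohort()`), so the
procedure itself is testable without data access.  Continuous covariates
are standardized against the base cohort before receiving coefficients,
which keeps the odds-ratio grid comparable to the parametric arm; the
patient-level coefficient defaults (0.35, 0.4, 0.45) are declared package
defaults, not estimates from any real data.  Hospital-level covariates
receive `gamma_z` on the treatment model — the same grid as the
parametric arm — and 0.4055 each on the outcome model.

What the synthetic base does *not* emulate: the real cohort's full
covariate set, its empirical correlation structure beyond the
age–comorbidity and volume–teaching associations built in, and any
non-linear relationships.  Conclusions about estimator behaviour on the
real database are therefore out of reach of these tests; what the tests
do show is that the plasmode procedure, the estimators and the metrics
compose correctly on realistically shaped clustered data.

## The causal forest

The forest is built in compiled code from first principles:

1. **Orthogonalization.**  Two honest subsampled regression forests (the
   same tree machinery with variance-reduction splitting) produce
   out-of-bag predictions of the propensity `e(x)` and the marginal
   outcome `y(x)`; residuals `Y - y(x)` and `T - e(x)` are the working
   data.  Out-of-bag prediction gives the cross-fitting that doubly
   robust estimation needs.  Propensities are clipped to `[0.02, 0.98]`
   (clip counts are kept on the fitted object); external propensities,
   when supplied, pass through the same clip.
2. **Honest double-sample trees.**  Each of the 200 trees draws half the
   rows without replacement (whole clusters when cluster ids are
   supplied), splits the subsample into a split half and an estimate
   half, and grows by exhaustive axis-aligned search maximizing
   `S_L^2/A_L + S_R^2/A_R` where `S = Σ (T-e)(Y-y)` and `A = Σ (T-e)^2`
   within a child — the between-child heterogeneity of the
   residual-on-residual effect estimate `S/A`.  Children must keep at
   least 5 rows and both treatment arms; splits stop when no strict gain
   remains.  Equal-gain ties break to the lowest covariate index, then
   the lowest threshold, so fits are bit-reproducible under a seed.
3. **Honest leaf effects.**  Leaf effects are `S/A` over the *estimate*
   half only.  A leaf whose estimate half lacks a treatment arm (or has
   no residual mass) inherits the effect of its nearest valid ancestor.
4. **AIPW averaging.**  With out-of-bag CATE predictions `tau(x)` and the
   nuisances, the potential-outcome means are estimated by augmented
   inverse-probability weighting and reported either as a risk difference
   or as a marginal log odds ratio `logit(mu1) - logit(mu0)` with a
   delta-method standard error from the influence scores; with cluster
   ids the scores are summed within clusters first (cluster-robust).

Choices made where the design was genuinely open:

* **Reporting scale.**  Forests natively estimate risk differences, while
  IPTW and the design truth live on the odds-ratio scale.  The default
  puts all four estimators on a log odds ratio scale — the forests
  report the marginal log odds ratio from their AIPW potential-outcome
  means — and scores everything against the design's conditional value
  0.4055.  This folds the noncollapsibility gap (~13% under the default
  outcome model) into the forests' measured bias; be aware that in
  these designs the forests' residual confounding (from the cross-level
  interaction and nuisance smoothing) partly *cancels* that gap, so
  their measured bias can sit well below the gap itself.  The
  alternative `scale = "risk_difference"` reports the forests on their
  native scale and compares them against the Monte Carlo
  risk-difference truth from `true_effect()` (about 0.088); on that
  scale the cancellation is absent and the forests' residual
  confounding is visible directly.  Both conventions are defensible;
  conclusions about estimator orderings can differ between them, which
  is itself a finding worth knowing about when reading any single
  simulation study.
* **The "50 forests" tuning record.**  The tree-group size for grouped
  variance bookkeeping is stored as `n_tree_groups = 50`; it has no
  effect on point estimates and is kept only so the configuration record
  is complete.
* **CF–clusterID nuisances.**  Cluster-level subsampling applies to
  *every* internal forest of the variant — the causal trees (whole
  clusters per subsample, honesty halves split at the cluster level,
  cluster-summed influence scores) *and* the two nuisance forests.  This
  matters: with cluster-subsampled nuisances, a row's out-of-bag
  propensity comes only from trees that excluded its entire cluster, so
  with few large clusters the cluster-level confounders are poorly
  learned and the orthogonalization degrades — which is precisely the
  regime where this variant falls apart.  Restricting the cluster
  subsampling to the causal trees alone (an earlier design) leaves the
  globally fitted residuals carrying all the confounding adjustment and
  erases that phenomenon.

## IPTW implementation

The propensity model is a main-effects logistic regression on the seven
confounders (`x1..x5`, `z1`, `z2`); the instrument and the risk factor
are excluded, and the cross-level interaction is excluded by default (a
flag adds it).  Fitted probabilities are clipped to `[0.001, 0.999]`.
Stabilized weights `p̄/e(x)` and `(1-p̄)/(1-e(x))` enter a logistic
outcome model `Y ~ T + (1 | cluster)` as per-observation likelihood
weights, fitted by Laplace approximation (bobyqa, with a Nelder–Mead
fallback; the optimizer is recorded in the result row).  The Wald
standard error of the treatment coefficient drives the 95% interval at
`estimate ± 1.96 se`; no cluster-robust sandwich is applied.  A
non-converged fit is flagged and excluded pairwise by the metrics layer,
with exclusion counts reported.

## Metrics

Per scenario and estimator, over `R` usable replications with truth `θ`:
relative bias `100 |mean(est) - θ| / |θ|` (a per-replication-absolute
mode exists behind a flag, since "average absolute relative bias" admits
both readings), empirical SE `sd(est)`, and 95% coverage, each with its
Monte Carlo standard error (`emp_se/√R · 100/|θ|`, `emp_se/√(2(R-1))`,
`√(cov(1-cov)/R)`).  The default truth is the conditional log odds
ratio 0.4055 for every estimator; in risk-difference mode the forests
are compared against the Monte Carlo risk-difference truth instead
(relative bias is scale-invariant, which keeps such mixed-scale tables
meaningful).  `summarize_scenario()` accepts any per-scenario (or
per-scenario-per-estimator) truth table.  Structure-averaged summaries
are unweighted means of per-structure values.

## Problem sizes and reproducibility

The canonical study sizes (n = 10 000; 100 or 1000 replications; 200
trees) make a full grid a long single-CPU computation.  The package's own
summaries — the acceptance script and the scenario-level tests — keep the
full cohort size of 10 000, because the forest's finite-sample bias
depends on n, and reduce the replication counts instead (14 paired
replications per structure for structure-averaged comparisons, 26 for
single-scenario ones in the script; smaller in the test suite), which
widens Monte Carlo error without moving what is being measured.  Every
replication seed derives from `(root seed, scenario index, replication)`
through a documented integer scheme (`derive_seed()`), so any cell is
regenerable in isolation and parallel execution is bit-identical to
serial.

## Known limitations

* The forest is this package's own implementation of honest
  double-sample causal trees; it follows the published algorithm but is
  not tuned to match any other software tree-for-tree, and replication
  counts at desk scale leave a few percentage points of Monte Carlo noise
  on bias summaries in the few-large-clusters structures.
* The weighted random-intercept model treats stabilized weights as
  likelihood weights; other weighting conventions (e.g. cluster-averaged
  weights) would give somewhat different small-`m` behaviour.
* Cluster sizes are non-informative, outcomes are binary, and only two
  cluster-level covariates exist in the parametric arm — all by design.
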