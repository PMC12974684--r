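---
title: "Transfer learning of optimal treatment regimes with censored survival data: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transfer learning of optimal treatment regimes with censored survival data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survtransfer)
```

## The problem

A trial (or other selection-biased study) measures covariates $X \in
\mathbb{R}^p$, a binary treatment $A$, and a right-censored survival
outcome: the observed time $U = \min(T, C)$ and event indicator $\Delta =
I(T \le C)$. The population we actually want to treat — the *target*
population — is represented only by a second sample carrying covariates and
known design weights $e(x) = 1/\Pr(I_T = 1 \mid X = x)$. Because inclusion
in the source study depends on $X$ (a *covariate shift*, with sampling
score $\pi_S(x) = \Pr(I_S = 1 \mid X = x)$), a treatment rule tuned to the
source sample is generally not optimal for the target population, and a
source-only value estimate of any rule is biased for its target value.

An individualized treatment regime (ITR) is a map $d : x \mapsto \{0, 1\}$.
Its value is $V(d) = E[y(T(d))]$ in the target population, where $T(d)$ is
the counterfactual survival time under the rule and $y$ is either the
survival indicator $y(T)=I(T \ge t)$ or the restricted-mean transformation
$y(T)=\min(T, L)$ (the RMST, the area under the survival curve on
$[0, L]$). We search the interpretable linear class
$$ d_\eta(x) = I\{\eta^\top (1, x^\top)^\top \ge 0\}, $$
with the coefficient of a designated continuous *anchor* covariate (by
convention the last column) fixed to $|\eta_{p+1}| = 1$ for
identifiability: any positive rescaling of $\eta$ leaves the rule
unchanged, so one coordinate must be pinned. `linear_itr()` normalizes by
the absolute value of the anchor coefficient, preserving its sign; the
canonical representation is $+1$ and the $-1$ branch arises only as the
mirrored policy-search run.

Identification rests on the usual causal survival assumptions *within the
source population* (consistency, treatment positivity, unconfoundedness,
conditionally independent censoring, and a maximal horizon $h$ with
$\Pr(C < h \mid X, A) < 1$), plus survival mean exchangeability between
source and target given $X$, positivity of source inclusion, and a known
target design.

## The estimator

The package's central estimator of the counterfactual survival curve
$S_d(t) = \Pr(T(d) > t)$ combines four terms, one per line:

$$
\widehat S_d(t) =
\sum_{i \in \text{src}} q_i\, \frac{I(A_i = d_i)}{\widehat\pi_{d_i}(X_i)}
  \frac{\Delta^h_i\, I(U_i \ge t)}{\widehat S_C(U^h_i \mid A_i, X_i)}
+ \sum_{j \in \text{tgt}} \frac{e_j}{\sum e_j}\, \widehat S(t \mid d_j, X_j)
- \sum_{i \in \text{src}} q_i\, \frac{I(A_i = d_i)}{\widehat\pi_{d_i}(X_i)}
  \widehat S(t \mid A_i, X_i)
+ \sum_{i \in \text{src}} q_i\, \frac{I(A_i = d_i)}{\widehat\pi_{d_i}(X_i)}
  \widehat J_i(t),
$$

an augmented calibration-weighted (ACW) estimator built on the efficient
influence function of $V(d)$: an inverse-probability-weighted term using
only rule-consistent source subjects, an outcome-regression term averaged
over the design-weighted target sample, a source-sample
outcome-regression correction, and a censoring-martingale augmentation
$\widehat J_i$. It is doubly robust — consistent if either the conditional
survival model or the combined sampling/propensity/censoring models are
correct — and locally efficient when all are.

Three numerical conventions deserve attention; each was adopted after the
alternative measurably failed.

**Horizon capping.** The transformation is indifferent to survival beyond
its maximal horizon $h$ ($L$ for the RMST), so the observed data are
capped at $h$: $U^h = \min(U, h)$ and $\Delta^h = \Delta \vee I(U \ge h)$ —
a subject still under observation at $h$ is an event at $h$. Censoring
positivity is guaranteed only up to $h$; without capping, the weight
$1/\widehat S_C(U)$ is evaluated beyond the horizon, where it can be
astronomically large, and single late events dominate whole bootstrap
replicates.

**The martingale integral runs to $\min(U_i, h)$, not to $t$.** With
$\widehat M_C$ the estimated censoring martingale, the augmentation is
$$
\widehat J_i(t) = \int_0^{\min(U_i, h)}
\widehat Q(u, t)\,
\frac{d\widehat M_C(u \mid A_i, X_i)}{\widehat S_C(u \mid A_i, X_i)},
\qquad
\widehat Q(u, t) = \begin{cases}
\widehat S(t \mid A_i, X_i)/\widehat S(u \mid A_i, X_i), & u \le t,\\
1, & u > t,
\end{cases}
$$
the conditional mean of $I(T \ge t)$ given survival to $u$. The increments
beyond $t$ have mean zero, which tempts one to drop them; but pathwise
$1/S_C(U) = 1 + \int_0^U \lambda_C/S_C\,du$, so exactly those increments
cancel the potentially enormous inverse-censoring factor of the first
term. In simulation under the benchmark generating process, truncating the
integral at $t$ left the estimator unbiased but inflated its sampling
standard deviation fourfold (0.19 versus 0.046 with oracle nuisances at
$n \approx 3000$).

**A tiny denominator floor.** Survival and censoring-survival denominators
are floored at `eps = 1e-6` — a guard against exact zeros, not a trimming
device. An aggressive floor (say 0.01) looks prudent but breaks the same
internal cancellation: the combined event-subject contribution is
$1 + \int_0^t (\lambda_C/S_C)\,(1 - S(t)/S(u))\,du$, finite precisely
because numerator and denominator degrade together; flooring one side
reintroduced a bias of $-0.12$ on an RMST of about 2.4 in the oracle
experiment. Propensity and sampling-score *probabilities* are clipped at
the conventional $[0.01, 0.99]$ band, where clipping is harmless.

All estimator blocks are Hájek-normalized: source weights $q_i$ sum to one
(entropy-balancing weights, or self-normalized inverse sampling scores),
and target weights are $e_j/\sum_j e_j$. With constant weights this makes
the ACW curve algebraically identical to the source-only doubly robust
curve when the two samples share covariates — the no-covariate-shift
equivalence that the test suite checks to $10^{-10}$.

The comparison estimators (`naive`, `ipsw`, `cw_ipw`, `cw_or`, `or_t`,
`dr_source`) share the same precomputed ingredients; see
`estimate_survival_simple()`.

## Nuisance models

`fit_nuisances()` fits the parametric working models: a logistic
propensity $\text{logit}\,\pi_A(x) = \theta^\top(1, f(x))$ and four Cox
proportional-hazards models (survival and censoring, one per arm) with
Breslow cumulative-baseline estimates
$\widehat\Lambda_0(t_k) = \sum_{t_j \le t_k} d_j / \sum_{l \in R(t_j)}
e^{\beta^\top z_l}$, which reduce exactly to Nelson–Aalen when $\beta = 0$.
Every model takes a *feature map*, the single mechanism used both to
control specification and to misspecify deliberately in simulation
studies. Random-forest nuisances (`fit_nuisances_forest()`, via `ranger`:
a probability forest for the propensity, survival forests for outcome and
censoring) satisfy the same prediction interface and plug into
cross-fitting unchanged.

Ties use Breslow handling, matching the baseline estimator. Perfect
separation in the logistic fit triggers a deterministic ridge-penalized
($\lambda = 10^{-4}$) refit with a warning.

## Calibration weighting

Rather than modelling $\pi_S$ explicitly, `calibrate_weights()` solves the
entropy-balancing program
$$
\min_q \sum_i q_i \log q_i
\quad\text{s.t.}\quad q \ge 0,\ \textstyle\sum_i q_i = 1,\
\sum_i q_i\, g(X_i) = \tilde g,
$$
where $\tilde g$ is the design-weighted target moment vector. The solution
$q_i \propto \exp(\hat\lambda^\top g(X_i))$ comes from a damped Newton
iteration on the strictly convex dual $\lambda \mapsto \log \sum_i
\exp\{\lambda^\top (g_i - \tilde g)\}$, started at $\lambda = 0$ with
backtracking line search, gradient tolerance $10^{-10}$, at most 200
iterations, and internal standardization of the $g$ columns for
conditioning. Infeasible targets (outside the convex hull of the source
values) are reported as such rather than silently approximated. The
loglinear form of $q$ doubles as an out-of-sample weight *predictor* —
used by cross-fitting, where calibration is re-solved on each training
complement and fold weights come from the complement's $\hat\lambda$.
Default calibration functions are the first covariate moments
(`moments = 2` adds squares; arbitrary named transforms are accepted).
The explicit-model alternative, `fit_sampling_score()`, fits source
membership on the stacked samples with design-weighted target rows; since
only relative weights matter after self-normalization, its inverse fitted
odds serve as inverse-probability-of-sampling weights.

## Policy search

The estimated value surface is piecewise constant in $\eta$ — non-convex
and non-smooth — so the package maximizes it with a population-based
global optimizer (differential evolution, `DE/rand/1/bin`), never with
gradients. Defaults: population 50, 200 generations, 5 restarts, box
$[-20, 20]$ per free coordinate, crossover 0.9, differential weight 0.8, a
mandatory seed, and a mirrored run with the linear score negated so both
signs of the anchor coefficient are covered. Covariates are standardized
internally for the search and the winning rule is mapped back to the raw
scale. Exact value ties keep the first-found candidate. The search budget
is configuration, not dogma: the value of a rule is flat near its optimum,
so modest budgets already recover near-optimal rules, but the *maximum* of
a noisy surface grows with search effort — comparisons of estimated values
across estimators should therefore hold the budget fixed.

Everything rule-independent is precomputed once (`value_context()`), so
one candidate evaluation costs two matrix cross-products; policy search at
$n \approx 3000$, 300 grid times runs at roughly a millisecond per
candidate.

## Cross-fitting

`crossfit_value()` implements $K$-fold cross-fitting (default $K = 5$):
both samples are split into near-equal folds; nuisances *and* calibration
are trained on each fold's complement; fold $k$ is evaluated with its
complement-trained models; and the estimate is the arithmetic mean of the
fold estimates. Per-subject weights are the out-of-fold calibration
predictions normalized globally, and fold estimates are defined as $K$
times the fold's share of the global sum. This choice makes the aggregate
*exactly* the full-sample estimator whenever the learners ignore their
training data, so fold-plan invariance under oracle nuisances is an
algebraic identity the tests can assert at $10^{-12}$, and the no-leakage
property is asserted with instrumented learner factories. Policy search
under cross-fitting maximizes the aggregated value with nuisances fitted
once per fold, not per candidate rule.

## Bootstrap inference

`bootstrap_value()` resamples source and target rows independently with
replacement (the two samples are independent by design), re-runs the full
pipeline on each replicate, and reports the replicate standard deviation
together with normal and percentile intervals. Resampled index sets are
drawn up front from the seed, so the replicate vector is bit-identical
across runs. Degenerate resamples (for example a single treatment arm)
fail inside the pipeline and are dropped with a warning; more than 10%
failures abort. `confint()` on a fitted `itr_fit` bootstraps the value at
the *fixed* fitted rule by default — re-optimizing the rule inside every
replicate is exposed as `reoptimize = TRUE` but is computationally
dominant and not part of the default procedure.

## The synthetic-data engine

`simulate_population()` generates the benchmark study the package is
validated on: covariates $(X_1, X_2, X_3)$ truncated ($\pm 4$) multivariate
normal with unit variances and $\text{corr}(X_1, X_3) = 0.2$; sampling
score $\pi_S(X) = \text{expit}(-4.5 - 0.5X_1 - 0.5X_2 - 0.4X_3)$ (about
1.6%, so $N = 2\times10^5$ yields $n \approx 3000$); propensity
$\pi_A(X) = \text{expit}(0.5 + 0.8X_1 - 0.5X_2)$; Gompertz-type hazards
$\lambda(t) = e^t k(x)$ with
$\log k_0 = -2.5 - 1.5X_1 - X_2 - 0.7X_3$ and
$\log k_1 = -1 - X_1 - 0.9X_2 - X_3 - 2X_2^2 + X_1X_3$, inverted in closed
form as $T = \log(1 + E/k)$ for $E \sim \text{Exp}(1)$; arm-specific
censoring hazards with scale 0.04 (≈20% censoring) or 0.2 (≈33%); a
simple-random target sample ($e = N/m$); and an RMST horizon $L = 4$.
Whole-vector rejection sampling preserves the correlation structure under
truncation (acceptance is essentially 1 at $\pm 4$). One censoring time is
drawn per arm per subject and the realized arm's is observed. Named RNG
substreams (covariates, each potential outcome, censoring, treatment
assignment, sampling, target draw) keep a change in one design knob from
perturbing unrelated draws.

Two details of the *working models* matter when replicating the benchmark:

- A "correctly specified" outcome model must carry the curvature of the
  arm-1 hazard: `scenario_nuisances()` therefore uses features
  $(X_1, X_2, X_3, X_2^2, X_1X_3)$ for the correct survival model (the
  extra columns are harmless in arm 0, where their true coefficients are
  zero). A Cox model linear in $X$ is *not* correct here, and treating it
  as such shifts the outcome-regression estimators by about $-0.13$.
- The misspecified versions under-specify the sampling model by
  calibrating on the first moment of $X_1$ only (leaving the $X_2$/$X_3$
  shift uncorrected — this reproduces the benchmark's reported
  outcome-regression-with-wrong-weights bias of about $-0.13$, where
  calibrating on $e^{X_1}$ would give $-0.32$), fit the propensity on
  $e^{X_3}$, and fit the survival/censoring Cox models on
  $(e^{X_1}, e^{X_2}, e^{X_3})$; for the correct-specification scenarios
  the calibration functions are the first moments of $(X_1, X_2, X_3)$.

`true_value_and_pcd()` evaluates any rule on a generated population by
plug-in averaging of the potential outcomes, and `oracle_eta_star()`
obtains the reference optimal linear rule by global search on the true
value; the percentage of correct decisions (PCD) of a candidate rule is
its agreement with that reference.

What the generator does *not* emulate: covariate measurement error,
time-varying covariates or treatments, competing risks, non-monotone
sampling designs, and real-data messiness such as ties from coarse
follow-up recording. Tests passing under this generator demonstrate
correctness of the estimators under the stated model, not robustness to
those phenomena.

## Problem sizes used by the validation suite

The packaged checks replicate the benchmark patterns at reduced scale,
chosen once as a deliberate compromise between Monte-Carlo resolution and
desk-scale runtime: populations of $10^5$ (source $n \approx 1600$, target
$m = 4000$) with 50 replications for the bias patterns; a uniform 300-point
time grid for RMST integration (step-integration error ≈ 0.005, well below
Monte-Carlo error at these sizes); differential-evolution budgets of
population 16–30 × 20–50 generations; and coverage checked at $N = 5\times
10^4$, $m = 1000$, 100 replications with $B = 100$ bootstrap replicates at
a fixed rule. Two consequences of the scale-down are worth knowing. First,
the estimated value at the *searched* rule is the maximum of a noisy
surface, so it grows with search budget; biases quoted for estimators with
large sampling variance (the pure weighting estimators especially) are
budget-dependent, and the suite asserts signs and magnitudes with
tolerances that accommodate this. Second, a genuine finite-sample effect
remains at these sizes: the Breslow baseline of the arm-1 censoring model
is estimated from sparse late jumps, which depresses the ACW value by a
few hundredths on an RMST of ≈2.4 — visibly smaller with oracle censoring,
and shrinking with $n$.

## Known limitations

- Single decision point, binary treatment, linear rules only.
- In the validation suite's all-models-wrong scenario, the
  misspecification bias of the augmented estimator reproduces in sign and
  pattern but its magnitude settles around 0.18 at the reduced study size
  (0.19 at the full benchmark size), somewhat below the published
  benchmark's 0.26; every shared ingredient (the wrong calibration, the
  wrong propensity and censoring models via the pure weighting
  estimators, the data-generating process itself) reproduces its own
  reference value, so the residual gap sits in the augmentation terms
  under joint misspecification, where implementation differences are not
  further resolvable from the published numbers alone. The corresponding
  check is asserted at its pre-registered band and reports the miss
  rather than hiding it.
- The bootstrap treats the fitted rule as fixed; inference on the *rule
  parameters* themselves (cube-root asymptotics) is out of scope.
- Closed-form influence-function variance estimates are not provided; the
  bootstrap is the inference route.
- Calibration requires the target moments to lie in the convex hull of the
  source values; severe non-overlap is reported as an error, by design.
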