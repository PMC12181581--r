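---
title: "Optimized cognitive scoring: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimized cognitive scoring: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opticog)
```

## The scoring model

Six cognitive test channels enter the model: fluid intelligence (correct
answers out of 13), pairs-matching memory errors, and mean reaction time in
milliseconds, each at a baseline visit t1 and an imaging visit t3. The
skewed channels are log-transformed — PMM as `log(x + 1)` because zero
errors are common, RT as `log(x)` — and each channel is standardized with
means and standard deviations fitted on training data only. Natural
logarithms are used throughout: the published RT channel means (about 6.32
for reaction times near 550 ms) are consistent only with base e.

The cognitive score is a sign-constrained logistic function of the
standardized channels,

$$\gamma = \sigma\!\left(\theta_0 + \sum_{i=1}^{6}\theta_i x_i\right),
\qquad \theta_1,\theta_2 \ge 0,\; \theta_3,\dots,\theta_6 \le 0,$$

encoding the prior knowledge that fluid intelligence correlates positively
with cognition while errors and slow reactions correlate negatively. The
projection onto this feasible domain maps each weight to its signed
absolute value and leaves the bias free; it is idempotent and is applied to
every candidate the optimizer generates.

Labels come from extreme quantiles of the *training* score distribution:
`lb` is the q-th and `ub` the (1−q)-th linear-interpolation quantile;
scores at or below `lb` are Cognitive Decliners, at or above `ub`
Positive-Agers, and the middle Normal-Agers, who are excluded from the
binary classification. Both boundary comparisons are inclusive. The
quantile estimator (interpolation between order statistics, R type 7) is a
documented, configurable choice; thresholds are re-derived from training
scores at every parameter evaluation — scoring and labeling sit inside the
optimization loop — and the pair belonging to the optimal parameters is
frozen and applied unchanged to validation and test data.

The package also ships the published optimal model
(`published_model()`): weights (−0.622, 1.764, 2.198, −0.349, −1.371,
−0.633, −1.191), channel means (6.86, 6.79, 1.40, 1.41, 6.32, 6.40) and
sds (1.98, 2.03, 0.62, 0.61, 0.18, 0.17), bounds 0.004 and 0.986. Whether
those statistics were fitted on training data alone or on the whole source
cohort is not recoverable; the package treats them as a frozen model and
fits its own standardizers train-only.

## The optimizer

CANS (constrained adaptive noise scaling) is a derivative-free,
simulated-annealing-style search. Each iteration draws `nc` candidates by
adding iid Gaussian noise (scale σ) to the incumbent, projects them
feasible, evaluates all, and takes the arg-min with ties going to the
lowest candidate index. A strictly smaller loss replaces the incumbent and
contracts σ by `delta_l`; otherwise σ expands by `delta_u`, capped at
`sigma_max`. "Improvement" is strict, so plateaus widen the search. One RNG
stream per run, consumed in candidate-major order, makes traces exactly
reproducible.

Defaults — `nc = 20`, `j_max = 200`, `delta_l = 0.9`, `delta_u = 1.1`,
`sigma_max = 1`, `sigma0 = 0.25`, zero initialization — are the package's
own choices of a modest geometric schedule; the source hyperparameter table
is not public, so all are exposed in configuration. Zero initialization is
feasible and neutral; a warm start from the PCA loading is available by
passing `theta_init`.

## The two predictive pipelines

The *inner* pipeline g keeps each loss evaluation cheap: features are
ranked by total Gini impurity reduction in one deterministic depth-capped
decision tree (all features available at every split, no subsampling) and
the top `f_keep = 150` at depth `m_fs = 50` are kept; selected features are
mean/variance-scaled on training rows; an L1-penalized logistic regression
is fitted over a 7-point log-spaced grid of inverse regularization
strengths spanning 1e−3 to 1e3, and the grid winner is the value with the
highest validation AUC. The description of the selector as one impurity
ranking (rather than iterated elimination with refits) follows the
procedure's own parenthetical definition; a single pass is also what keeps
g fast enough to sit inside the optimizer. The loss is `1 − AUC` on the
validation extremes. Degenerate labelings — all scores equal, or an empty
extreme class — return a sentinel loss of 1.0 with a warning so the
optimizer remains total.

The *final* pipeline G replaces speed with capacity: robust scaling
(median/IQR, linear-interpolation quartiles, zero-IQR features divide by 1
and are flagged), impurity selection with *tunable* `f_keep` and `m_fs`,
and a gradient-boosted tree ensemble. Hyperparameters — `f_keep` in
[20, 150], selector depth [3, 50], boosting rounds [50, 500], tree depth
[2, 8], learning rate [0.01, 0.3] on the log scale, row/column subsampling
[0.5, 1], L2 regularization [1e−3, 10] log — are searched by sequential
model-based optimization: a maximin Latin-hypercube initial design, then
expected-improvement acquisition over a random-forest surrogate whose
per-tree spread provides the predictive uncertainty. No dedicated Bayesian
optimization package ships with the common scientific R stacks, so this
small SMBO loop is implemented in-package. Candidates are scored by k-fold
cross-validated AUC on the combined train+validation extremes (the final
model is trained on both, and the source does not say how its search
objective was scored; cross-validation is this package's choice, default 5
folds), and the winner is refit on all rows.

Baselines: `dmri_only` and `demo_only` re-run the whole procedure with one
feature block removed; `pca` replaces the optimized scorer by the first
principal component of the standardized tests mapped through the sigmoid.
The PC sign is indeterminate, so the loading is oriented to make the FI3
coefficient non-negative, matching the sign prior of the main model.

## Trajectory calculus

The linear predictor decomposes exactly as
$\theta_0 + S_1^{adj} + S_3^{adj}$, with each visit's adjusted score
weighting that visit's standardized tests by its optimal coefficients.
Applying the logit to the labeling rule turns class membership into
half-plane rules on $S_1^{adj}+S_3^{adj}$ with boundary constants
$c(b) = -\theta_0 + \ln(b/(1-b))$; for the published model these are −4.9
and 4.9 at one decimal (carried at full precision internally, rounded for
display). The adjusted slope is $(S_3^{adj}-S_1^{adj})/\Delta t$; the
synthetic default Δt of 8 years reflects a 2006–2010 baseline visit and a
2014 imaging visit, and is configurable per participant.

Mean slope versus baseline age is fitted per class by robust M-estimation
(Huber weights) to downweight sparse outlying age cells; integrating the
fitted line $mt+b$ gives the average trajectory curve
$C(t)=mt^2/2+bt+u$ with $u$ anchored so $C(55)$ equals the class's mean
baseline adjusted score. One-dimensional class split points minimize
weighted Gini impurity greedily over midpoints of consecutive unique
values (ties toward the smaller threshold, at most two thresholds, stop
when no split strictly reduces impurity). The expected-slope grid averages
slopes over participants of a given integer age whose baseline adjusted
score lies within ±0.25 of the grid value, and reports cells with fewer
than 10 participants as missing. The first-visit classifier is a
depth-limited (default 4) three-class decision tree on baseline-only
features.

## Feature importance

Shapley attributions for the boosted model use the exact tree-path
algorithm via the booster's prediction contributions, on the margin
(log-odds) scale by default, where local accuracy is exact: attributions
plus the base value reproduce each observation's margin. A probability
option rescales each row linearly so attributions sum to the shift from
the base-rate probability — convenient for "percentage-point impact"
readings, at the cost of exactness of the per-feature decomposition.
Importance is the mean absolute attribution; aggregation sums dMRI feature
importances within a diffusion attribute or tract (conserving the total
exactly) and reports demographic features singly.

## The synthetic cohort generator

A latent ability trait $z \sim N(0,1)$ drives everything. Standardized
test channels are $\pm \lambda z + \varepsilon$ (FI positive, PMM/RT
negative; default loading 0.9, noise sd 0.35, rescaled to unit variance),
then inverted through the published channel statistics and the log
transforms to produce raw values: FI rounded and clipped to 0–13, PMM as
`round(exp(x) − 1)` clipped non-negative, RT as `exp(x)`. The rounding
introduces a mild marginal distortion at the integer scales. Informative
dMRI features equal $\rho\,t + \sqrt{1-\rho^2}\,\varepsilon$ where the
target $t$ is the latent trait (default) or the standardized planted
linear predictor (`dmri_target = "score"`, used to study asymmetric
weightings); defaults plant 20 informative features of 135 at ρ = 0.6.
Demographics shift with $z$ in the directions reported for aging cohorts —
Positive-Agers younger, more educated, more often male, higher income,
slightly larger waist — at an adjustable effect scale whose values are
illustrative, not calibrated to any cohort table. Ages span 55–70 at
baseline.

What passing tests on this generator do show: the optimizer recovers a
planted monotone latent ordering; the pipelines detect genuinely
informative features and stay at chance when none exist; the trajectory
identities hold. What they do not show: performance on real cohort data,
whose dMRI features are strongly cross-correlated (here only through the
single planted trait), whose missingness is structured (here complete
cases by construction), and whose demographic effects are confounded with
age rather than planted independently.

## Numerical and design choices

* Standard deviation convention: sample (N−1) by default, configurable to
  population (N); the two differ negligibly at cohort sizes but matter in
  toy examples.
* Splits are drawn from the full cohort before labeling; Normal-Agers are
  excluded after labeling within each split, which is why extreme-class
  counts vary with q.
* Split sizes take the floor of each fraction with leftovers assigned by
  largest fractional remainder, ties toward the test set.
* Missing values are handled by complete-case exclusion with per-row
  warnings; no imputation.
* AUC uses the Mann–Whitney rank statistic with half credit for ties.
* Hedge's g includes the small-sample correction J and is signed as group
  a minus group b over the pooled sd.
* Degenerate cases surface explicitly: undefined metrics are `NA` with a
  warning, never 0; a tie `lb == ub` labels via the Decliner branch first
  and warns; zero-IQR features scale by 1 and are flagged.
* Scores are computed in double precision with no clipping — the logistic
  never attains 0 or 1.

## Problem sizes used by the test suite

The behavioural checks run at deliberately modest scale so the whole suite
completes in minutes on one CPU: parameter-recovery experiments use
synthetic cohorts of n = 2000 over three seeds with a reduced optimizer
budget (10 candidates × 50 iterations) and an 8-evaluation, 3-fold search
for the final pipeline; the baseline-ordering experiment uses n = 1200
with weakened dMRI correlation (ρ = 0.4) and extra test noise so the
compared AUCs sit below ceiling; algebraic identities are asserted on 10⁴
random participants at 1e−10. These sizes are the package's chosen
experimental conditions for its own regression tests, large enough that
the measured properties are stable across seeds.

## Known limitations

* The exact tract inventory behind the 135-feature dMRI block is not
  enumerated publicly; the feature count and metadata are configurable and
  the synthetic inventory uses real tract names cycled over attributes.
* The optimizer's published hyperparameters and the final pipeline's
  search table are in non-public supplementary material; defaults here are
  documented stand-ins.
* Population-level results from the restricted source cohort (its AUC
  tables, demographic contrasts, and data-derived split points) are out of
  scope: the package verifies procedures, not those numbers.
* No alternative link functions, no joint optimization over q, no deep
  learners, and no interaction decomposition of Shapley values.
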