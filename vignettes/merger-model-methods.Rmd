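---
title: "Naive Bayes consensus merger models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Naive Bayes consensus merger models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbcmerge)
```

## The problem

Clinical cohorts assembled from routine records are wide, mixed-type and
incomplete: a few hundred patients, dozens of candidate predictors (comorbidity
flags, spirometry, ECG measurements, anthropometry), and a binary composite
outcome such as *death or very poor health-related quality of life*. Two
things make ordinary regression awkward here. First, complete-case logistic
regression discards any patient missing any included predictor, so the usable
sample shrinks — sometimes drastically — as predictors are added. Second,
variable selection on a single data set is unstable at these sample sizes.

`nbcmerge` implements a *consensus merger model* built around a naive
Bayesian classifier (NBC):

1. the cohort is randomly partitioned into a training and a held-out test set
   (defaults 538/200), independently, ten times;
2. within each training set, predictors are selected by greedy backward
   elimination against a leave-one-out objective;
3. variables selected in at least four of the ten training sets form the
   consensus candidate pool;
4. a final NBC is fit on the full cohort after one more greedy reduction of
   the pool, and reported with leave-one-out validation, classification
   diagnostics and a posterior-odds evidence table.

## The classifier

For class $y \in \{0, 1\}$ and discretized predictors $x_1, \dots, x_p$ the
NBC applies Bayes rule under conditional independence:

$$P(y \mid x) \propto P(y) \prod_{j\,:\,x_j\ \text{observed}} P(x_j \mid y).$$

Each $P(x_j = c \mid y)$ is a smoothed frequency
$(n_{cy} + \alpha) / (n_{\cdot y} + \alpha K)$ with pseudo-count
$\alpha = 0.5$ per cell. The half-count is the minimal (Jeffreys-style)
smoothing that keeps never-observed cells away from zero; no informative
prior beyond it is used anywhere. Two missing-data rules give the NBC its
full-cohort data usage:

* **pairwise deletion at fit time** — a patient missing predictor $j$ is
  excluded only from predictor $j$'s frequency table;
* **factor skipping at prediction time** — an unobserved predictor simply
  contributes no factor, so a patient with no observed predictors scores the
  class prior. Under the model this equals marginalising the missing
  predictors out of the joint distribution, which the test suite checks
  against brute-force enumeration.

A category never seen at fit time is treated as missing (with a warning)
rather than crashing prediction.

## Discretization

Continuous predictors are cut into $k = 3$ equal-frequency bins, fit on
training rows only; the low/middle/high pattern matches how clinical
thresholds for such models are usually reported. The derivation of such
published thresholds is typically unstated, so tertiles are the default and
explicit cutpoints declared in the schema (for instance the conventional BMI
classes at 20/25/30) override the data-driven rule. Bins are right-closed,
$(c_{j-1}, c_j]$, lowest bin closed below at $-\infty$: a value equal to a
cutpoint falls in the lower bin. The convention is arbitrary but must be
fixed somewhere; it is serialized with the map.

## Greedy backward elimination and the leave-one-out objective

Selection starts from the full candidate set and repeatedly removes the
single variable whose removal most improves the leave-one-out (LOO)
**log-score**, the mean of $-\ln$ of the predicted probability of the true
class; it stops when no removal improves, breaking ties toward the variable
earliest in schema order. Log-score is preferred to accuracy because
accuracy is piecewise constant and blind to most single-variable changes at
$n$ of a few hundred.

Because the naive-Bayes log-posterior is additive over predictors and each
predictor's table uses pairwise deletion, a variable's LOO contribution to
every row can be computed once from the full-data counts (subtracting the
held-out row's own contribution); the objective of any subset is then a sum
of cached columns. This is algebraically identical to refitting $n$ models
per evaluation — the equivalence is asserted in the tests at $10^{-12}$ —
and makes a full backward pass over ~50 candidates take fractions of a
second, which is what allows property-style tests to run whole pipelines
repeatedly.

LOO accuracy is reported next to a *best guess* reference (always predict
the majority class); the log-score reference uses the class prior as the
constant predicted probability. Published log-scores for this model family
follow no convention we could reproduce, so only internal consistency is
asserted for ours.

## The consensus rule

Each of the ten partitions re-samples 538 + 200 of the cohort's rows without
replacement, independently (fresh draws, not a rotation). A variable enters
the final candidate pool if selected in at least 4 of 10 training sets. The
splits share most of their rows, so the ten selections are positively
correlated; the consensus therefore filters split-specific noise but *not*
cohort-level chance association. This is visible in simulations with planted
effects: the final model recovers essentially all planted predictors but
retains a handful (typically 4–7 of 43) of null variables whose association
with the outcome is stable in that cohort. That behaviour is a property of
the procedure at $n \approx 738$, and the acceptance suite reports it
honestly rather than hiding it.

## Posterior odds and Jeffreys intervals

Evidence strength for each final-model variable is reported per direction:
the *protective* record uses the category most frequent in the good-outcome
class, the *risk* record the category most associated with the poor outcome.
For a single-factor posterior $p$ (a raw conditional frequency, with counts
exposed so a smoothed variant can be formed if wanted), the posterior odds
are $\mathrm{PO} = p/(1-p)$, and equal-tailed credibility intervals come
from the Jeffreys posterior $\mathrm{Beta}(x + \tfrac12, n - x + \tfrac12)$,
with the conventional endpoint fixes at $x = 0$ and $x = n$. Odds intervals
are the odds transform of the probability interval (a strictly monotone map,
so containment is preserved). The interval denominator defaults to the
number of rows with the variable observed — back-calculation of published
intervals of this kind is consistent with that convention — and can be
switched to the factor-count convention (`ci_n = "factor"`), which is the
one whose frequentist coverage the tests verify (92–98% across
$n \in \{50, 647\}$). Percentages and odds are rounded to one decimal for
presentation; unrounded values stay attached as an attribute.

## Logistic benchmarks

Six complete-case logistic strategies are provided for comparison: (1) the
merger model's own variables, (2) variables at least 80% observed, (3)
variables fully observed, (4) forward and (5) backward stepwise at
likelihood-ratio $p = 0.10$ over all candidates, and (6) manual one-by-one
dropping of the worst-$p$ predictor with refitting on the complete cases of
the survivors. Variants 4–5 run on the complete cases of the full candidate
set, as an automated stepwise tool would; variant 6's usable rows grow as
predictors leave, which is why its $n$ differs. McFadden's pseudo-$R^2$ is
reported (the convention of the usual econometric tooling), classification
is at 0.5, and each variant also reports the *worst possible correct
classification*: `round(correct/100 * n_used) / n_total * 100`, the
guaranteed floor if every row the complete-case fit discarded were
misclassified. Fits with separation are flagged non-converged rather than
reported as clean estimates.

## The synthetic cohort generator

No patient-level data of this kind are publicly deposited, so the package
ships a generator whose default spec is the study condition for every test:

* **n = 738** patients, 49 predictors: 21 binary comorbidity/medication
  flags, 26 continuous measurements (Gaussian, or lognormal for skewed
  quantities such as pack-years and CRP) with means and SDs matching
  published cohort descriptives (e.g. FEV$_1$ % predicted ~N(57, 19), QTc
  ~N(420, 25)), and 2 ordered categorical scores;
* **ten planted effects** on the latent (pre-binning) scale: odds ratios
  2.1–4.7 on six comorbidity flags and per-unit effects on FEV$_1$, QTc, age
  at asthma onset and BMI — the magnitudes reported for cohorts of this
  kind;
* **outcome prevalence 0.287**: the intercept is solved on the realised
  linear predictor so the mean outcome probability equals the target
  exactly, making prevalence a parameter rather than a tuning exercise;
* **missingness** MCAR on twelve measurement columns (ECG, diffusing
  capacity, post-bronchodilator spirometry, blood gases) at rates 3–7%,
  chosen so the all-49-variable complete-case fraction is ~0.56 — the
  attrition level complete-case regression exhibits on such tables. A
  MAR mechanism (rate modulated on the logit scale by an observed covariate)
  is available but off by default.

Reproducibility: one root seed; each column and the outcome draw from their
own child streams in declaration order, so results do not depend on
evaluation order, and identical spec + seed reproduce the stored CSV byte
for byte.

What the generator does *not* emulate: correlation between predictors (all
are drawn independently), informative missingness tied to the outcome,
survival time (the outcome is a fixed binary composite), or the item
structure of any HRQoL instrument. Passing tests therefore demonstrate the
pipeline's behaviour under clean conditional-independence conditions, not
its performance on real clinical data, where correlated predictors would
change both selection stability and the meaning of single-factor posterior
odds.

## Numerical choices and degenerate inputs

* Posterior computation is done on the logit scale; opposing infinite
  log-likelihood ratios (possible only at $\alpha = 0$) cancel to "no
  evidence".
* Classification ties at the threshold go to the majority training class.
* `compute_po` signals $p \in \{0, 1\}$ distinctly (0 or `Inf`, with a
  warning) instead of erroring, since boundary posteriors legitimately occur
  with perfect predictors.
* Constant or near-constant continuous columns make equal-frequency
  cutpoints collide and raise an error naming the column.
* A training outcome with a single class is an error at fit time.

## Problem sizes used in the tests

Property suites run whole pipelines at the default study scale (n = 738, 49
predictors, 10 splits — about three seconds per run), with 25-replicate
recovery simulations, 50-replicate Wald-coverage checks at n = 10 000, and
2 000-replicate interval-coverage checks; smaller toy tables are used where
the oracle is hand enumeration.

## Known limitations

* The consensus rule does not control cohort-level false inclusion (see
  above); interpret final-model membership as "stably associated in this
  cohort", not as a causal or even population-level claim.
* Single-factor posterior percentages are marginal, not adjusted; with
  correlated predictors they would not multiply into the model's joint
  posterior.
* Stepwise benchmark mechanics (entry/stay order, LRT vs Wald) vary across
  software; ours is LRT at 0.10 both directions and is validated against an
  exhaustive fixed-point search on five candidates, not against any
  particular commercial implementation.
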