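---
title: "Deep survival networks: model, training, optimization and interpretation"
author: "DeepCox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep survival networks: model, training, optimization and interpretation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DeepCox)
```

## The model and its assumptions

A deep survival network is a feed-forward network whose output layer is a
Cox proportional-hazards model. Hidden layer $h$ applies
$A_h = \sigma(A_{h-1} W_h + b_h)$ with $\sigma$ either ReLU or tanh; the
output is the linear score $s_i = X_i \beta$, where $X_i$ denotes the
final hidden representation of patient $i$ and $\beta$ the Cox
coefficients. The exponential of the Cox model is never applied: the
network predicts log-relative risk, and only the ordering of scores
matters for both the likelihood and the evaluation metric.

Training minimizes the negative log partial likelihood
$$
l = -\sum_{i \in U}\Big( s_i - \log \sum_{j \in R_i} e^{s_j} \Big),
$$
with $U$ the uncensored patients and $R_i = \{\, j : Y_j \ge Y_i \,\}$ the
risk set at patient $i$'s observed time. The underlying assumptions are
those of any Cox-type model: censoring non-informative given the
features, and hazards proportional in the *learned* representation — a
much weaker requirement than proportionality in the raw features, which
is exactly what the hidden layers buy.

Two conventions are fixed deliberately:

* **Ties.** The risk set uses $\ge$, i.e. Breslow handling of tied event
  times, with no Efron correction. Tied patients are mutually at risk.
* **Per-sample gradient.** The loss derivative backpropagated from the
  output layer is
  $\partial l/\partial s_i = -c_i + e^{s_i}\sum_{j \in U,\, i \in R_j}
  \big(\sum_{k \in R_j} e^{s_k}\big)^{-1}$, where $c_i$ is the event
  indicator. The unit tests pin this against central finite differences
  of the loss (relative error below $10^{-6}$ across random instances
  with tied times and mixed censoring) — the gradient components also sum
  to zero, a useful quick invariant.

Numerically, the inner $\log \sum e^{s_j}$ is computed with the
subtract-the-maximum log-sum-exp so large scores cannot overflow, and the
risk-set sums are accumulated over time-sorted tie groups, making the
loss exactly invariant to patient permutation and to adding a constant to
all scores.

## Training mechanics

Because the partial likelihood couples patients through risk sets, all
samples form one batch and the model takes one update per epoch
(mini-batching is available via `batchSize` but off by default). Each
epoch: forward pass with a fresh dropout mask, backpropagation, then a
single backtracking line-search step on all parameters jointly with
Armijo constant $10^{-4}$, shrink factor $0.5$ and initial step $1$.
Weights are initialized by a seeded scaled-uniform (Glorot) scheme;
training stops at `maxEpochs` (default 500) or when the relative
improvement of the dropout-free training loss over a 10-epoch window
falls below $10^{-6}$. With no dropout the recorded loss is provably
non-increasing (the line search guarantees sufficient decrease); with
dropout each epoch's line search targets that epoch's masked objective.

Dropout is implemented as inverted unit dropout on hidden activations:
surviving units are rescaled by $1/(1-q)$ during training and nothing is
rescaled at evaluation. A DropConnect-style variant that masks individual
weights instead is exposed as `dropoutMode = "weights"`, since the two
readings of "dropout of network weights" differ; unit dropout is the
default because it is what the standard implementations do. The ReLU
derivative at exactly zero uses subgradient 0 — a measure-zero,
deterministic convention. There is no L1/L2 penalty: dropout is the only
regularizer.

With zero hidden layers the model class collapses to linear Cox
regression, which anchors several oracle tests: on well-specified linear
simulations ($n = 2000$, $p = 10$, 30 % censoring) the trained $\beta$
reaches cosine similarity $\ge 0.95$ with the truth and test concordance
within 0.02 of the true-risk oracle, and the fitted coefficients agree
with an independent partial-likelihood maximizer to numerical precision.

## Harrell's c-index

`concordanceIndex` implements Harrell's statistic with an explicit rule,
because tie handling silently differs between implementations: a pair
with distinct times is permissible iff the earlier patient had the event;
an equal-time pair is permissible only when exactly one member had the
event (that member treated as earlier); equal-time double-event pairs are
excluded. Concordance requires the earlier patient's risk to be strictly
higher; tied risks score 0.5. The vectorized implementation is tested for
exact equality against a naive $O(n^2)$ pair enumeration on random tied
instances, and against the `survival` package's concordance on tie-free
data, where the rules coincide. This rule is a documented package choice,
not an inference about any particular prior implementation.

## Bayesian design optimization

The searched space is exactly four hyperparameters: layers 1–5, width
10–1000 (log scale), dropout 0–0.9, activation ReLU/tanh. Training
details (optimizer, line-search constants) are not searched. The search
is sequential model-based: 5 Latin-hypercube designs to start, then a
Gaussian-process surrogate with a squared-exponential kernel and
per-dimension (ARD) length-scales fitted by marginal likelihood from a
deterministic start, and expected improvement maximized over a seeded
candidate pool. The pool mixes 1000 uniform draws, local perturbations of
the incumbent at three scales, and axis-aligned moves that re-draw one
coordinate — the local candidates let EI fine-tune a near-optimal design,
and ARD flattens irrelevant coordinates (with one activation or a
degenerate range a coordinate simply stops mattering). Integer
coordinates are relaxed to continuous and rounded on decoding; already
evaluated designs are excluded from the pool.

The default budget is 30 evaluations. A design whose training throws an
error is recorded with score 0 (with a warning) and the search continues:
a single pathological configuration must not abort an optimization run.
Everything — initial design, candidates, GP fit — is deterministic for a
fixed seed. A regression test checks that at budget 15 on a smooth toy
objective the search beats the median best of equal-budget space-filling
random draws and lands within 0.05 of the optimum of a 50 × 10 reference
grid (an absolute band, since the toy optimum is within rounding of
zero).

After the search, `refitBest` retrains the winning design from a fresh
seeded initialization on the combined training and validation rows; the
held-out test set only ever scores that refit model.

## The evaluation protocol

`repeatedHoldout` repeats the full pipeline over randomizations: split
60/20/20 (sizes `round(0.6 n)`, `round(0.2 n)`, remainder to test —
base-R rounding, remainder policy a package choice), optimize on
train/validation, refit on train + validation, score on test. Repeat $r$
uses split seed `baseSeed + r`, so the 20 default randomizations are
distinct but reproducible. The summary statistic is the median test
c-index, which is robust to the occasional unlucky assignment.

## The simulator

`simulateSurvival` emulates the statistical shape of multi-platform
cancer cohorts at desk scale: a few hundred to a few thousand patients,
standard-normal features, 30–90 % right-censoring. Event times follow a
Weibull proportional-hazards model (exponential by default, so the
partial likelihood is exactly well-specified for recovery tests) with
rate `baselineRate * exp(risk)`. Censoring times are exponential with a
rate calibrated by bisection so that the expected censored fraction —
estimated as $E[1 - e^{-c T}]$ over a pilot sample of 10,000 event times
drawn from the same mechanism — matches the target; this empirical route
also works for nonlinear risks, and monotonicity of the censored fraction
in the rate (asserted on the bracket) is what makes bisection valid.
Observed censored fractions land within ±0.02 of the target at $n =
5000$.

Defaults are chosen once to be realistic rather than convenient: the
stock linear coefficients (`defaultLinearBeta`) alternate in sign and are
scaled so the true log-hazard has standard deviation 1.5, putting the
oracle c-index near 0.77–0.82 under 30 % censoring — the discrimination
seen in well-powered genomic cohorts; censoring targets of 0.3–0.9 cover
the range from nearly complete follow-up to the heavy censoring typical
of breast-cancer registries. The nonlinear surfaces (`quadratic`, `xor`,
`interaction`) are deterministic functions of at most the first four
features for which any linear score has chance-level population
concordance, so they isolate exactly the payoff of hidden layers: an
$H \ge 1$ tanh network beats the linear model by at least 0.10 test
c-index on the quadratic design ($n = 2000$, $p = 4$). What the simulator
does **not** emulate: correlated gene-expression blocks, heavy-tailed
count distributions, batch effects, or informative censoring — passing
tests demonstrate correctness of the machinery, not performance on real
cohorts.

## Preprocessing and merging

* Categorical columns expand to one indicator per observed level
  (`col=level`); a single-level column is dropped with a warning. A
  missing categorical value propagates `NA` to its indicators for
  downstream imputation.
* Designated binary clinical columns are mean-imputed, so the fill value
  is the observed prevalence — the prior likelihood of the positive
  class.
* 1-NN imputation drops features missing in $\ge 20\,\%$ of patients
  (the boundary is dropped: strictly-below is imputed) and fills each
  remaining hole from the nearest patient by Euclidean distance over
  mutually observed features, falling back to the column mean when no
  donor shares an observed feature. Observed cells are never altered.
* Standardization uses the population standard deviation (divisor $n$)
  and drops zero-variance columns. By default statistics are computed on
  the full dataset before splitting — the simplest protocol and the
  package default; the stored center/scale record plus
  `applyStandardization` support the stricter train-only mode, computing
  statistics on the training rows and reusing them on validation and
  test. Neither mode leaks outcome information; the difference on
  evaluation is negligible at these sample sizes but both are provided
  because the choice is genuinely open.
* Event indicators accept 0/1, TRUE/FALSE and dead/alive
  (case-insensitive); anything else is an error rather than a guess.
* Merging multi-cohort data intersects feature names after an optional
  alias map (the shipped default unifies pathologic and clinical stage as
  `stage`), concatenates rows, and keeps the cohort of origin as a
  provenance column outside the feature matrix. No re-normalization is
  applied at merge time, so cohort-specific scale differences are the
  caller's responsibility.

## Interpretation

Risk backpropagation evaluates, per patient, the gradient of predicted
risk with respect to each input:
$\partial R/\partial f = \beta \prod_{h=1}^{H} J_h$ with $J_h$ the
Jacobian of hidden layer $h$ at that patient's activations, computed by
the same backward pass as training with a unit seed vector and dropout
off. With $H = 0$ every patient's score vector is exactly $\beta$; with
hidden layers the scores vary across patients — the fitted risk surface
is nonlinear, and its local slope is patient-specific (on quadratic
simulations the per-patient score for $x_1$ tracks $2 x_1$, changing
sign across the cohort).

Cohort-level ranking takes each feature's median signed score and orders
by its absolute value, displaying the sign (positive = risk-increasing,
negative = protective). The alternative — median of absolute scores — is
available as `statistic = "medianAbsolute"`; the two differ exactly when
per-patient gradients change sign, and both phrasings are defensible, so
both are exposed and the signed-median variant is the documented default.
Ties order alphabetically. Scores live in the model's input space
(standardized units); passing the stored scale record rescales them per
original unit. The ranked list exports to the standard two-column,
header-less, tab-separated preranked format for gene-set enrichment
tools.

The model used for interpretation follows the repeated-holdout protocol:
the design of the best test-scoring repeat is retrained on *all* samples
(`interpretationModel`), since at interpretation time there is no need to
hold anything out.

## Problem sizes and runtime choices

The test suite and acceptance checks run the full pipeline at sizes
chosen to exercise every code path in minutes on one CPU: oracle checks
at $n \le 50$, recovery and nonlinearity checks at $n = 2000$, and the
20-repeat protocol replica at $n = 1000$, $p = 10$ with a reduced design
space (1–2 layers, width 10–64, dropout ≤ 0.5) and budget 8 — a
scaled-down stand-in whose median test c-index exceeds 0.70 against a
true-risk oracle near 0.82. These sizes are package choices for a
desk-scale demonstration; the defaults (`budget = 30`, the full space)
are what production runs should use.

## Known limitations

* Full-batch training scales linearly in $n \times$ width; very wide
  networks on tens of thousands of features want GPU training, which is
  out of scope.
* Breslow tie handling only; no Efron correction, no time-varying
  covariates, no competing risks.
* The GP surrogate treats the discrete coordinates as rounded continuous
  ones; for spaces dominated by categorical choices a tree-based
  surrogate would fit better.
* 1-NN imputation is quadratic in patients on its missing cells — fine
  for cohorts of thousands, not for biobank scale.
* The simulator's independence assumptions (i.i.d. features, independent
  exponential censoring) make it an oracle for correctness, not a
  benchmark of real-data performance.
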