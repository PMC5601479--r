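# DeepCox

Deep survival networks for right-censored time-to-event data: feed-forward
neural networks whose output layer is a Cox proportional-hazards model, so
the whole network is trained by backpropagating the Cox partial log
likelihood. The package is aimed at biostatisticians and computational
biologists who want to model patient survival from high-dimensional
molecular and clinical feature tables (expression, mutations, copy number,
clinical covariates) without hand-selecting features, and who need the
model design chosen automatically and the fitted model to remain
interpretable.

## The model

Hidden layers apply affine transforms followed by ReLU or tanh
activations; the output layer produces a linear risk score `X_i β` (no
exponential — the network predicts log-relative risk). Training minimizes
the negative log partial likelihood

    l(β, X) = − Σ_{i∈U} ( X_i β − log Σ_{j∈R_i} exp(X_j β) )

where `U` is the set of uncensored patients and `R_i = { j : Y_j ≥ Y_i }`
is the risk set at patient *i*'s time (Breslow convention for ties). Its
derivative with respect to each sample's score,

    ∂l/∂s_i = −c_i + exp(s_i) Σ_{j∈U, i∈R_j} 1 / Σ_{k∈R_j} exp(s_k),

is backpropagated through the layers; optimization is full-batch gradient
descent with a backtracking (Armijo) line search, and dropout provides
regularization. Because the partial likelihood couples samples through
their risk sets, all samples form a single batch and the model updates
once per epoch.

Around this core the package provides:

- **Bayesian design optimization** — a Gaussian-process surrogate with
  expected-improvement acquisition searches layers (1–5), width (10–1000),
  dropout (0–0.9) and activation (ReLU/tanh) against validation
  concordance (`optimizeHyperparameters`, `refitBest`).
- **Evaluation** — Harrell's c-index with an explicitly documented
  tie/permissibility rule (`concordanceIndex`) and the randomized 60/20/20
  holdout protocol repeated over seeds (`repeatedHoldout`).
- **Interpretation by risk backpropagation** — per-patient gradients of
  predicted risk with respect to each input feature
  (`featureRiskScores`), cohort-level ranking by median score
  (`rankFeatures`), and export of a preranked `.rnk` list for gene-set
  enrichment tools (`exportPreranked`).
- **Data handling** — delimited-table I/O, one-hot expansion of
  categorical columns, mean and 1-NN imputation, standardization with
  reusable train statistics, and multi-cohort merging on shared features
  for transfer learning (`mergeDatasets`).
- **A calibrated simulator** — proportional-hazards data with known
  linear or nonlinear log-hazard and censoring calibrated by bisection to
  a target fraction (`simulateSurvival`), so every stage is testable end
  to end.

## Worked example

Simulate a 600-patient cohort with 10 standardized features, a linear
log-hazard and ~60 % censoring; optimize a small design space; refit and
score on held-out patients; then interpret the model:

```r
library(DeepCox)

sim <- simulateSurvival(simulationSpec(n = 600, p = 10,
                                       beta = defaultLinearBeta(10),
                                       censoringTarget = 0.6, seed = 7))
ds <- standardizeFeatures(sim$dataset)
ds
#> SurvivalDataset: 600 patients x 10 features
#>   events: 245 observed, 355 censored (59.2% censored)

sp <- splitTrainValTest(ds, seed = 7)
sp
#> SplitAssignment (seed 7): 360 train / 120 val / 120 test

space <- hyperparameterSpace(layers = c(1, 2), width = c(10, 64))
trace <- optimizeHyperparameters(ds[, sp@train], ds[, sp@val], space,
                                 budget = 8, seed = 7,
                                 control = list(maxEpochs = 100))
trace
#> OptimizationTrace: 8 evaluations (seed 7)
#>   best: 2 layer(s) x 15, dropout 0.113, relu -> score 0.8755

model <- refitBest(ds[, sort(c(sp@train, sp@val))], trace)
test <- ds[, sp@test]
concordanceIndex(predictRisk(model, test), survTimes(test), survEvents(test))
#> c-index 0.6397  (1896 concordant of 2964 permissible pairs)

head(rankFeatures(featureRiskScores(model, ds)), 3)
#>   feature median_score rank
#> 1      x8   -0.5253533    1
#> 2     x10   -0.3391858    2
#> 3      x1    0.3263603    3
```

The trace's best design scored 0.876 on its own validation split; on the
independent test patients the refit model reaches a c-index of 0.64 (1 =
perfect concordance, 0.5 = chance — heavier censoring makes ranking
harder). The ranked table reads per standardized unit: `x8`'s negative
median risk gradient marks it protective, `x1`'s positive one
risk-increasing, matching the signs of the simulation's true
coefficients.

A command-line wrapper over the same functions is installed at
`system.file("cli", "deepcox.R", package = "DeepCox")` with subcommands
`simulate`, `preprocess`, `split`, `merge`, `train`, `optimize`,
`evaluate` and `interpret`; every artifact is written next to a manifest
recording options and seeds.

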