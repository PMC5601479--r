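test_that("a linear model's risk scores equal beta for every patient", {
  ds <- toyDataset(15, 4, seed = 61)
  m <- trainDeepCox(ds, networkConfig(nHiddenLayers = 0, maxEpochs = 30))
  S <- riskScores(featureRiskScores(m, ds))
  expect_equal(dim(S), c(15, 4))
  for (i in 1:15) expect_equal(unname(S[i, ]), unname(m@beta))
})

test_that("affine layers compose to the closed-form W1 W2 beta product", {
  # ReLU behaves as the identity on a region where pre-activations stay
  # positive: positive weights, large positive biases, positive inputs
  set.seed(62)
  W1 <- matrix(runif(3 * 4, 0.1, 0.5), 3, 4)
  W2 <- matrix(runif(4 * 2, 0.1, 0.5), 4, 2)
  m <- new("DeepCoxModel", weights = list(W1, W2),
           biases = list(rep(5, 4), rep(5, 2)), beta = c(0.7, -0.2),
           activation = "relu", dropoutFrac = 0,
           featureNames = c("a", "b", "c"), trainingLog = numeric(0),
           config = list())
  X <- matrix(runif(5 * 3, 0.1, 1), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  S <- riskScores(featureRiskScores(m, X))
  expected <- as.numeric(W1 %*% W2 %*% c(0.7, -0.2))
  for (i in 1:5) expect_equal(unname(S[i, ]), expected)
})

test_that("analytic scores match finite differences for deep nets", {
  for (H in c(1, 3)) for (act in c("relu", "tanh")) {
    ds <- toyDataset(8, 4, seed = 63 + H)
    m <- trainDeepCox(ds, networkConfig(nHiddenLayers = H, layerWidth = 6,
                                        activation = act, maxEpochs = 8,
                                        initSeed = H))
    X <- featureMatrix(ds)
    S <- riskScores(featureRiskScores(m, ds))
    for (i in c(1, 5)) {
      fd <- fdGradient(function(x) {
        Xi <- X
        Xi[i, ] <- x
        predictRisk(m, Xi)[i]
      }, X[i, ])
      expect_lt(max(abs(S[i, ] - fd)) / max(abs(fd), 1e-8), 1e-6)
    }
  }
})

test_that("feature ranking orders by |median| with signs retained", {
  S <- rbind(c(0.8, -0.9, 0.1), c(0.8, -0.9, 0.1), c(0.8, -0.9, 0.1))
  colnames(S) <- c("up", "down", "weak")
  rsm <- new("RiskScoreMatrix", scores = S, modelConfig = list())
  tab <- rankFeatures(rsm)
  expect_equal(tab$feature, c("down", "up", "weak"))
  expect_equal(tab$median_score, c(-0.9, 0.8, 0.1))
  expect_equal(tab$rank, 1:3)
})

test_that("single-patient medians and all-tied name ordering are deterministic", {
  S1 <- matrix(c(0.3, -0.2), 1, 2, dimnames = list("p", c("b", "a")))
  rsm1 <- new("RiskScoreMatrix", scores = S1, modelConfig = list())
  expect_equal(rankFeatures(rsm1)$median_score, c(0.3, -0.2))
  S0 <- matrix(0, 2, 3, dimnames = list(NULL, c("c", "a", "b")))
  rsm0 <- new("RiskScoreMatrix", scores = S0, modelConfig = list())
  expect_equal(rankFeatures(rsm0)$feature, c("a", "b", "c"))
})

test_that("the absolute-median variant and unit rescaling are available", {
  S <- rbind(c(1, -2), c(-1, 2), c(1, -2))
  colnames(S) <- c("sym", "big")
  rsm <- new("RiskScoreMatrix", scores = S, modelConfig = list())
  signed <- rankFeatures(rsm, "medianSigned")
  absolute <- rankFeatures(rsm, "medianAbsolute")
  expect_equal(signed$median_score[signed$feature == "sym"], 1)
  expect_equal(absolute$median_score[absolute$feature == "sym"], 1)
  scaled <- rankFeatures(rsm, scale = c(sym = 2, big = 1))
  expect_equal(scaled$median_score[scaled$feature == "sym"], 0.5)
})

test_that("preranked export writes a sorted, header-less two-column file", {
  tab <- data.frame(feature = c("a", "b", "c"),
                    median_score = c(1.0, -0.5, 0.2), rank = 1:3)
  path <- tempfile(fileext = ".rnk")
  exportPreranked(tab, path)
  lines <- readLines(path)
  expect_equal(length(lines), 3)
  parsed <- read.table(path, sep = "\t", header = FALSE)
  expect_equal(parsed$V1, c("a", "c", "b"))      # descending signed score
  expect_equal(parsed$V2, c(1.0, 0.2, -0.5))
  dup <- data.frame(feature = c("a", "a"), median_score = c(1, 2))
  expect_error(exportPreranked(dup, path), "duplicate")
})

test_that("linear simulations recover the true coefficient ranking", {
  sim <- simulateSurvival(simulationSpec(2000, 10,
                                         beta = c(2, -1.5, 1, -0.8, 0.6,
                                                  -0.4, 0.3, -0.2, 0.1, 0),
                                         censoringTarget = 0.3, seed = 71))
  ds <- standardizeFeatures(sim$dataset)
  m <- trainDeepCox(ds, networkConfig(nHiddenLayers = 0, maxEpochs = 200))
  tab <- rankFeatures(featureRiskScores(m, ds))
  medians <- tab$median_score[match(paste0("x", 1:10), tab$feature)]
  expect_gt(cor(abs(medians), abs(metadata(sim$dataset)$simulation$beta),
                method = "spearman"), 0.9)
})

test_that("quadratic surfaces give patient-dependent gradients tracking 2 x1", {
  sim <- simulateSurvival(simulationSpec(800, 4,
                                         riskFunction = makeNonlinearRisk("quadratic"),
                                         censoringTarget = 0.3, seed = 72))
  ds <- sim$dataset
  m <- trainDeepCox(ds, networkConfig(nHiddenLayers = 2, layerWidth = 16,
                                      activation = "tanh", maxEpochs = 150,
                                      initSeed = 4))
  S <- riskScores(featureRiskScores(m, ds))
  x1 <- featureMatrix(ds)[, "x1"]
  expect_gt(cor(S[, "x1"], 2 * x1), 0.7)
  expect_gt(sd(S[, "x1"]), 0.1)  # gradients genuinely vary across patients
})

test_that("the interpretation model retrains the best repeat's design on all rows", {
  results <- data.frame(rep = 1:3, seed = 1:3,
                        layers = c(1L, 0L, 2L), width = c(16L, 10L, 12L),
                        dropout = c(0, 0, 0.2),
                        activation = c("tanh", "relu", "tanh"),
                        valC = c(0.6, 0.8, 0.7), testC = c(0.6, 0.8, 0.7))
  ds <- toyDataset(30, 3, seed = 73)
  m <- interpretationModel(ds, results, maxEpochs = 10)
  expect_equal(length(m@weights), 0)           # repeat 2's linear design
  expect_error(interpretationModel(ds, results[0, ]), "no holdout results")
  single <- interpretationModel(ds, results[1, , drop = FALSE],
                                maxEpochs = 5)
  expect_equal(length(single@weights), 1)
  ci <- concordanceIndex(predictRisk(m, ds), survTimes(ds), survEvents(ds))
  expect_gte(ci$cIndex, 0.5)
})
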