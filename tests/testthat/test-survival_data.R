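test_that("a delimited table parses into an aligned dataset", {
  path <- writeToyTable(data.frame(time = c(1, 2, 3, 4),
                                   event = c(1, 0, 1, 0),
                                   f1 = c(0.1, 0.2, 0.3, 0.4),
                                   f2 = c(1, 1, 0, 0)))
  ds <- readSurvivalTable(path)
  expect_s4_class(ds, "SurvivalDataset")
  expect_equal(ncol(featureMatrix(ds)), 2)
  expect_equal(length(survTimes(ds)), 4)
  expect_equal(unname(survEvents(ds)), c(1, 0, 1, 0))
  expect_equal(unname(featureKinds(ds)), rep("numeric", 2))
})

test_that("event and time validation rejects malformed tables", {
  bad_event <- writeToyTable(data.frame(time = 1:4, event = c(0, 1, 2, 1),
                                        f1 = rnorm(4)))
  expect_error(readSurvivalTable(bad_event), "0/1")
  neg_time <- writeToyTable(data.frame(time = c(1, -2, 3, 4),
                                       event = c(1, 0, 1, 0),
                                       f1 = rnorm(4)))
  expect_error(readSurvivalTable(neg_time), "egative")
  no_col <- writeToyTable(data.frame(t = 1:4, event = c(1, 0, 1, 0)))
  expect_error(readSurvivalTable(no_col), "missing required column")
})

test_that("event indicators accept the documented alternative codings", {
  path <- writeToyTable(data.frame(time = 1:4,
                                   event = c("dead", "Alive", "TRUE", "false"),
                                   f1 = rnorm(4)))
  expect_equal(unname(survEvents(readSurvivalTable(path))), c(1, 0, 1, 0))
})

test_that("categorical columns are flagged at load and one-hot expanded", {
  path <- writeToyTable(data.frame(time = 1:5, event = c(1, 0, 1, 1, 0),
                                   grade = c("II", "III", "IV", "II", "III"),
                                   age = c(50, 60, 70, 55, 65)))
  ds <- readSurvivalTable(path)
  expect_equal(ncol(featureMatrix(ds)), 1)  # only the numeric column so far
  ex <- expandCategorical(ds)
  X <- featureMatrix(ex)
  ind <- X[, c("grade=II", "grade=III", "grade=IV")]
  expect_equal(unname(rowSums(ind)), rep(1, 5))
  expect_equal(unname(featureKinds(ex)[colnames(ind)]),
               rep("binary-expanded", 3))
})

test_that("expansion drops single-level columns and counts indicators", {
  ds <- SurvivalDataset(matrix(rnorm(6), 6, 1, dimnames = list(NULL, "a")),
                        times = 1:6, events = rep(1, 6),
                        categorical = data.frame(
                          u = c("x", "x", "y", "y", "x", "y"),
                          v = c("p", "q", "r", "p", "q", "r"),
                          w = rep("only", 6)))
  expect_warning(ex <- expandCategorical(ds), "single observed level")
  # 2 + 3 indicator columns replace the two informative categoricals
  expect_equal(ncol(featureMatrix(ex)), 1 + 5)
})

test_that("mean imputation fills with the observed mean", {
  X <- cbind(b = c(1, 0, 1, NA), c = c(2, 2, 2, 2))
  ds <- SurvivalDataset(X, times = 1:4, events = c(1, 1, 0, 1))
  imp <- imputeMean(ds, "b")
  expect_equal(featureMatrix(imp)[4, "b"], 2 / 3)
  # untouched column identical
  expect_identical(featureMatrix(imp)[, "c"], featureMatrix(ds)[, "c"])
  expect_identical(featureMatrix(imputeMean(ds, "c")), featureMatrix(ds))
  all_missing <- SurvivalDataset(cbind(b = c(NA, NA, NA), c = 1:3),
                                 times = 1:3, events = c(1, 1, 1))
  expect_error(imputeMean(all_missing, "b"), "entirely missing")
  expect_error(imputeMean(ds, "nope"), "unknown feature")
})

test_that("1-NN imputation fills from the nearest patient and drops sparse features", {
  X <- cbind(a = c(0, 0.1, 5, 10), b = c(1, NA, 3, 4),
             sparse = c(NA, NA, NA, 4))  # 75% missing -> dropped
  ds <- SurvivalDataset(X, times = 1:4, events = rep(1, 4))
  expect_warning(imp <- imputeKNN(ds, maxMissingFrac = 0.5), "dropping")
  Xi <- featureMatrix(imp)
  expect_false("sparse" %in% colnames(Xi))
  # patient 2's nearest neighbour in 'a' is patient 1 -> b <- 1
  expect_equal(Xi[2, "b"], 1)
  # observed cells never altered
  expect_identical(unname(Xi[-2, "b"]), unname(X[-2, "b"]))
  expect_identical(unname(Xi[, "a"]), unname(X[, "a"]))
})

test_that("the missingness cutoff is 'at or above the threshold is dropped'", {
  n <- 20
  X <- cbind(full = rnorm(n),
             at = replace(rnorm(n), 1:4, NA),     # exactly 20% missing
             under = replace(rnorm(n), 1:3, NA))  # 15% missing
  ds <- SurvivalDataset(X, times = 1:n, events = rep(1, n))
  expect_warning(imp <- imputeKNN(ds, maxMissingFrac = 0.20), "at")
  expect_equal(colnames(featureMatrix(imp)), c("full", "under"))
  expect_false(anyNA(featureMatrix(imp)))
})

test_that("1-NN imputation on complete data is the identity", {
  ds <- toyDataset(15, 4, seed = 5)
  expect_identical(featureMatrix(imputeKNN(ds)), featureMatrix(ds))
})

test_that("standardization gives zero-mean unit-sd columns (divisor n)", {
  ds <- SurvivalDataset(cbind(x = c(1, 2, 3), const = c(5, 5, 5)),
                        times = 1:3, events = c(1, 1, 1))
  expect_warning(st <- standardizeFeatures(ds), "zero-variance")
  expect_equal(unname(featureMatrix(st)[, "x"]),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_false("const" %in% colnames(featureMatrix(st)))
  rec <- standardizationRecord(st)
  expect_equal(unname(rec$center), 2)
  expect_equal(unname(rec$scale), sqrt(2 / 3))
})

test_that("standardization is idempotent and records reapply to new data", {
  ds <- toyDataset(30, 4, seed = 2)
  s1 <- standardizeFeatures(ds)
  s2 <- standardizeFeatures(s1)
  expect_lt(max(abs(featureMatrix(s1) - featureMatrix(s2))), 1e-10)
  # train-statistics reapplied to the same rows reproduce the transform
  re <- applyStandardization(ds, standardizationRecord(s1))
  expect_equal(featureMatrix(re), featureMatrix(s1))
})

test_that("60/20/20 splits have exact sizes and partition the patients", {
  for (n in c(10, 100, 1000)) {
    sp <- splitTrainValTest(n, seed = 3)
    expect_equal(length(sp@train), round(0.6 * n))
    expect_equal(length(sp@val), round(0.2 * n))
    expect_equal(length(sp@test), n - round(0.6 * n) - round(0.2 * n))
    expect_setequal(c(sp@train, sp@val, sp@test), seq_len(n))
  }
  set.seed(99)
  for (k in 1:20) {  # property: disjoint cover for random n and seeds
    n <- sample(5:500, 1)
    sp <- splitTrainValTest(n, seed = sample.int(1e6, 1))
    expect_identical(sort(c(sp@train, sp@val, sp@test)), seq_len(n))
  }
})

test_that("splits are deterministic in the seed and need n >= 5", {
  ds <- toyDataset(10)
  a <- splitTrainValTest(ds, 7)
  b <- splitTrainValTest(ds, 7)
  expect_identical(a@train, b@train)
  expect_identical(a@test, b@test)
  expect_false(identical(splitTrainValTest(ds, 8)@train, a@train))
  expect_error(splitTrainValTest(4, 1), "at least 5")
})

test_that("merging keeps shared features, provenance, and outcome alignment", {
  d1 <- SurvivalDataset(cbind(a = 1:3, b = 4:6, c = 7:9), times = 1:3,
                        events = c(1, 0, 1), patientIds = c("p1", "p2", "p3"))
  d2 <- SurvivalDataset(cbind(b = c(1, 2), c = c(3, 4), d = c(5, 6)),
                        times = c(9, 10), events = c(1, 1),
                        patientIds = c("q1", "q2"))
  m <- mergeDatasets(list(A = d1, B = d2))
  expect_equal(ncol(m), 5)
  expect_setequal(colnames(featureMatrix(m)), c("b", "c"))
  expect_equal(unname(SummarizedExperiment::colData(m)$origin),
               c("A", "A", "A", "B", "B"))
  # no re-normalization: values carried over verbatim
  expect_equal(unname(featureMatrix(m)["q2", "b"]), 2)
})

test_that("merge is order-insensitive up to row permutation", {
  d1 <- toyDataset(8, 3, seed = 11)
  raw <- toyDataset(6, 3, seed = 12)
  d2 <- SurvivalDataset(featureMatrix(raw), survTimes(raw),
                        survEvents(raw), paste0("Q", 1:6))
  m12 <- mergeDatasets(list(d1, d2))
  m21 <- mergeDatasets(list(d2, d1))
  ord <- match(patientIds(m12), patientIds(m21))
  expect_false(anyNA(ord))
  expect_equal(featureMatrix(m21)[ord, colnames(featureMatrix(m12))],
               featureMatrix(m12))
  expect_equal(unname(survTimes(m21))[ord], unname(survTimes(m12)))
})

test_that("stage aliases unify names before the intersection", {
  d1 <- SurvivalDataset(cbind(pathologic_stage = 1:3, a = 4:6),
                        times = 1:3, events = rep(1, 3),
                        patientIds = paste0("x", 1:3))
  d2 <- SurvivalDataset(cbind(clinical_stage = c(2, 3), a = c(1, 2)),
                        times = 4:5, events = c(1, 0),
                        patientIds = paste0("y", 1:2))
  m <- mergeDatasets(list(d1, d2), aliases = stageAliases())
  expect_true("stage" %in% colnames(featureMatrix(m)))
})

test_that("merge rejects disjoint features and duplicate ids", {
  d1 <- SurvivalDataset(cbind(a = 1:3), times = 1:3, events = rep(1, 3),
                        patientIds = paste0("p", 1:3))
  d2 <- SurvivalDataset(cbind(b = 1:3), times = 1:3, events = rep(1, 3),
                        patientIds = paste0("q", 1:3))
  expect_error(mergeDatasets(list(d1, d2)), "share no features")
  d3 <- SurvivalDataset(cbind(a = 1:3), times = 1:3, events = rep(1, 3),
                        patientIds = paste0("p", 1:3))
  expect_error(mergeDatasets(list(d1, d3)), "duplicate patient ids")
  expect_error(mergeDatasets(list(d1)), "at least two")
})

test_that("duplicate patient ids within one dataset are rejected", {
  expect_error(SurvivalDataset(cbind(a = 1:3), times = 1:3,
                               events = rep(1, 3),
                               patientIds = c("p", "p", "q")),
               "unique")
})

test_that("table and split-assignment writers round-trip", {
  ds <- toyDataset(12, 3, seed = 4)
  path <- tempfile(fileext = ".tsv")
  writeSurvivalTable(ds, path)
  back <- readSurvivalTable(path, idCol = "id")
  expect_equal(featureMatrix(back), featureMatrix(ds),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(survTimes(back)), unname(survTimes(ds)),
               tolerance = 1e-12)
  sp <- splitTrainValTest(ds, 5)
  spath <- tempfile(fileext = ".tsv")
  writeSplitAssignment(sp, ds, spath)
  tab <- read.table(spath, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 12)
  expect_equal(sum(tab$split == "train"), round(0.6 * 12))
})
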