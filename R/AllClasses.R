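#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData colData<- rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' SurvivalDataset: right-censored survival data with a feature matrix
#'
#' The central container of the package: a \linkS4class{SummarizedExperiment}
#' whose single \code{"features"} assay holds numeric features (features in
#' rows, patients in columns) and whose \code{colData} carries the survival
#' time (\code{time}, non-negative, any unit) and the event indicator
#' (\code{event}; 1 = death/event observed, 0 = right-censored). Per-feature
#' kind tags (\code{"numeric"}, \code{"binary-expanded"},
#' \code{"clinical-binary"}) live in \code{rowData(x)$kind}. Categorical
#' columns read from disk but not yet expanded to indicators are parked in
#' \code{metadata(x)$categorical} until \code{\link{expandCategorical}} is
#' called; they are not part of the numeric feature matrix.
#'
#' Missing feature values (\code{NA}) are permitted until imputation
#' completes; outcomes must always be complete.
#'
#' @seealso \code{\link{SurvivalDataset}} (constructor),
#'   \code{\link{readSurvivalTable}}, \code{\link{featureMatrix}}
#' @name SurvivalDataset-class
#' @aliases SurvivalDataset-class
#' @exportClass SurvivalDataset
setClass("SurvivalDataset", contains = "SummarizedExperiment")

setValidity("SurvivalDataset", function(object) {
  msg <- character()
  if (!"features" %in% names(assays(object)))
    msg <- c(msg, "assay 'features' is required")
  if (ncol(object) < 2L)
    msg <- c(msg, "a SurvivalDataset needs at least 2 patients")
  cd <- colData(object)
  if (!all(c("time", "event") %in% names(cd))) {
    msg <- c(msg, "colData must contain 'time' and 'event'")
  } else {
    tm <- cd$time
    ev <- cd$event
    if (anyNA(tm) || any(tm < 0))
      msg <- c(msg, "times must be non-negative and non-missing")
    if (anyNA(ev) || !all(ev %in% c(0, 1)))
      msg <- c(msg, "event indicators must be 0 or 1")
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "patient ids must be present and unique")
  if (nrow(object) > 0L &&
      (is.null(rownames(object)) || anyDuplicated(rownames(object))))
    msg <- c(msg, "feature names must be present and unique")
  if (nrow(object) > 0L && !is.numeric(assay(object, "features")))
    msg <- c(msg, "the feature matrix must be numeric")
  if (length(msg)) msg else TRUE
})

#' SplitAssignment: a 60/20/20 train/validation/test partition
#'
#' Disjoint index sets produced by \code{\link{splitTrainValTest}}. Sizes
#' follow the protocol |train| = round(0.6 n), |val| = round(0.2 n),
#' |test| = n - |train| - |val|.
#'
#' @slot train,val,test integer patient indices (disjoint, covering 1..n).
#' @slot seed integer seed the permutation was drawn with.
#' @slot n total number of patients.
#' @name SplitAssignment-class
#' @aliases SplitAssignment-class
#' @exportClass SplitAssignment
setClass("SplitAssignment",
  representation(train = "integer", val = "integer", test = "integer",
                 seed = "integer", n = "integer"))

setValidity("SplitAssignment", function(object) {
  idx <- sort(c(object@train, object@val, object@test))
  if (!identical(idx, seq_len(object@n)))
    return("train/val/test must partition 1..n exactly")
  if (length(object@train) != round(0.6 * object@n) ||
      length(object@val) != round(0.2 * object@n))
    return("split sizes must follow the 60/20/20 rounding rule")
  TRUE
})

#' DeepCoxModel: a feed-forward network with a Cox output layer
#'
#' Hidden layers apply an affine transform followed by a ReLU or tanh
#' activation; the output layer is a linear Cox proportional-hazards score
#' \eqn{X\beta} (no exponential: the model predicts log-relative risk).
#'
#' @slot weights list of hidden-layer weight matrices (input-dim x width).
#' @slot biases list of hidden-layer bias vectors.
#' @slot beta numeric Cox parameter vector of the output layer.
#' @slot activation \code{"relu"} or \code{"tanh"}.
#' @slot dropoutFrac dropout fraction used during training (inactive at
#'   prediction time).
#' @slot featureNames feature names the model was trained on, in order.
#' @slot trainingLog numeric vector of the training loss per epoch,
#'   evaluated without dropout.
#' @slot config list of the full training configuration (see
#'   \code{\link{networkConfig}}).
#' @name DeepCoxModel-class
#' @aliases DeepCoxModel-class
#' @exportClass DeepCoxModel
setClass("DeepCoxModel",
  representation(weights = "list", biases = "list", beta = "numeric",
                 activation = "character", dropoutFrac = "numeric",
                 featureNames = "character", trainingLog = "numeric",
                 config = "list"))

setValidity("DeepCoxModel", function(object) {
  H <- length(object@weights)
  if (length(object@biases) != H)
    return("weights and biases must have one entry per hidden layer")
  dim_in <- length(object@featureNames)
  for (h in seq_len(H)) {
    W <- object@weights[[h]]
    if (nrow(W) != dim_in) return("layer dimensions do not chain")
    if (length(object@biases[[h]]) != ncol(W))
      return("bias length must equal layer width")
    dim_in <- ncol(W)
  }
  if (length(object@beta) != dim_in)
    return("beta length must equal the last hidden width")
  if (!all(is.finite(object@beta))) return("beta must be finite")
  if (!object@activation %in% c("relu", "tanh"))
    return("activation must be 'relu' or 'tanh'")
  TRUE
})

#' OptimizationTrace: history of a Bayesian hyperparameter search
#'
#' One row of \code{evaluations} per trained configuration, in evaluation
#' order, with the validation c-index each achieved.
#'
#' @slot evaluations data.frame with columns \code{eval}, \code{layers},
#'   \code{width}, \code{dropout}, \code{activation}, \code{score},
#'   \code{epochs}.
#' @slot bestConfig list of arguments reproducing the best configuration.
#' @slot bestScore best validation c-index observed.
#' @slot seed integer RNG seed of the search.
#' @name OptimizationTrace-class
#' @aliases OptimizationTrace-class
#' @exportClass OptimizationTrace
setClass("OptimizationTrace",
  representation(evaluations = "data.frame", bestConfig = "list",
                 bestScore = "numeric", seed = "integer"))

setValidity("OptimizationTrace", function(object) {
  ev <- object@evaluations
  if (nrow(ev) > 0 && !isTRUE(all.equal(object@bestScore, max(ev$score))))
    return("bestScore must equal the maximum trace score")
  TRUE
})

#' RiskScoreMatrix: per-patient, per-feature risk gradients
#'
#' Entry (i, f) is the partial derivative of the predicted risk with respect
#' to feature f, evaluated at patient i's feature vector — the risk
#' backpropagation score.
#'
#' @slot scores numeric matrix, patients x features, finite.
#' @slot modelConfig list describing the model the scores came from.
#' @name RiskScoreMatrix-class
#' @aliases RiskScoreMatrix-class
#' @exportClass RiskScoreMatrix
setClass("RiskScoreMatrix",
  representation(scores = "matrix", modelConfig = "list"))

setValidity("RiskScoreMatrix", function(object) {
  if (!all(is.finite(object@scores))) return("risk scores must be finite")
  if (is.null(colnames(object@scores))) return("feature names are required")
  TRUE
})
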