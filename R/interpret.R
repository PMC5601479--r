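#' Risk backpropagation: per-patient feature risk scores
#'
#' Computes, for every patient, the gradient of the predicted (linear) risk
#' with respect to each input feature: the output-layer Cox coefficients
#' composed with the chain of hidden-layer Jacobians evaluated at that
#' patient's activations. Dropout is disabled. For a model with no hidden
#' layers every patient's score vector equals the Cox coefficient vector;
#' with hidden layers the scores vary from patient to patient, tracing the
#' local slope of the nonlinear risk surface.
#'
#' @param model a \linkS4class{DeepCoxModel}.
#' @param ds a \linkS4class{SurvivalDataset} (or feature matrix) aligned by
#'   feature name.
#' @return a \linkS4class{RiskScoreMatrix} (patients x features).
#' @seealso \code{\link{rankFeatures}}, \code{\link{exportPreranked}}
#' @export
featureRiskScores <- function(model, ds) {
  X <- .alignFeatures(model, ds)
  params <- list(W = model@weights, b = model@biases, beta = model@beta)
  cfg <- list(dropoutFrac = 0, dropoutMode = "units",
              activation = model@activation)
  fw <- .forwardPass(params, X, cfg)
  G <- .backwardPass(params, fw, rep(1, nrow(X)), cfg, inputGradient = TRUE)
  dimnames(G) <- list(rownames(X), model@featureNames)
  new("RiskScoreMatrix", scores = G,
      modelConfig = c(model@config,
                      list(nFeatures = length(model@featureNames))))
}

#' @rdname featureRiskScores
#' @param x a \linkS4class{RiskScoreMatrix}.
#' @export
setMethod("riskScores", "RiskScoreMatrix", function(x) x@scores)

setMethod("show", "RiskScoreMatrix", function(object) {
  cat("RiskScoreMatrix:", nrow(object@scores), "patients x",
      ncol(object@scores), "features\n")
  med <- apply(object@scores, 2, stats::median)
  top <- order(-abs(med))[seq_len(min(3, length(med)))]
  cat("  top |median| features:",
      paste(sprintf("%s (%.3g)", colnames(object@scores)[top], med[top]),
            collapse = ", "), "\n")
  invisible(NULL)
})

#' Rank features by their median risk score
#'
#' Cohort-level feature ranking: each feature's per-patient scores are
#' summarized by a median and features are ordered by descending magnitude.
#' The default statistic is the median of the signed scores ranked by its
#' absolute value, so the sign is retained: positive medians read as
#' risk-increasing (poor prognosis), negative as protective.
#' \code{"medianAbsolute"} instead takes the median of the absolute scores.
#' Ties are broken deterministically by feature name.
#'
#' @param rsm a \linkS4class{RiskScoreMatrix}.
#' @param statistic \code{"medianSigned"} (default) or
#'   \code{"medianAbsolute"}.
#' @param scale optional named per-feature scale record (see
#'   \code{\link{standardizeFeatures}}); when given, scores are divided by
#'   it so they read per original feature unit rather than per standardized
#'   unit.
#' @return data.frame with columns \code{feature}, \code{median_score},
#'   \code{rank}, ordered by rank.
#' @export
rankFeatures <- function(rsm, statistic = c("medianSigned", "medianAbsolute"),
                         scale = NULL) {
  statistic <- match.arg(statistic)
  S <- riskScores(rsm)
  if (!is.null(scale)) {
    miss <- setdiff(colnames(S), names(scale))
    if (length(miss))
      stop2("scale record lacks feature(s): ", paste(miss, collapse = ", "))
    S <- sweep(S, 2, scale[colnames(S)], "/")
  }
  med <- if (statistic == "medianSigned") apply(S, 2, stats::median)
         else apply(abs(S), 2, stats::median)
  ord <- order(-abs(med), colnames(S))
  data.frame(feature = colnames(S)[ord], median_score = unname(med[ord]),
             rank = seq_along(med), row.names = NULL)
}

#' Export a preranked feature list
#'
#' Writes the two-column, tab-separated, header-less ranked-list format
#' consumed by preranked gene-set enrichment tools: feature identifier and
#' signed median score, sorted by descending score (not magnitude).
#'
#' @param x a \linkS4class{RiskScoreMatrix} or a ranked table from
#'   \code{\link{rankFeatures}}.
#' @param path output file (conventionally \code{.rnk}).
#' @return the path, invisibly.
#' @export
exportPreranked <- function(x, path) {
  tab <- if (is(x, "RiskScoreMatrix")) rankFeatures(x) else x
  if (anyDuplicated(tab$feature))
    stop2("duplicate feature names in ranked list")
  tab <- tab[order(-tab$median_score, tab$feature), ]
  utils::write.table(tab[, c("feature", "median_score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Retrain the best-performing design on all samples for interpretation
#'
#' Risk backpropagation is applied to a model trained on every available
#' patient: the design is taken from the repeat with the highest test
#' c-index among the randomized holdout results, and a fresh model with
#' that design is trained on the full dataset.
#'
#' @param ds the full \linkS4class{SurvivalDataset}.
#' @param results data.frame from \code{\link{repeatedHoldout}}.
#' @param maxEpochs,initSeed training options for the final fit.
#' @return a \linkS4class{DeepCoxModel} trained on all rows.
#' @export
interpretationModel <- function(ds, results, maxEpochs = 200L,
                                initSeed = 1L) {
  if (is.null(results) || nrow(results) == 0)
    stop2("no holdout results to choose a design from")
  best <- results[which.max(results$testC), ]
  trainDeepCox(ds, networkConfig(nHiddenLayers = best$layers,
                                 layerWidth = best$width,
                                 activation = best$activation,
                                 dropoutFrac = best$dropout,
                                 maxEpochs = maxEpochs,
                                 initSeed = initSeed))
}

#' Write a risk-score matrix as a delimited table
#'
#' @param rsm a \linkS4class{RiskScoreMatrix}.
#' @param path output file.
#' @param delimiter field separator.
#' @export
writeRiskScores <- function(rsm, path, delimiter = "\t") {
  df <- data.frame(id = rownames(riskScores(rsm)),
                   as.data.frame(riskScores(rsm), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
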