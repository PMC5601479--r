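#' Harrell's concordance index
#'
#' Fraction of permissible patient pairs in which the patient with the
#' shorter survival received the higher predicted risk; 0.5 is chance, 1 is
#' perfect concordance. The permissibility rule is Harrell's original one,
#' stated exactly because tie handling varies between implementations:
#' \itemize{
#'   \item a pair with distinct times is permissible iff the earlier
#'     patient's event was observed;
#'   \item a pair with equal times is permissible only when exactly one of
#'     the two had the event, in which case the event patient is treated as
#'     the earlier one;
#'   \item equal-time pairs with two events, and pairs whose earlier member
#'     is censored, are not permissible.
#' }
#' A permissible pair is concordant when the earlier patient's risk is
#' strictly higher; tied risks count 0.5.
#'
#' @param risk predicted risk scores (higher = shorter expected survival).
#' @param times,events survival times and 0/1 event indicators.
#' @return list of class \code{EvaluationResult} with \code{cIndex},
#'   \code{nPairs} (permissible pairs) and \code{nConcordant} (tied risks
#'   counted 0.5).
#' @examples
#' concordanceIndex(c(3, 2, 1), times = c(1, 2, 3), events = c(1, 1, 1))
#' @export
concordanceIndex <- function(risk, times, events) {
  n <- length(risk)
  if (length(times) != n || length(events) != n)
    stop2("risk, times and events must have equal length")
  if (n < 2) stop2("need at least two patients")
  earlier <- outer(times, times, "<")
  tied <- outer(times, times, "==")
  evI <- matrix(events == 1, n, n)
  cnI <- matrix(events == 0, n, n, byrow = TRUE)
  perm <- (earlier & evI) | (tied & evI & cnI)
  nPairs <- sum(perm)
  if (nPairs == 0) stop2("no permissible pairs")
  gt <- outer(risk, risk, ">")
  eq <- outer(risk, risk, "==")
  nConc <- sum(perm & gt) + 0.5 * sum(perm & eq)
  structure(list(cIndex = nConc / nPairs, nPairs = nPairs,
                 nConcordant = nConc),
            class = "EvaluationResult")
}

#' @export
print.EvaluationResult <- function(x, ...) {
  cat(sprintf("c-index %.4f  (%s concordant of %d permissible pairs)\n",
              x$cIndex, format(x$nConcordant), x$nPairs))
  invisible(x)
}

#' Randomized-holdout evaluation protocol
#'
#' For each of \code{nRepeats} randomizations: split the patients 60/20/20
#' (seed \code{baseSeed + r}), run Bayesian hyperparameter optimization on
#' the train/validation pair, refit the best design on train + validation,
#' and score the refit model on the held-out test set with Harrell's
#' c-index. Repeating over randomizations accounts for variation due to
#' sample assignment; the summary statistic is the median test c-index.
#'
#' @param ds a preprocessed \linkS4class{SurvivalDataset}.
#' @param space a \code{\link{hyperparameterSpace}}.
#' @param nRepeats number of randomizations (default 20).
#' @param budget Bayesian-optimization evaluations per randomization.
#' @param baseSeed integer; repeat r uses split seed \code{baseSeed + r}.
#' @param control list of training options forwarded to each trial (see
#'   \code{\link{optimizeHyperparameters}}), e.g. \code{maxEpochs}.
#' @return data.frame with one row per repeat (\code{rep}, \code{seed},
#'   chosen design, \code{valC}, \code{testC}); the median test c-index is
#'   attached as \code{attr(x, "medianTestC")}.
#' @export
repeatedHoldout <- function(ds, space = hyperparameterSpace(),
                            nRepeats = 20L, budget = 30L, baseSeed = 1L,
                            control = list()) {
  if (nRepeats < 1) stop2("nRepeats must be >= 1")
  rows <- vector("list", nRepeats)
  for (r in seq_len(nRepeats)) {
    seed <- baseSeed + r
    sp <- splitTrainValTest(ds, seed)
    trace <- optimizeHyperparameters(ds[, sp@train], ds[, sp@val], space,
                                     budget = budget, seed = seed,
                                     control = control)
    model <- refitBest(ds[, sort(c(sp@train, sp@val))], trace)
    test <- ds[, sp@test]
    cres <- concordanceIndex(predictRisk(model, test), survTimes(test),
                             survEvents(test))
    bc <- trace@bestConfig
    rows[[r]] <- data.frame(rep = r, seed = seed, layers = bc$nHiddenLayers,
                            width = bc$layerWidth, dropout = bc$dropoutFrac,
                            activation = bc$activation,
                            valC = trace@bestScore, testC = cres$cIndex)
  }
  out <- do.call(rbind, rows)
  attr(out, "medianTestC") <- stats::median(out$testC)
  out
}
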