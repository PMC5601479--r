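#' Network training configuration
#'
#' Hyperparameters of a deep survival network and of its full-batch
#' line-search training loop. The Bayesian optimizer searches
#' \code{nHiddenLayers} (1–5), \code{layerWidth} (10–1000),
#' \code{dropoutFrac} (0–0.9) and \code{activation}; the remaining fields
#' are fixed training mechanics. \code{nHiddenLayers = 0} is allowed
#' directly (no hidden layers: the model is exactly linear Cox regression).
#'
#' @param nHiddenLayers number of hidden layers H (>= 0).
#' @param layerWidth units per hidden layer.
#' @param activation \code{"tanh"} or \code{"relu"}.
#' @param dropoutFrac fraction of hidden units dropped per training epoch,
#'   in [0, 0.9]; inverted dropout (surviving activations are rescaled by
#'   1/(1-q)) so no rescaling is needed at evaluation.
#' @param dropoutMode \code{"units"} (standard unit dropout, default) or
#'   \code{"weights"} (DropConnect-style masking of individual weights).
#' @param maxEpochs maximum full-batch epochs.
#' @param initSeed seed for weight initialization and dropout masks.
#' @param lineSearch backtracking parameters: \code{initialStep},
#'   \code{shrink}, \code{sufficientDecrease} (Armijo constant) and
#'   \code{maxShrinks}.
#' @param tol,tolWindow stop when the relative training-loss improvement
#'   over \code{tolWindow} epochs falls below \code{tol}.
#' @param batchSize optional mini-batch size; \code{NULL} (default) trains
#'   on all samples as a single batch, which is the intended mode since the
#'   partial likelihood couples samples through their risk sets.
#' @return a \code{NetworkConfig} list.
#' @export
networkConfig <- function(nHiddenLayers = 1L, layerWidth = 32L,
                          activation = c("tanh", "relu"),
                          dropoutFrac = 0, dropoutMode = c("units", "weights"),
                          maxEpochs = 500L, initSeed = 1L,
                          lineSearch = list(initialStep = 1, shrink = 0.5,
                                            sufficientDecrease = 1e-4,
                                            maxShrinks = 50L),
                          tol = 1e-6, tolWindow = 10L, batchSize = NULL) {
  activation <- match.arg(activation)
  dropoutMode <- match.arg(dropoutMode)
  if (nHiddenLayers < 0) stop2("nHiddenLayers must be >= 0")
  if (nHiddenLayers > 0 && layerWidth < 1) stop2("layerWidth must be >= 1")
  if (dropoutFrac < 0 || dropoutFrac > 0.9)
    stop2("dropoutFrac must lie in [0, 0.9]")
  ls <- utils::modifyList(list(initialStep = 1, shrink = 0.5,
                               sufficientDecrease = 1e-4, maxShrinks = 50L),
                          lineSearch)
  structure(list(nHiddenLayers = as.integer(nHiddenLayers),
                 layerWidth = as.integer(layerWidth),
                 activation = activation, dropoutFrac = dropoutFrac,
                 dropoutMode = dropoutMode,
                 maxEpochs = as.integer(maxEpochs),
                 initSeed = as.integer(initSeed), lineSearch = ls,
                 tol = tol, tolWindow = as.integer(tolWindow),
                 batchSize = batchSize),
            class = "NetworkConfig")
}

.act <- function(Z, activation) {
  if (activation == "tanh") tanh(Z) else pmax(Z, 0)
}

## derivative of the activation w.r.t. its pre-activation input; ReLU uses
## subgradient 0 at exactly 0 (deterministic, measure-zero convention)
.actDeriv <- function(Z, A, activation) {
  if (activation == "tanh") 1 - A * A else (Z > 0) + 0
}

## Scaled-uniform (Glorot) initialization, seeded by the caller's stream.
.initParams <- function(p, config) {
  H <- config$nHiddenLayers
  w <- config$layerWidth
  dims <- c(p, rep(w, H))
  W <- vector("list", H)
  b <- vector("list", H)
  for (h in seq_len(H)) {
    a <- sqrt(6 / (dims[h] + dims[h + 1]))
    W[[h]] <- matrix(stats::runif(dims[h] * dims[h + 1], -a, a),
                     dims[h], dims[h + 1])
    b[[h]] <- numeric(dims[h + 1])
  }
  a <- sqrt(6 / (dims[H + 1] + 1))
  list(W = W, b = b, beta = stats::runif(dims[H + 1], -a, a))
}

## Draw per-epoch dropout masks. For unit dropout: one 0/1 mask per hidden
## layer's activation matrix. For weight dropout (DropConnect): masks the
## hidden weight matrices instead.
.drawMasks <- function(params, n, config) {
  q <- config$dropoutFrac
  if (q <= 0 || config$nHiddenLayers == 0) return(NULL)
  if (config$dropoutMode == "units") {
    lapply(params$W, function(W)
      matrix(stats::rbinom(n * ncol(W), 1, 1 - q), n, ncol(W)))
  } else {
    lapply(params$W, function(W)
      matrix(stats::rbinom(length(W), 1, 1 - q), nrow(W), ncol(W)))
  }
}

## Forward pass. masks = NULL means evaluation mode (no dropout, no
## rescaling). Returns the linear risk scores s = A_H beta (the exponential
## is never applied: the network predicts log-relative risk) plus the
## per-layer pre- and post-activation matrices needed for backpropagation.
.forwardPass <- function(params, X, config, masks = NULL) {
  H <- length(params$W)
  q <- config$dropoutFrac
  A <- vector("list", H + 1)
  Z <- vector("list", H)
  A[[1]] <- X
  for (h in seq_len(H)) {
    W <- params$W[[h]]
    if (!is.null(masks) && config$dropoutMode == "weights")
      W <- W * masks[[h]] / (1 - q)
    Z[[h]] <- sweep(A[[h]] %*% W, 2, params$b[[h]], "+")
    Ah <- .act(Z[[h]], config$activation)
    if (!is.null(masks) && config$dropoutMode == "units")
      Ah <- Ah * masks[[h]] / (1 - q)
    A[[h + 1]] <- Ah
  }
  list(s = as.numeric(A[[H + 1]] %*% params$beta), A = A, Z = Z)
}

## Backpropagate d(loss)/d(risk) through the layers. Returns gradients with
## the same list structure as params. When dRisk is the all-ones vector this
## computes the risk-backpropagation Jacobian product instead (see
## featureRiskScores), in which case gradInput is the matrix of per-patient
## input gradients.
.backwardPass <- function(params, fw, dRisk, config, masks = NULL,
                          inputGradient = FALSE) {
  H <- length(params$W)
  q <- config$dropoutFrac
  gBeta <- as.numeric(crossprod(fw$A[[H + 1]], dRisk))
  G <- tcrossprod(dRisk, params$beta)         # n x width(H)
  gW <- vector("list", H)
  gb <- vector("list", H)
  for (h in rev(seq_len(H))) {
    if (!is.null(masks) && config$dropoutMode == "units")
      G <- G * masks[[h]] / (1 - q)
    preA <- .act(fw$Z[[h]], config$activation)  # pre-dropout activation
    D <- G * .actDeriv(fw$Z[[h]], preA, config$activation)
    gW[[h]] <- crossprod(fw$A[[h]], D)
    gb[[h]] <- colSums(D)
    W <- params$W[[h]]
    if (!is.null(masks) && config$dropoutMode == "weights") {
      gW[[h]] <- gW[[h]] * masks[[h]] / (1 - q)
      W <- W * masks[[h]] / (1 - q)
    }
    G <- tcrossprod(D, W)
  }
  if (inputGradient) return(G)
  list(W = gW, b = gb, beta = gBeta)
}

.paramAxpy <- function(params, grads, alpha) {
  list(W = Map(function(W, g) W - alpha * g, params$W, grads$W),
       b = Map(function(b, g) b - alpha * g, params$b, grads$b),
       beta = params$beta - alpha * grads$beta)
}

.gradNormSq <- function(g) {
  sum(vapply(g$W, function(m) sum(m * m), numeric(1))) +
    sum(vapply(g$b, function(v) sum(v * v), numeric(1))) +
    sum(g$beta * g$beta)
}

#' Train a deep survival network
#'
#' Full-batch training by backpropagation of the Cox partial-likelihood
#' gradient with backtracking (Armijo) line search: each epoch performs one
#' forward pass over all training samples (with a fresh dropout mask), one
#' backward pass, and a single joint line-search step on all parameters.
#' The training loss recorded per epoch is always evaluated without dropout;
#' with \code{dropoutFrac = 0} the line search makes it non-increasing.
#' Training stops at \code{maxEpochs}, when the relative loss improvement
#' over \code{tolWindow} epochs drops below \code{tol}, or (with a warning)
#' when the line search fails to find a decrease.
#'
#' Deterministic for fixed \code{initSeed}: initialization and all dropout
#' masks are drawn from one seeded stream.
#'
#' @param ds training rows as a \linkS4class{SurvivalDataset}; features
#'   should already be standardized and must contain at least one observed
#'   event.
#' @param config a \code{\link{networkConfig}}.
#' @return a \linkS4class{DeepCoxModel}.
#' @examples
#' sim <- simulateSurvival(simulationSpec(120, 4, beta = c(1, -1, 0.5, 0),
#'                                        seed = 3))
#' fit <- trainDeepCox(sim$dataset,
#'                     networkConfig(nHiddenLayers = 0, maxEpochs = 50))
#' head(predictRisk(fit, sim$dataset))
#' @export
trainDeepCox <- function(ds, config = networkConfig()) {
  stopifnot(inherits(config, "NetworkConfig"))
  X <- featureMatrix(ds)
  if (anyNA(X)) stop2("training features contain missing values")
  times <- survTimes(ds)
  events <- survEvents(ds)
  if (!any(events == 1)) stop2("training data contain no observed events")
  n <- nrow(X)
  ls <- config$lineSearch
  batches <- if (is.null(config$batchSize)) list(seq_len(n)) else
    split(seq_len(n), ceiling(seq_len(n) / config$batchSize))

  withSeed(config$initSeed, {
    params <- .initParams(ncol(X), config)
    lossLog <- numeric(0)
    converged <- FALSE
    for (epoch in seq_len(config$maxEpochs)) {
      for (idx in batches) {
        Xb <- X[idx, , drop = FALSE]
        tb <- times[idx]
        eb <- events[idx]
        if (!any(eb == 1)) next
        masks <- .drawMasks(params, length(idx), config)
        fw <- .forwardPass(params, Xb, config, masks)
        f0 <- coxNegLogLik(fw$s, tb, eb)
        dRisk <- coxRiskGradient(fw$s, tb, eb)
        grads <- .backwardPass(params, fw, dRisk, config, masks)
        gn2 <- .gradNormSq(grads)
        if (gn2 == 0) { converged <- TRUE; break }
        alpha <- ls$initialStep
        ok <- FALSE
        for (k in seq_len(ls$maxShrinks)) {
          cand <- .paramAxpy(params, grads, alpha)
          f1 <- coxNegLogLik(.forwardPass(cand, Xb, config, masks)$s, tb, eb)
          if (is.finite(f1) &&
              f1 <= f0 - ls$sufficientDecrease * alpha * gn2) {
            ok <- TRUE
            break
          }
          alpha <- alpha * ls$shrink
        }
        if (!ok) {
          warning("line search failed to find a decrease after ",
                  ls$maxShrinks, " shrinks; stopping at epoch ", epoch)
          converged <- TRUE
          break
        }
        params <- cand
      }
      evalLoss <- coxNegLogLik(.forwardPass(params, X, config)$s,
                               times, events)
      lossLog <- c(lossLog, evalLoss)
      if (converged) break
      w <- config$tolWindow
      if (epoch > w) {
        prev <- lossLog[epoch - w]
        if ((prev - evalLoss) < config$tol * max(abs(prev), 1e-12)) break
      }
    }
    new("DeepCoxModel", weights = lapply(params$W, unname),
        biases = lapply(params$b, unname),
        beta = unname(params$beta), activation = config$activation,
        dropoutFrac = config$dropoutFrac, featureNames = colnames(X),
        trainingLog = lossLog, config = unclass(config))
  })
}

setMethod("show", "DeepCoxModel", function(object) {
  H <- length(object@weights)
  cat(sprintf("DeepCoxModel: %d input feature(s), %d hidden layer(s)%s, %s\n",
              length(object@featureNames), H,
              if (H) sprintf(" of width %d", ncol(object@weights[[1]])) else "",
              object@activation))
  cat(sprintf("  dropout %.2f; trained %d epoch(s); final loss %.4f\n",
              object@dropoutFrac, length(object@trainingLog),
              utils::tail(object@trainingLog, 1)))
  invisible(NULL)
})

## eval-mode forward pass for a fitted model
.modelForward <- function(model, X) {
  params <- list(W = model@weights, b = model@biases, beta = model@beta)
  cfg <- list(dropoutFrac = 0, dropoutMode = "units",
              activation = model@activation)
  .forwardPass(params, X, cfg)
}

## reorder ds features by the model's feature names, erroring on absences
.alignFeatures <- function(model, ds) {
  X <- if (is(ds, "SurvivalDataset")) featureMatrix(ds) else as.matrix(ds)
  miss <- setdiff(model@featureNames, colnames(X))
  if (length(miss))
    stop2("dataset lacks model feature(s): ", paste(miss, collapse = ", "))
  X[, model@featureNames, drop = FALSE]
}

#' Predict risk scores
#'
#' Evaluation-mode forward pass (dropout disabled): returns the linear Cox
#' scores, where a higher value means a higher predicted hazard. Features
#' are matched by name, so column order need not match training; absent
#' features are an error.
#'
#' @param object a \linkS4class{DeepCoxModel}.
#' @param ds a \linkS4class{SurvivalDataset} or a plain feature matrix with
#'   column names.
#' @param ... unused.
#' @return numeric risk vector, one value per patient.
#' @name predictRisk
#' @aliases predictRisk,DeepCoxModel-method
#' @export
setMethod("predictRisk", "DeepCoxModel", function(object, ds, ...) {
  X <- .alignFeatures(object, ds)
  .modelForward(object, X)$s
})

#' Serialize / load a trained model
#'
#' The model is written as a single JSON document: a readable header
#' (configuration, feature names, training log) plus each weight array as a
#' base64-encoded little-endian double blob, so the round trip is bit-exact.
#'
#' @param model a \linkS4class{DeepCoxModel}.
#' @param path file path.
#' @return \code{readDeepCoxModel}: the restored model, identical to the
#'   one written.
#' @export
writeDeepCoxModel <- function(model, path) {
  enc <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                   size = 8,
                                                   endian = "little"))
  doc <- list(
    format = "DeepCoxModel/1",
    activation = model@activation,
    dropoutFrac = model@dropoutFrac,
    featureNames = model@featureNames,
    trainingLog = enc(model@trainingLog),
    config = model@config[setdiff(names(model@config), "lineSearch")],
    lineSearch = model@config$lineSearch,
    dims = lapply(model@weights, dim),
    weights = lapply(model@weights, enc),
    biases = lapply(model@biases, enc),
    beta = enc(model@beta))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname writeDeepCoxModel
#' @export
readDeepCoxModel <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  dec <- function(s) readBin(jsonlite::base64_dec(s), "double",
                             n = 1e7, size = 8, endian = "little")
  H <- length(doc$weights)
  dims <- doc$dims
  if (is.matrix(dims)) dims <- lapply(seq_len(nrow(dims)), function(i) dims[i, ])
  W <- lapply(seq_len(H), function(h)
    matrix(dec(doc$weights[[h]]), dims[[h]][1], dims[[h]][2]))
  b <- lapply(seq_len(H), function(h) dec(doc$biases[[h]]))
  cfg <- doc$config
  cfg$lineSearch <- doc$lineSearch
  new("DeepCoxModel", weights = W, biases = b, beta = dec(doc$beta),
      activation = doc$activation, dropoutFrac = doc$dropoutFrac,
      featureNames = doc$featureNames,
      trainingLog = dec(doc$trainingLog), config = cfg)
}
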