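#' The searchable network design space
#'
#' Defaults are the full space searched by the framework: 1–5 hidden
#' layers, width 10–1000, dropout 0–0.9, ReLU or tanh activation. Narrower
#' sub-ranges (within those bounds) may be supplied for scaled-down runs.
#'
#' @param layers,width integer ranges \code{c(lo, hi)}.
#' @param dropout real range \code{c(lo, hi)}.
#' @param activation subset of \code{c("relu", "tanh")}.
#' @return a \code{HyperparameterSpace} list.
#' @export
hyperparameterSpace <- function(layers = c(1L, 5L), width = c(10L, 1000L),
                                dropout = c(0, 0.9),
                                activation = c("relu", "tanh")) {
  chk <- function(r, lo, hi, nm) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < lo || r[2] > hi)
      stop2(nm, " range must lie within [", lo, ", ", hi, "]")
  }
  chk(layers, 1, 5, "layers")
  chk(width, 10, 1000, "width")
  chk(dropout, 0, 0.9, "dropout")
  if (!length(activation) || !all(activation %in% c("relu", "tanh")))
    stop2("activation must be a subset of {relu, tanh}")
  structure(list(layers = as.integer(layers), width = as.integer(width),
                 dropout = as.numeric(dropout), activation = activation),
            class = "HyperparameterSpace")
}

## Decode a unit-cube point into a concrete design. Width is searched on a
## log10 scale; integer coordinates are relaxed to continuous and rounded;
## the activation is one 0/1 coordinate.
.decodeConfig <- function(u, space) {
  layers <- as.integer(round(space$layers[1] +
                               u[1] * (space$layers[2] - space$layers[1])))
  lw <- log10(space$width)
  width <- as.integer(round(10^(lw[1] + u[2] * (lw[2] - lw[1]))))
  width <- min(max(width, space$width[1]), space$width[2])
  dropout <- space$dropout[1] + u[3] * (space$dropout[2] - space$dropout[1])
  acts <- space$activation
  activation <- if (length(acts) == 1) acts else
    acts[1 + (u[4] >= 0.5)]
  list(nHiddenLayers = layers, layerWidth = width, dropoutFrac = dropout,
       activation = activation)
}

## Re-encode a realized design so the surrogate sees the rounded values it
## was actually evaluated at.
.encodeConfig <- function(cfg, space) {
  lw <- log10(space$width)
  c(if (space$layers[2] > space$layers[1])
      (cfg$nHiddenLayers - space$layers[1]) /
        (space$layers[2] - space$layers[1]) else 0.5,
    if (lw[2] > lw[1])
      (log10(cfg$layerWidth) - lw[1]) / (lw[2] - lw[1]) else 0.5,
    if (space$dropout[2] > space$dropout[1])
      (cfg$dropoutFrac - space$dropout[1]) /
        (space$dropout[2] - space$dropout[1]) else 0.5,
    if (length(space$activation) > 1)
      as.numeric(cfg$activation == space$activation[2]) else 0.5)
}

## --- Gaussian-process surrogate -------------------------------------------
## Squared-exponential kernel on the normalized coordinates, unit signal
## variance on standardized responses. Length-scale and noise are selected
## by marginal likelihood over a small deterministic grid: with at most a
## few dozen observations a full gradient fit buys nothing.
.gpKernel <- function(X1, X2, ell) {
  S1 <- sweep(X1, 2, ell, "/")
  S2 <- sweep(X2, 2, ell, "/")
  d2 <- outer(rowSums(S1^2), rowSums(S2^2), "+") - 2 * tcrossprod(S1, S2)
  exp(-0.5 * pmax(d2, 0))
}

## Marginal-likelihood fit of per-dimension (ARD) length-scales and the
## noise variance, from a deterministic start, so irrelevant design
## coordinates are automatically flattened out of the surrogate.
.gpFit <- function(X, y) {
  mu <- mean(y)
  sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy < 1e-12) sdy <- 1
  ys <- (y - mu) / sdy
  d <- ncol(X)
  negll <- function(theta) {
    ell <- exp(theta[seq_len(d)])
    noise <- exp(theta[d + 1])
    K <- .gpKernel(X, X, ell) + diag(noise, nrow(X))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    0.5 * sum(ys * alpha) + sum(log(diag(ch)))
  }
  opt <- stats::optim(c(rep(log(0.3), d), log(1e-2)), negll,
                      method = "L-BFGS-B",
                      lower = c(rep(log(0.05), d), log(1e-6)),
                      upper = c(rep(log(5), d), log(0.5)))
  ell <- exp(opt$par[seq_len(d)])
  noise <- exp(opt$par[d + 1])
  K <- .gpKernel(X, X, ell) + diag(noise, nrow(X))
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  list(ell = ell, noise = noise, chol = ch, alpha = alpha,
       X = X, mu = mu, sdy = sdy)
}

.gpPredict <- function(fit, Xnew) {
  Ks <- .gpKernel(Xnew, fit$X, fit$ell)
  mean_s <- Ks %*% fit$alpha
  v <- forwardsolve(t(fit$chol), t(Ks))
  var_s <- pmax(1 + fit$noise - colSums(v^2), 1e-12)
  list(mean = fit$mu + fit$sdy * as.numeric(mean_s),
       sd = fit$sdy * sqrt(var_s))
}

.expectedImprovement <- function(mean, sd, best) {
  imp <- mean - best
  z <- imp / sd
  ei <- imp * stats::pnorm(z) + sd * stats::dnorm(z)
  ei[sd < 1e-10] <- pmax(imp[sd < 1e-10], 0)
  ei
}

#' Bayesian optimization of the network design
#'
#' Sequential model-based search over \code{\link{hyperparameterSpace}}:
#' an initial space-filling design of 5 Latin-hypercube configurations is
#' evaluated, then a Gaussian-process surrogate (squared-exponential kernel
#' on normalized coordinates; integers relaxed and rounded; activation as a
#' 0/1 coordinate) is fit to the observed (design, validation c-index)
#' pairs and the next design maximizes expected improvement over 1000
#' seeded candidate draws. Each evaluated design is trained on the training
#' rows and scored by c-index on the validation rows; a design whose
#' training fails scores 0 (with a warning) so one pathological
#' configuration cannot abort the search. Deterministic for a fixed seed.
#'
#' @param train,val \linkS4class{SurvivalDataset}s (training rows must
#'   contain at least one event). Ignored when \code{objective} is given.
#' @param space a \code{\link{hyperparameterSpace}}.
#' @param budget total number of designs to evaluate (>= 3).
#' @param seed integer seed for the initial design and candidate draws.
#' @param objective optional function(config) -> score, replacing the
#'   train-and-validate objective (used for testing the search itself).
#' @param control list of training options for each trial:
#'   \code{maxEpochs} (default 100), \code{tol}, \code{dropoutMode}.
#' @return an \linkS4class{OptimizationTrace}.
#' @export
optimizeHyperparameters <- function(train, val, space = hyperparameterSpace(),
                                    budget = 30L, seed = 1L,
                                    objective = NULL, control = list()) {
  if (budget < 3) stop2("budget must be at least 3")
  if (is.null(objective)) {
    if (!any(survEvents(train) == 1))
      stop2("training data contain no observed events")
    vt <- survTimes(val)
    ve <- survEvents(val)
    objective <- function(cfg) {
      net <- networkConfig(nHiddenLayers = cfg$nHiddenLayers,
                           layerWidth = cfg$layerWidth,
                           activation = cfg$activation,
                           dropoutFrac = cfg$dropoutFrac,
                           dropoutMode = control$dropoutMode %||% "units",
                           maxEpochs = control$maxEpochs %||% 100L,
                           tol = control$tol %||% 1e-6,
                           initSeed = control$initSeed %||% (seed + 104729L))
      model <- trainDeepCox(train, net)
      concordanceIndex(predictRisk(model, val), vt, ve)$cIndex
    }
  }
  nInit <- min(5L, budget)
  withSeed(seed, {
    U <- lhs::randomLHS(nInit, 4)
    evals <- list()
    seen <- character(0)
    evalOne <- function(u) {
      cfg <- .decodeConfig(u, space)
      score <- tryCatch(objective(cfg), error = function(e) {
        warning("design evaluation failed (", conditionMessage(e),
                "); scoring 0")
        0
      })
      evals[[length(evals) + 1L]] <<- c(cfg, list(score = score))
      seen <<- c(seen, paste(cfg$nHiddenLayers, cfg$layerWidth,
                             signif(cfg$dropoutFrac, 6), cfg$activation))
    }
    for (i in seq_len(nInit)) evalOne(U[i, ])
    while (length(evals) < budget) {
      X <- do.call(rbind, lapply(evals, .encodeConfig, space = space))
      y <- vapply(evals, `[[`, numeric(1), "score")
      fit <- .gpFit(X, y)
      ## global uniform candidates plus local perturbations of the
      ## incumbent, so EI can both explore and fine-tune
      incumbent <- X[which.max(y), ]
      local <- do.call(rbind, lapply(c(0.03, 0.1, 0.3), function(sd)
        matrix(stats::rnorm(150 * 4, mean = incumbent, sd = sd),
               150, 4, byrow = TRUE)))
      ## axis-aligned moves from the incumbent: one coordinate re-drawn
      axis <- do.call(rbind, lapply(1:4, function(j) {
        m <- matrix(incumbent, 50, 4, byrow = TRUE)
        m[, j] <- stats::runif(50)
        m
      }))
      cand <- rbind(matrix(stats::runif(1000 * 4), 1000, 4),
                    pmin(pmax(local, 0), 1), axis)
      pr <- .gpPredict(fit, cand)
      ei <- .expectedImprovement(pr$mean, pr$sd, max(y))
      keys <- apply(cand, 1, function(u) {
        cfg <- .decodeConfig(u, space)
        paste(cfg$nHiddenLayers, cfg$layerWidth,
              signif(cfg$dropoutFrac, 6), cfg$activation)
      })
      ei[keys %in% seen] <- -Inf
      pick <- if (all(!is.finite(ei))) cand[1, ] else
        cand[which.max(ei), ]
      evalOne(pick)
    }
    ev <- data.frame(
      eval = seq_along(evals),
      layers = vapply(evals, `[[`, integer(1), "nHiddenLayers"),
      width = vapply(evals, `[[`, integer(1), "layerWidth"),
      dropout = vapply(evals, `[[`, numeric(1), "dropoutFrac"),
      activation = vapply(evals, `[[`, character(1), "activation"),
      score = vapply(evals, `[[`, numeric(1), "score"))
    best <- which.max(ev$score)
    new("OptimizationTrace", evaluations = ev,
        bestConfig = evals[[best]][c("nHiddenLayers", "layerWidth",
                                     "dropoutFrac", "activation")],
        bestScore = ev$score[best], seed = as.integer(seed))
  })
}

#' @rdname optimizeHyperparameters
#' @param x an \linkS4class{OptimizationTrace}.
#' @export
setMethod("bestConfig", "OptimizationTrace", function(x) x@bestConfig)

#' @rdname optimizeHyperparameters
#' @export
setMethod("evaluations", "OptimizationTrace", function(x) x@evaluations)

setMethod("show", "OptimizationTrace", function(object) {
  bc <- object@bestConfig
  cat(sprintf("OptimizationTrace: %d evaluations (seed %d)\n",
              nrow(object@evaluations), object@seed))
  cat(sprintf("  best: %d layer(s) x %d, dropout %.3f, %s -> score %.4f\n",
              bc$nHiddenLayers, bc$layerWidth, bc$dropoutFrac,
              bc$activation, object@bestScore))
  invisible(NULL)
})

#' Refit the best design on training + validation rows
#'
#' After the search finishes, the winning design is retrained from scratch
#' on the combined training and validation samples (a fresh seeded
#' initialization) and that refit model is what the test set scores.
#'
#' @param trainPlusVal combined rows as a \linkS4class{SurvivalDataset}.
#' @param trace an \linkS4class{OptimizationTrace}.
#' @param refitSeed seed for the refit initialization (default: the trace
#'   seed + 1).
#' @param maxEpochs training epochs for the refit.
#' @return a \linkS4class{DeepCoxModel}.
#' @export
refitBest <- function(trainPlusVal, trace, refitSeed = NULL,
                      maxEpochs = NULL) {
  if (nrow(trace@evaluations) == 0) stop2("empty optimization trace")
  bc <- trace@bestConfig
  trainDeepCox(trainPlusVal,
               networkConfig(nHiddenLayers = bc$nHiddenLayers,
                             layerWidth = bc$layerWidth,
                             activation = bc$activation,
                             dropoutFrac = bc$dropoutFrac,
                             maxEpochs = maxEpochs %||% 200L,
                             initSeed = refitSeed %||% (trace@seed + 1L)))
}

#' Write an optimization trace and its best design
#'
#' The trace is written as a tab-separated log (one row per evaluation) and
#' the best design as a JSON configuration file reusable by the command
#' line.
#'
#' @param trace an \linkS4class{OptimizationTrace}.
#' @param tracePath,configPath output files (\code{NULL} to skip either).
#' @export
writeOptimizationTrace <- function(trace, tracePath = NULL,
                                   configPath = NULL) {
  if (!is.null(tracePath))
    utils::write.table(trace@evaluations, tracePath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(configPath))
    writeLines(jsonlite::toJSON(trace@bestConfig, auto_unbox = TRUE,
                                digits = NA), configPath)
  invisible(trace)
}
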