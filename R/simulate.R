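#' Specify a proportional-hazards simulation
#'
#' Describes a right-censored survival simulation with known ground truth:
#' features are i.i.d. standard normal, the true log-hazard is either linear
#' (\code{beta}) or a nonlinear function of the features
#' (\code{riskFunction}, see \code{\link{makeNonlinearRisk}}), event times
#' follow a Weibull proportional-hazards model (exponential by default,
#' \code{shape = 1}) with rate \code{baselineRate * exp(risk)}, and
#' independent exponential censoring is calibrated so the expected censored
#' fraction matches \code{censoringTarget}.
#'
#' @param n number of patients (>= 2).
#' @param p number of features (>= 1).
#' @param beta length-p vector of linear log-hazard coefficients, or
#'   \code{NULL} when \code{riskFunction} is given.
#' @param riskFunction function mapping the n x p feature matrix to a
#'   length-n log-hazard vector.
#' @param baselineRate positive baseline hazard rate (sets the time unit).
#' @param censoringTarget target censored fraction in [0, 1); 0 disables
#'   censoring.
#' @param shape Weibull shape; 1 gives exponential event times.
#' @param seed integer seed.
#' @return a \code{SimulationSpec} list.
#' @export
simulationSpec <- function(n, p, beta = NULL, riskFunction = NULL,
                           baselineRate = 0.1, censoringTarget = 0.3,
                           shape = 1, seed = 1L) {
  if (n < 2) stop2("n must be at least 2")
  if (p < 1) stop2("p must be at least 1")
  if (censoringTarget < 0 || censoringTarget >= 1)
    stop2("censoringTarget must lie in [0, 1)")
  if (baselineRate <= 0) stop2("baselineRate must be positive")
  if (is.null(beta) && is.null(riskFunction))
    stop2("provide beta or riskFunction")
  if (!is.null(beta) && length(beta) != p)
    stop2("beta must have length p")
  structure(list(n = as.integer(n), p = as.integer(p), beta = beta,
                 riskFunction = riskFunction, baselineRate = baselineRate,
                 censoringTarget = censoringTarget, shape = shape,
                 seed = as.integer(seed)),
            class = "SimulationSpec")
}

#' Default linear log-hazard coefficients
#'
#' The stock coefficient pattern for linear simulations: alternating signs,
#' scaled so the true log-hazard has standard deviation \code{sd} over
#' standard-normal features. With the default \code{sd = 1.5} the oracle
#' c-index of the true risk is about 0.77 under 30 percent censoring —
#' comparable to the discrimination seen in well-powered genomic cohorts.
#'
#' @param p number of features.
#' @param sd standard deviation of the resulting log-hazard.
#' @return length-p numeric vector.
#' @export
defaultLinearBeta <- function(p, sd = 1.5) {
  rep(c(1, -1), length.out = p) * sd / sqrt(p)
}

#' Named nonlinear log-hazard functions
#'
#' Deterministic risk surfaces on the first few features for which a linear
#' Cox model is provably suboptimal, used to exercise the payoff of hidden
#' layers:
#' \describe{
#'   \item{quadratic}{\eqn{r(x) = x_1^2 - x_2^2}; uncorrelated with every
#'     linear score, so a linear fit has population c-index ~ 0.5.}
#'   \item{xor}{\eqn{r(x) = sign(x_1 x_2)}.}
#'   \item{interaction}{\eqn{r(x) = x_1 x_2 + x_3 x_4}.}
#' }
#'
#' @param kind one of \code{"quadratic"}, \code{"xor"},
#'   \code{"interaction"}.
#' @param seed accepted for interface symmetry; the surfaces are
#'   deterministic.
#' @return a function taking a feature matrix and returning the log-hazard
#'   vector, with a \code{"kind"} attribute.
#' @export
makeNonlinearRisk <- function(kind = c("quadratic", "xor", "interaction"),
                              seed = NULL) {
  kind <- match.arg(kind)
  f <- switch(kind,
    quadratic = function(X) X[, 1]^2 - X[, 2]^2,
    xor = function(X) sign(X[, 1] * X[, 2]),
    interaction = function(X) {
      if (ncol(X) < 4) stop2("'interaction' risk needs at least 4 features")
      X[, 1] * X[, 2] + X[, 3] * X[, 4]
    })
  attr(f, "kind") <- kind
  f
}

## Calibrate the exponential censoring rate by bisection so that the
## expected censored fraction P(C < T) = E[1 - exp(-rate * T)] over a pilot
## sample of event times matches the target. Monotonicity of the censored
## fraction in the rate is what makes bisection valid; it is asserted on the
## initial bracket.
.calibrateCensoring <- function(pilotT, target, tol = 0.005) {
  frac <- function(rate) mean(1 - exp(-rate * pilotT))
  lo <- 1e-12
  hi <- 1 / stats::median(pilotT)
  while (frac(hi) < target && hi < 1e12) hi <- hi * 4
  stopifnot(frac(hi) >= frac(lo))  # censored fraction is monotone in rate
  for (it in 1:200) {
    mid <- sqrt(lo * hi)
    if (frac(mid) < target) lo <- mid else hi <- mid
    if (abs(frac(mid) - target) < tol) return(mid)
  }
  sqrt(lo * hi)
}

#' Simulate a right-censored survival dataset with known risks
#'
#' Draws features, true log-hazards, Weibull/exponential event times and
#' calibrated exponential censoring times per the simulation spec. The
#' censoring rate is tuned by bisection on a pilot sample of 10,000 event
#' times drawn from the same mechanism, so the expected censored fraction
#' matches the target for nonlinear risks too. Deterministic for a fixed
#' seed.
#'
#' @param spec a \code{\link{simulationSpec}}.
#' @return list with \code{dataset} (a \linkS4class{SurvivalDataset}; the
#'   realized censoring rate and spec are kept in its metadata) and
#'   \code{trueRisk} (the length-n true log-hazard vector, for oracle
#'   evaluation).
#' @examples
#' sim <- simulateSurvival(simulationSpec(100, 5, beta = rep(0.5, 5),
#'                                        seed = 7))
#' sim$dataset
#' @export
simulateSurvival <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  withSeed(spec$seed, {
    riskOf <- function(X) {
      if (!is.null(spec$riskFunction)) as.numeric(spec$riskFunction(X))
      else as.numeric(X %*% spec$beta)
    }
    drawT <- function(r) {
      lam <- spec$baselineRate * exp(r)
      (stats::rexp(length(r)) / lam)^(1 / spec$shape)
    }
    censRate <- 0
    if (spec$censoringTarget > 0) {
      m <- 10000L
      pilotX <- matrix(stats::rnorm(m * spec$p), m, spec$p)
      censRate <- .calibrateCensoring(drawT(riskOf(pilotX)),
                                      spec$censoringTarget)
    }
    X <- matrix(stats::rnorm(spec$n * spec$p), spec$n, spec$p,
                dimnames = list(NULL, paste0("x", seq_len(spec$p))))
    risk <- riskOf(X)
    T <- drawT(risk)
    C <- if (censRate > 0) stats::rexp(spec$n, rate = censRate) else
      rep(Inf, spec$n)
    ds <- SurvivalDataset(X, pmin(T, C), as.numeric(T <= C),
                          sprintf("sim%05d", seq_len(spec$n)))
    metadata(ds)$simulation <- list(
      n = spec$n, p = spec$p, beta = spec$beta,
      riskKind = attr(spec$riskFunction, "kind"),
      baselineRate = spec$baselineRate,
      censoringTarget = spec$censoringTarget,
      censoringRate = censRate, shape = spec$shape, seed = spec$seed)
    list(dataset = ds, trueRisk = risk)
  })
}
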