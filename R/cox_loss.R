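## Shared preparation for the partial-likelihood loss and its gradient:
## sort by time (increasing), locate tie groups, and accumulate the
## stabilized risk-set sums. Risk sets use the Breslow convention
## R_i = { j : t_j >= t_i }, so tied times are mutually at risk.
.coxPrep <- function(risk, times, events) {
  n <- length(risk)
  if (length(times) != n || length(events) != n)
    stop2("risk, times and events must have equal length")
  if (!all(is.finite(risk))) stop2("risk scores must be finite")
  if (!any(events == 1)) stop2("no uncensored samples")
  ord <- order(times)
  s <- risk[ord]
  t <- times[ord]
  e <- events[ord]
  m <- max(s)
  es <- exp(s - m)
  rc <- rev(cumsum(rev(es)))          # sum over j with sorted index >= i
  grp <- cumsum(!duplicated(t))       # tie-group id, increasing
  first <- match(grp, grp)            # first index of each tie group
  idx <- seq_len(n)
  last <- stats::ave(idx, grp, FUN = max)
  D <- rc[first]                      # sum_{t_k >= t_i} exp(s_k - m)
  list(ord = ord, s = s, t = t, e = e, m = m, es = es, D = D,
       first = first, last = last, n = n)
}

#' Negative log Cox partial likelihood
#'
#' Computes \deqn{l = -\sum_{i \in U} ( s_i - \log \sum_{j \in R_i} e^{s_j} )}
#' where \eqn{s} are the linear risk scores (the inputs to the Cox output
#' layer times its coefficients), \eqn{U} the uncensored patients, and the
#' risk set \eqn{R_i = \{ j : t_j \ge t_i \}} includes tied times (Breslow
#' convention). The inner log-sum-exp is stabilized by subtracting the
#' maximum score. The loss is invariant to adding a constant to all scores
#' and to permuting the patients.
#'
#' @param risk length-n numeric vector of linear risk scores.
#' @param times,events survival times and 0/1 event indicators.
#' @return scalar loss (non-negative).
#' @seealso \code{\link{coxRiskGradient}}
#' @export
coxNegLogLik <- function(risk, times, events) {
  p <- .coxPrep(risk, times, events)
  sum(p$e * (log(p$D) + p$m - p$s))
}

#' Gradient of the partial-likelihood loss with respect to the risk scores
#'
#' Component i is
#' \deqn{\partial l / \partial s_i = -c_i +
#'   e^{s_i} \sum_{j \in U,\, i \in R_j} 1 / \sum_{k \in R_j} e^{s_k}}
#' with \eqn{c_i} the event indicator — the per-sample derivative that
#' backpropagation multiplies through the hidden-layer chain rule. The
#' components always sum to zero: each event contributes \eqn{-1} balanced
#' by softmax weights summing to one over its risk set.
#'
#' @inheritParams coxNegLogLik
#' @return length-n gradient vector (same order as the inputs).
#' @export
coxRiskGradient <- function(risk, times, events) {
  p <- .coxPrep(risk, times, events)
  inv <- cumsum(p$e / p$D)     # sum over events j with sorted index <= .
  A <- inv[p$last]             # events j with t_j <= t_i (tie-inclusive)
  g <- numeric(p$n)
  g[p$ord] <- -p$e + p$es * A
  g
}
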