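## Fixtures and independent reference implementations used across tests.
## The references are deliberately naive (double loops, direct formulas) so
## they stay independent of the package's vectorized code paths.

toyDataset <- function(n = 20, p = 3, seed = 1, censorFrac = 0.4) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  times <- rexp(n)
  events <- rbinom(n, 1, 1 - censorFrac)
  if (!any(events == 1)) events[1] <- 1
  SurvivalDataset(X, times, events)
}

## negative log partial likelihood by direct summation over risk sets
naiveCoxLoss <- function(risk, times, events) {
  l <- 0
  for (i in which(events == 1)) {
    R <- which(times >= times[i])
    l <- l - (risk[i] - log(sum(exp(risk[R]))))
  }
  l
}

## central finite differences of a scalar function of a vector
fdGradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h
    xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

## Harrell's c-index by explicit pair enumeration (the documented rule)
bruteConcordance <- function(risk, times, events) {
  num <- 0
  den <- 0
  n <- length(risk)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    permissible <- (times[i] < times[j] && events[i] == 1) ||
      (times[i] == times[j] && events[i] == 1 && events[j] == 0)
    if (!permissible) next
    den <- den + 1
    if (risk[i] > risk[j]) num <- num + 1
    else if (risk[i] == risk[j]) num <- num + 0.5
  }
  list(cIndex = num / den, nPairs = den)
}

## random survival instance with tied times and mixed censoring
randomInstance <- function(n, maxTime = 8) {
  list(risk = rnorm(n),
       times = sample(seq_len(maxTime), n, replace = TRUE),
       events = {
         e <- rbinom(n, 1, 0.6)
         if (!any(e == 1)) e[1] <- 1
         e
       })
}

writeToyTable <- function(df, delimiter = "\t") {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE,
              na = "")
  path
}
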