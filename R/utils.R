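`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code with a temporary RNG state so library calls never disturb the
## caller's random stream. All stochastic entry points funnel through this.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop2("seed must be a single integer")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

## Validation failures carry a condition class so the command-line layer can
## map them to a user-error exit code.
stop2 <- function(...) {
  stop(errorCondition(paste0(...), class = c("deepcox_error", "error")))
}

## Small deterministic rolling hash over a serialized object; used only to
## stamp output manifests so reruns are comparable.
tinyHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L)[-(1:14)])
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
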