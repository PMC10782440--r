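# internal helpers

# numerically stable log(mean(exp(x)))
logmeanexp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

# run code with an isolated, seeded RNG stream, restoring the caller's state
with_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_numerical <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("evbthermo_numerical", "error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("evbthermo_data", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
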