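# Internal helpers: classed error conditions and seed scoping.

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("evograph_invalid_parameter", "evograph_error")))
}

stop_capacity <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("evograph_capacity_error", "evograph_error")))
}

stop_sampling <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("evograph_sampling_error", "evograph_error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("evograph_validation_error", "evograph_error")))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# stream is restored afterwards. seed = NULL runs in the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_invalid("seed must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

check_fitness <- function(fprime, f) {
  if (!is.numeric(fprime) || !is.numeric(f) || any(fprime <= 0) || any(f <= 0) ||
      anyNA(fprime) || anyNA(f))
    stop_invalid("fitness values must be strictly positive")
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
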