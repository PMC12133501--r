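#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif approx fft coef lm median sd
#' @importFrom utils read.csv write.csv head tail
NULL

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  Keeps every seeded operation reproducible without
# clobbering the global stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Derive a child seed from a base seed; stays below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647L)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(structure(class = c("exotremor_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
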