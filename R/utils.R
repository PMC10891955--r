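#' @import methods
#' @importFrom stats cor quantile rnorm runif sd var setNames
#' @importFrom utils read.csv write.csv head
NULL

# Internal input-check helper: stop with a classed condition so callers and
# tests can distinguish user-input errors from bugs.
ncStop <- function(msg, class = "nichecast_input_error", ...) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

ncWarn <- function(msg) warning(msg, call. = FALSE)

#' Derive a stage seed from a master seed and a label
#'
#' One master seed drives the whole pipeline; each stochastic stage draws its
#' own seed from the master seed and the stage's name, so toggling one stage
#' never shifts the random stream of another. The derivation is a small
#' deterministic integer hash kept below 2^31.
#'
#' @param masterSeed single integer master seed.
#' @param label character stage label.
#' @return a single integer seed.
#' @export
#' @examples
#' deriveSeed(42, "thin")
deriveSeed <- function(masterSeed, label) {
  stopifnot(length(masterSeed) == 1, is.finite(masterSeed),
            is.character(label), length(label) == 1)
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 131 + code) %% 1000003
  as.integer((abs(as.numeric(masterSeed)) * 2654435 + h) %% 2147483647)
}

# Run code under a local RNG seed without disturbing the caller's stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
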