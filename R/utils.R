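#' Logit and inverse-logit
#'
#' Numerically safe logit / inverse-logit used throughout the effect-mapping
#' layer (relative effects are applied on the log-odds scale).
#'
#' @param p probability in (0, 1)
#' @param x real number
#' @return `logit()` returns log(p / (1 - p)); `inv_logit()` returns
#'   1 / (1 + exp(-x)).
#' @export
logit <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p <= 0 | p >= 1)) {
    stop("logit() requires probabilities strictly inside (0, 1)")
  }
  log(p) - log1p(-p)
}

#' @rdname logit
#' @export
inv_logit <- function(x) {
  stopifnot(is.numeric(x))
  1 / (1 + exp(-x))
}

# Clamp a probability into [0, 1], counting how many values were clamped.
# Returns list(value, n_clamped); the Markov engine aggregates the counts
# into its warning log.
clamp_prob <- function(p) {
  hi <- p > 1
  lo <- p < 0
  p[hi] <- 1
  p[lo] <- 0
  list(value = p, n_clamped = sum(hi) + sum(lo))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
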