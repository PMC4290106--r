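#' @useDynLib avigc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats chisq.test cor cor.test median optim pexp plogis qlogis
#'   quantile rbinom rexp rlnorm rnorm runif sd setNames var wilcox.test
#'   complete.cases rmultinom
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x, lo = 0.02, hi = 0.98) pmin(pmax(x, lo), hi)

#' Derive independent substream seeds from one master seed
#'
#' Used so that, e.g., adding genes to a simulated dataset does not perturb
#' the trait draws: each generator consumes its own stream.
#'
#' @param seed master seed (integer below 2^31).
#' @param n number of substream seeds.
#' @return integer vector of `n` seeds.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

stop_avigc <- function(...) stop(..., call. = FALSE)

warn_avigc <- function(...) warning(..., call. = FALSE)
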