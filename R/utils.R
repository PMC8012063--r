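#' @importFrom methods new validObject is setValidity show slot
#' @importFrom stats median mad quantile rbeta rexp rgamma rlnorm rnorm runif
#'   p.adjust pchisq pgamma pt ks.test wilcox.test t.test shapiro.test
#'   fisher.test binom.test cor dhyper sd
#' @importFrom utils read.delim write.table head packageVersion
#' @importFrom Rcpp evalCpp
#' @useDynLib xtenrich, .registration = TRUE
NULL

# Run `expr` under a fixed RNG state when `seed` is given, without touching
# the caller's global stream; with seed = NULL the global stream is used.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Deterministic per-stage substream seeds fanned out from one master seed.
# Kept strictly below 2^31 so they remain valid R integers.
fanout_seed <- function(seed, k) {
  (as.double(seed) * 1103L + 7919L * as.double(k)) %% 2147483647
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
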