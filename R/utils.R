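#' @useDynLib olcassembler, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rbinom rnorm runif
#' @importFrom utils head tail write.table
NULL

# Run code with a private RNG stream; the caller's .Random.seed is restored
# afterwards so library calls never perturb user-level randomness.
with_private_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Byte-order (C locale) string sort: deterministic across platforms/locales.
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_dna <- function(x, what = "sequence", allow_n = FALSE) {
  if (!is.character(x)) stop(what, " must be a character vector", call. = FALSE)
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- grepl(pat, x)
  if (any(bad)) {
    stop(what, " contains characters outside {A,C,G,T",
         if (allow_n) ",N", "} (first offender: ",
         which(bad)[1L], ")", call. = FALSE)
  }
  invisible(x)
}
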