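# Internal helpers: reproducible seeding, logging, small format utilities.

#' Evaluate an expression under a fixed RNG seed, restoring the caller's state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a run with a given master seed is bit-identical,
#' regardless of what the surrounding session has done with the RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Derive a deterministic sub-seed from a master seed and context tokens
#'
#' Sub-seeds for per-site / per-window bootstraps are functions of the master
#' seed and the site's identity (chromosome, position, window size), never of
#' execution order, so parallel scheduling cannot change any p-value.
#'
#' @param seed master integer seed.
#' @param ... context tokens (coerced to character).
#' @return an integer in [1, 2^31 - 2].
#' @keywords internal
derive_seed <- function(seed, ...) {
  s <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
             collapse = "|")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483629
  as.integer(1 + (h %% 2147483645))
}

# Package-level logging; silenced with options(peakdeconv.verbose = FALSE).
pd_log <- function(fmt, ...) {
  if (isTRUE(getOption("peakdeconv.verbose", TRUE))) {
    message(sprintf(paste0("[peakdeconv] ", fmt), ...))
  }
  invisible(NULL)
}

# Short content hash used in reproducibility headers (not cryptographic).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = " ")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483629
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
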