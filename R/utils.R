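# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards. A `NULL` seed leaves the RNG stream untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

stop_pgtsma <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "pgtsma_error")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
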