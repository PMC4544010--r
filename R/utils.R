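#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. All user-facing randomness flows
# through an explicit integer seed via withr::with_seed; no function touches
# the global RNG state.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

#' Run code with a fixed RNG seed, restoring global state afterwards
#' @noRd
with_seed <- function(seed, code) {
  if (!is_count_scalar(seed)) stopf("seed must be a single non-negative integer")
  withr::with_seed(as.integer(seed), code)
}
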