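#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# Run code under a temporary RNG state derived from `seed`, restoring the
# caller's RNG afterwards. All stochastic operations in the package go
# through this so results are reproducible and side-effect free.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Deterministically spawn a sub-seed for stage `index` from a master seed,
# kept within 32-bit integer range.
spawn_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 7919) %% 2147483647L)
}

ln_stop <- function(...) stop(sprintf(...), call. = FALSE)
ln_warn <- function(...) warning(sprintf(...), call. = FALSE)

# Proportion helper guarding against division by zero.
safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
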