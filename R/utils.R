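# Internal helpers shared across modules.

# Classed conditions so callers can distinguish failure modes programmatically.
stop_cspselect <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cspselect_error", "error")))
}

validation_error <- function(msg) stop_cspselect(msg, "cspselect_validation_error")
format_error     <- function(msg) stop_cspselect(msg, "cspselect_format_error")
lookup_error     <- function(msg) stop_cspselect(msg, "cspselect_lookup_error")
numerical_error  <- function(msg) stop_cspselect(msg, "cspselect_numerical_error")
domain_error     <- function(msg) stop_cspselect(msg, "cspselect_domain_error")
io_error         <- function(msg) stop_cspselect(msg, "cspselect_io_error")

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
# All stochastic operations in the package route through this, so results are
# pure functions of their seed arguments and never disturb the global stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
  }
  force(code)
}

# Deterministic child seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + as.numeric(i) * 10007) %% 2147483629L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}
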