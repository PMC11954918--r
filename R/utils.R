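# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# .Random.seed. All exported stochastic functions route through this so a
# given seed is reproducible regardless of surrounding RNG use.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(master, k) {
  as.integer((as.double(master) * 48271 + 11 * as.double(k)) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

# sample max - min, 0-safe
value_range <- function(x) if (length(x) == 0L) NA_real_ else max(x) - min(x)
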