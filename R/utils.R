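#' @keywords internal
"_PACKAGE"

## Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
## RNG state afterwards so generators never disturb user randomness.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

abort_asm <- function(msg, class) {
  stop(structure(
    class = c(class, "asm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

parse_error <- function(msg) abort_asm(msg, "asm_parse_error")
integrity_error <- function(msg) abort_asm(msg, "asm_integrity_error")
lookup_error <- function(msg) abort_asm(msg, "asm_lookup_error")
config_error <- function(msg) abort_asm(msg, "asm_config_error")
range_error <- function(msg) abort_asm(msg, "asm_range_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
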