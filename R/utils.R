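# Internal helpers shared across modules.

#' @keywords internal
tt_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "tt_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

format_error       <- function(msg, ...) tt_error("tt_format_error", msg, ...)
alignment_error    <- function(msg, ...) tt_error("tt_alignment_error", msg, ...)
value_error        <- function(msg, ...) tt_error("tt_value_error", msg, ...)
partition_error    <- function(msg, ...) tt_error("tt_partition_error", msg, ...)
optimization_error <- function(msg, ...) tt_error("tt_optimization_error", msg, ...)

#' Run an expression under a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a `seed` argument makes them pure functions of their
#' inputs without disturbing the session RNG.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    value_error("seed must be a single finite number")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a global seed and a stage label
#'
#' One run-level seed fans out deterministically to per-generator seeds so
#' that modules can be exercised in isolation yet reproduce jointly.  The
#' derivation is a simple 32-bit-safe polynomial hash of the label mixed
#' with the parent seed; the result is always in `[1, 2^31 - 2]`.
#'
#' @param seed integer parent seed.
#' @param label character stage label (e.g. `"alignment"`, `"trace"`).
#' @return a single integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, label) {
  if (!is.character(label) || length(label) != 1L)
    value_error("label must be a single string")
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}
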