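# Seed scoping and derivation. All stochastic entry points take an explicit
# seed; evaluation under with_seed() leaves the caller's RNG stream intact.

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
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
  force(expr)
}

#' Derive a stream-specific seed from a global seed
#'
#' A single pipeline seed fans out to per-component seeds so that modules
#' are individually reproducible yet jointly deterministic. The derivation
#' is a fixed integer hash kept inside the 32-bit signed range.
#'
#' @param seed integer global seed.
#' @param ... one or more integers or strings identifying the stream
#'   (e.g. an activity code and a trace index).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p))
    for (v in as.double(p)) {
      h <- (h * 69069 + v + 1) %% 2147483647
    }
  }
  as.integer(h)
}
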