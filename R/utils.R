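# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All exported stochastic operations
# route their draws through this so one top-level seed governs everything
# without clobbering the user's RNG stream.
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
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a parent seed and a stream label, keeping the
# result a valid positive 32-bit integer. Deterministic string hash (djb2),
# no RNG involved, so stream splitting is reproducible across platforms.
child_seed <- function(seed, label) {
  stopifnot(length(seed) == 1, is.finite(seed))
  h <- 5381
  for (ch in utf8ToInt(paste0(label, ":", as.integer(seed)))) {
    h <- (h * 33 + ch) %% 2147483647
  }
  as.integer(max(h, 1L))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_phenorisk <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, finite = TRUE) {
  if (length(x) != 1 || !is.numeric(x) || (finite && !is.finite(x))) {
    stop_phenorisk(sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}
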