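#' @keywords internal
"_PACKAGE"

# Hierarchical seed splitting: one root seed expands deterministically into
# independent child seeds (participants, conditions, channels) so that a
# cohort is reproducible as a whole while its parts do not share streams.
# Lehmer-style mixing keeps every derived seed inside the 32-bit integer range.
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647)
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 9349 + 1) %% 2147483647
  }
  as.integer(s)
}

# Run an expression under a local RNG state.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}
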