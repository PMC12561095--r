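# Classed conditions shared by all modules. Every user-facing failure is an
# "fs_error" with a specific subclass so callers (and the CLI) can react
# without parsing messages.

fs_abort <- function(message, class) {
  stop(structure(
    class = c(class, "fs_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' @keywords internal
fs_assert <- function(cond, message, class) {
  if (!isTRUE(cond)) fs_abort(message, class)
  invisible(TRUE)
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic steps in the package go
# through this so library calls never disturb user RNG state.
with_local_seed <- function(seed, code) {
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
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Small deterministic integer mixer used to derive per-draw seeds.
mix_seed <- function(...) {
  parts <- as.numeric(c(...))
  h <- 104729
  for (p in parts) h <- (h * 31 + (p %% 2147483647)) %% 2147483647
  as.integer(h)
}
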