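# internal helpers shared across modules

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards so generators are pure functions of (config, seed).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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

stopifnot_scalar_pos <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (allow_zero) {
    if (x < 0) stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  } else if (x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# classed error for a singular linlog steady state so callers can assign a
# penalty instead of aborting
singular_steady_state_error <- function(msg = "singular steady-state system (N E B' not invertible)") {
  stop(errorCondition(msg, class = c("replimet_singular_error", "error", "condition")))
}

singular_response_error <- function(msg) {
  stop(errorCondition(msg, class = c("replimet_singular_response", "error", "condition")))
}
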