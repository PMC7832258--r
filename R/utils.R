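# Internal helpers: error signalling, argument checks, local RNG scoping.

abort_dv <- function(msg, class, ...) {
  rlang::abort(msg, class = c(paste0("dopplervti_error_", class), "dopplervti_error"), ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE, allow_equal_upper = TRUE,
                         class = "config") {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (allow_equal_lower) x >= lower else x > lower) &&
    (if (allow_equal_upper) x <= upper else x < upper)
  if (!ok) {
    abort_dv(sprintf("`%s` must be a finite number in %s%s, %s%s (got %s).",
                     name,
                     if (allow_equal_lower) "[" else "(", format(lower),
                     format(upper), if (allow_equal_upper) "]" else ")",
                     paste(format(x), collapse = ", ")),
             class = class)
  }
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All stochastic generator functions route through
# this so that a given seed is reproducible regardless of ambient RNG state.
with_local_seed <- function(seed, expr) {
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

# Deterministic master-seed -> per-subject seed derivation. Kept below 2^31.
derive_subject_seed <- function(master_seed, subject_index) {
  (as.double(master_seed) %% 1e6) * 2048 + 7 * subject_index + 1
}

# Smooth monotone ramp: 0 at x<=0, 1 at x>=1, C1 in between.
smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}
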