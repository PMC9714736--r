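#' @keywords internal
"_PACKAGE"

# Internal argument checks. Kept minimal on purpose: every user-facing error
# must name the offending argument.

stop_bad <- function(...) stop(..., call. = FALSE)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L)
    stop_bad(sprintf("'%s' must be a single number", name))
  if (!allow_na && !is.finite(x))
    stop_bad(sprintf("'%s' must be finite", name))
  if (is.finite(x) && (x < lower || x > upper))
    stop_bad(sprintf("'%s' must be in [%s, %s]", name, lower, upper))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_scalar_number(x, name, lower = min)
  if (x != round(x)) stop_bad(sprintf("'%s' must be a whole number", name))
  invisible(as.integer(x))
}

check_numeric_vector <- function(x, name, min_len = 1L, lower = -Inf) {
  if (!is.numeric(x) || length(x) < min_len)
    stop_bad(sprintf("'%s' must be numeric with at least %d value(s)",
                     name, min_len))
  if (any(!is.finite(x)))
    stop_bad(sprintf("'%s' contains non-finite values", name))
  if (any(x < lower))
    stop_bad(sprintf("'%s' must be >= %s", name, lower))
  invisible(x)
}

# Probabilities are clamped away from {0,1} only where a finite logit is
# required; plogis(Inf) == 1 is otherwise fine.
clamp01 <- function(p) pmin(1, pmax(0, p))

# Seeded evaluation that never clobbers the caller's RNG stream.
with_seed <- function(seed, code) {
  check_count(seed, "seed", min = 0L)
  withr::with_seed(as.integer(seed), code)
}

# Deterministic child seeds for multi-stage pipelines (kept < 2^31).
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483000L
}
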