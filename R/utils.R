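# Internal helpers shared across modules.

# Classed conditions so callers (and the CLI) can distinguish bad
# configuration from bad data.
abort_config <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("apms_config_error", "error")))
}

abort_value <- function(msg) {
  stop(errorCondition(msg, class = c("apms_value_error", "error")))
}

# Round half away from zero to `digits` decimals. base::round() rounds
# half to even, which would turn 5.65 into 5.6; percent reporting here
# follows the conventional half-up rule.
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Scalar validators used by configuration checks; `name` makes the error
# message identify the offending field.
check_number <- function(x, name, min = -Inf, max = Inf,
                         integer = FALSE, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_config(sprintf("field '%s' must be a single non-missing number", name))
  }
  if (integer && x != trunc(x)) {
    abort_config(sprintf("field '%s' must be an integer (got %s)", name, x))
  }
  low_ok <- if (strict_min) x > min else x >= min
  if (!low_ok || x > max) {
    abort_config(sprintf(
      "field '%s' must be in %s%s, %s] (got %s)",
      name, if (strict_min) "(" else "[", min, max, x
    ))
  }
  invisible(x)
}

# Run `expr` with the RNG seeded to `seed`, then restore the caller's
# RNG state so simulation calls do not perturb the session stream.
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x
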