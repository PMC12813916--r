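# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is_number(x))
    stopf("'%s' must be a single finite number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stopf("'%s' must be in %s%g, %g%s (got %g)", name,
          if (strict_lower) "(" else "[", lower, upper,
          if (strict_upper) ")" else "]", x)
  invisible(x)
}

# Evaluate expr with a temporary RNG state seeded at `seed`; the caller's
# stream is restored afterwards so package randomness never leaks.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Linear interpolation; with `period` the signal is treated as periodic on
# [0, period) so queries past the last sample wrap to the start of the cycle.
interp_linear <- function(time, value, t_out, period = NULL) {
  if (!is.null(period)) {
    t_out <- t_out %% period
    time <- c(time, time[1L] + period)
    value <- c(value, value[1L])
  }
  stats::approx(time, value, xout = t_out, method = "linear",
                rule = 2, ties = "ordered")$y
}

check_strictly_increasing <- function(x, name) {
  if (length(x) > 1L && any(diff(x) <= 0))
    stopf("'%s' must be strictly increasing", name)
  invisible(x)
}
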