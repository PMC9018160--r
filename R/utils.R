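# Classed conditions so callers (and the CLI) can distinguish bad input
# from internal failures.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("npad_validation_error", "npad_error")))
}

stop_computation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("npad_computation_error", "npad_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_numeric <- function(x, name, finite = TRUE) {
  if (!is.numeric(x)) stop_validation("'%s' must be numeric", name)
  if (finite && any(!is.finite(x)))
    stop_validation("'%s' contains non-finite values", name)
  invisible(x)
}

check_aligned <- function(..., n = NULL) {
  lens <- vapply(list(...), length, integer(1))
  if (length(unique(lens)) != 1L)
    stop_validation("inputs must have equal length (got %s)",
                    paste(lens, collapse = ", "))
  if (!is.null(n) && lens[1] < n)
    stop_validation("need at least %d observations, got %d", n, lens[1])
  invisible(lens[1])
}

# Draw from N(mean, sd) truncated to [lo, hi] by resampling.
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
    guard <- guard + 1L
  }
  pmin(pmax(x, lo), hi)
}
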