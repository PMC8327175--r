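# Internal helpers shared across modules.

# Trapezoidal integral of y over x (non-uniform grids allowed).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# Contiguous runs of TRUE in a logical vector; data.frame with start/end indices.
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Every stochastic generator takes an explicit seed and leaves the global RNG
# stream untouched.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
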