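# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Classed condition for segments dropped by a quality rule; callers that
# process segment tables catch this class and record the reason.
reject_segment <- function(reason, ...) {
  msg <- sprintf(reason, ...)
  cond <- structure(
    class = c("ppg_rejection", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x)
}

# Steady-state initial filter conditions, so a step input produces a step
# output with no start-up transient (direct-form II transposed state).
filter_initial_state <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  if (n == 1) return(numeric(0))
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[-1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  solve(diag(n - 1) - t(comp), b[-1] - a[-1] * b[1])
}

# Single-pass IIR filter with explicit initial state.
iir_filter <- function(b, a, x, zi) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  y <- numeric(length(x))
  z <- zi
  bt <- b[-1]
  at <- a[-1]
  b1 <- b[1]
  for (m in seq_along(x)) {
    y[m] <- b1 * x[m] + z[1]
    z <- c(z[-1], 0) + bt * x[m] - at * y[m]
  }
  y
}

# Zero-phase forward-backward filtering with mirror (even-reflection)
# padding and steady-state initial conditions at both ends. The padding must
# be long enough that reflection-point transients (decay time ~ fs / lowest
# cutoff) die out before reaching the data; mirror padding preserves signal
# amplitude across the boundary, which keeps edge transients small for
# oscillatory pulse waveforms.
zero_phase_filter <- function(b, a, x, padlen = NULL) {
  n <- max(length(a), length(b))
  if (is.null(padlen)) padlen <- 3 * n
  padlen <- min(padlen, length(x) - 1)
  if (length(x) <= padlen) {
    stop("signal too short for zero-phase filtering (need > ", padlen, " samples)")
  }
  nx <- length(x)
  ext <- c(x[(padlen + 1):2], x, x[(nx - 1):(nx - padlen)])
  zi <- filter_initial_state(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + nx)]
}
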