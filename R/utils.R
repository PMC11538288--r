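# Internal helpers shared across modules.

# Signal a classed error so callers and tests can match on condition class.
hcStop <- function(subclass, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(subclass, "holocall_error", "error", "condition")))
}

hcWarn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Truncated-normal draws by rejection; bounds are physical (never tight),
# so rejection is cheap.
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  x <- stats::rnorm(n, mean, sd)
  for (it in 1:1000) {
    bad <- x < lo | x > hi
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lo), hi)
}

# Centered moving average with edge shrinkage (window in samples, odd).
movingAverage <- function(x, k) {
  if (k <= 1L) return(x)
  k <- as.integer(k)
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(x)
  cs <- cumsum(c(0, x))
  h <- k %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Amplitude envelope: magnitude of the analytic signal (FFT Hilbert
# transform), optionally smoothed with a moving average of `smoothMs`.
hilbertEnvelope <- function(x, rateHz, smoothMs = 1) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(stats::fft(X * h, inverse = TRUE) / n)
  if (smoothMs > 0)
    env <- movingAverage(env, max(1L, round(smoothMs / 1000 * rateHz)))
  env
}

# Derive a per-stream seed below 2^31 from a base seed and a counter, so one
# user-facing seed fans out into independent reproducible streams.
fanSeed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 16807) %% 2147483647)
}
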