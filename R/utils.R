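# internal helpers shared across stages

# deterministic per-unit seed fan-out; stays below 2^31 - 1
derive_seed <- function(base, i) {
  as.integer((as.numeric(base) %% 1048576 * 1000003 + as.numeric(i) * 7919) %% 2147483647)
}

# half-open analysis windows [s, s + window_s) covering a duration
window_starts <- function(duration, window_s, overlap) {
  if (duration < window_s) stop("series shorter than one window")
  step <- window_s * (1 - overlap)
  n <- floor((duration - window_s) / step + 1e-9) + 1
  (seq_len(n) - 1) * step
}

# trapezoidal integral on an arbitrary grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# centred moving average via cumulative sums (edge windows shrink)
movavg <- function(x, k) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - k %/% 2, 1)
  hi <- pmin(seq_len(n) + (k - k %/% 2) - 1, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

zscore_cols <- function(x, center, scale) {
  scale[scale == 0] <- 1
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}
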