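#' Detect R peaks and beat-wise amplitudes
#'
#' Pan-Tompkins-style detection: band-pass 5-30 Hz, differentiate, square,
#' moving-window integration (150 ms) and thresholding, followed by
#' refinement of each beat to the local extremum of the band-passed signal.
#' The peak-to-peak amplitude is measured on the input signal within a
#' +/-60 ms window around each R peak. Physiologically implausible beats
#' (RR < 0.27 s or > 3 s) are rejected.
#'
#' @param x ECG lead (numeric series).
#' @param fs Sampling rate (Hz, default 128).
#' @return A list of class `beat_series`: `times` (s), `pp_amplitude`
#'   (peak-to-peak, signal units), `rr` (s, one shorter than `times`).
#' @export
detect_r_peaks <- function(x, fs = 128) {
  stopifnot(length(x) >= 10 * fs)
  bp <- signal::butter(2, c(5, 30) / (fs / 2), type = "pass")
  xb <- zerophase(bp, x, pad = fs)
  d <- c(0, diff(xb))
  # centred moving-window integration via cumulative sums
  k <- as.integer(0.15 * fs)
  cs <- cumsum(c(0, d^2))
  n0 <- length(d)
  lo <- pmax(seq_len(n0) - k %/% 2, 1)
  hi <- pmin(seq_len(n0) + (k - k %/% 2), n0)
  integ <- cs[hi + 1] - cs[lo]
  thr <- 0.2 * stats::quantile(integ, 0.99)
  above <- integ > thr
  if (!any(above)) stop("insufficient beats")
  # candidate regions -> one beat per contiguous run
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cand <- mapply(function(s, e) s - 1 + which.max(integ[s:e]),
                 starts[runs$values], ends[runs$values])
  # refine to extremum of |band-passed| signal within +/-100 ms
  w <- as.integer(0.1 * fs)
  peaks <- vapply(cand, function(i) {
    lo <- max(1, i - w); hi <- min(length(x), i + w)
    lo - 1 + which.max(abs(xb[lo:hi]))
  }, 0)
  peaks <- sort(unique(peaks))
  # enforce minimum RR 0.27 s, keeping the stronger beat
  min_gap <- 0.27 * fs
  keep <- logical(length(peaks))
  last <- -Inf; last_i <- 0
  for (i in seq_along(peaks)) {
    if (peaks[i] - last >= min_gap) {
      keep[i] <- TRUE; last <- peaks[i]; last_i <- i
    } else if (abs(xb[peaks[i]]) > abs(xb[peaks[last_i]])) {
      keep[last_i] <- FALSE; keep[i] <- TRUE; last <- peaks[i]; last_i <- i
    }
  }
  peaks <- peaks[keep]
  if (length(peaks) < 2) stop("insufficient beats")
  w2 <- as.integer(0.06 * fs)
  pp <- vapply(peaks, function(i) {
    lo <- max(1, i - w2); hi <- min(length(x), i + w2)
    max(x[lo:hi]) - min(x[lo:hi])
  }, 0)
  structure(list(times = (peaks - 1) / fs, pp_amplitude = pp,
                 rr = diff(peaks) / fs), class = "beat_series")
}

#' ECG-derived respiration
#'
#' Shape-preserving piecewise-cubic Hermite (monotone Fritsch-Carlson)
#' interpolation of the beat-wise QRS peak-to-peak amplitudes onto a
#' uniform grid at the analysis rate. The monotone-segment property means
#' the result never overshoots the range of the measured amplitudes.
#'
#' @param beats A `beat_series` from [detect_r_peaks()].
#' @param fa Analysis rate (Hz).
#' @param t_grid Target time grid (s); defaults to the beat-time span.
#' @return Numeric series on `t_grid`.
#' @export
compute_edr <- function(beats, fa = 4, t_grid = NULL) {
  stopifnot(length(beats$times) >= 4)
  if (anyDuplicated(beats$times)) stop("duplicate beat times")
  if (is.null(t_grid)) t_grid <- seq(beats$times[1], beats$times[length(beats$times)], by = 1 / fa)
  f <- stats::splinefun(beats$times, beats$pp_amplitude, method = "monoH.FC")
  y <- f(pmin(pmax(t_grid, beats$times[1]), beats$times[length(beats$times)]))
  y
}

#' Heart-rate variability series
#'
#' Instantaneous heart rate (1/RR, Hz) at the beat times with recursive
#' outlier correction: while any point deviates from the current series
#' mean by more than 18% of that mean, the worst offender is replaced by
#' cubic-spline interpolation through the remaining points and the mean is
#' recomputed. The corrected series is then cubic-spline interpolated onto
#' a 1 Hz grid and spline-resampled to the analysis rate.
#'
#' @inheritParams compute_edr
#' @param outlier_frac Outlier threshold as a fraction of the mean (0.18).
#' @return Numeric series on `t_grid` (Hz).
#' @export
compute_hrv <- function(beats, fa = 4, t_grid = NULL, outlier_frac = 0.18) {
  stopifnot(length(beats$times) >= 4)
  tb <- beats$times[-1]
  rate <- 1 / beats$rr
  it <- 0; max_it <- 10 * length(rate)
  repeat {
    m <- mean(rate)
    dev <- abs(rate - m)
    if (max(dev) <= outlier_frac * m) break
    it <- it + 1
    if (it > max_it) stop("outlier correction diverged")
    worst <- which.max(dev)
    # interpolate from the currently acceptable points so clustered
    # outliers cannot feed each other's replacements
    good <- which(dev <= outlier_frac * m)
    if (length(good) < 4) stop("outlier correction diverged")
    repl <- stats::spline(tb[good], rate[good], xout = tb[worst], ties = "ordered")$y
    if (abs(repl - m) > outlier_frac * m) # spline overshoot: fall back to linear
      repl <- stats::approx(tb[good], rate[good], xout = tb[worst], rule = 2,
                            ties = "ordered")$y
    rate[worst] <- repl
  }
  # 1 Hz grid first, then up to the common analysis rate
  t1 <- seq(tb[1], tb[length(tb)], by = 1)
  y1 <- stats::spline(tb, rate, xout = t1, ties = "ordered")$y
  if (is.null(t_grid)) t_grid <- seq(tb[1], tb[length(tb)], by = 1 / fa)
  tg <- pmin(pmax(t_grid, t1[1]), t1[length(t1)])
  if (length(t1) < 4) return(stats::approx(t1, y1, tg, rule = 2)$y)
  stats::spline(t1, y1, xout = tg, ties = "ordered")$y
}

#' Surface-EMG envelope
#'
#' Rectifies the signal, detects local maxima of the rectified amplitude,
#' cubic-spline interpolates through the peaks, applies a quadratic local
#' least-squares (Savitzky-Golay) smoothing window, low-passes below the
#' analysis Nyquist and samples onto the analysis grid.
#'
#' @param x sEMG channel at `fs` (numeric series).
#' @param fs Input rate (Hz, default 128).
#' @param fa Analysis rate (Hz).
#' @param t_grid Target time grid (s).
#' @param smooth_win_s Quadratic smoothing window (s, default 0.009).
#' @param peak_halfwin_s Half-width (s) of the neighbourhood a peak must
#'   dominate; block maxima of the rectified signal are far less volatile
#'   than single-sample maxima, giving a stable envelope.
#' @return Numeric series on `t_grid` (>= 0).
#' @export
compute_emge <- function(x, fs = 128, fa = 4, t_grid = NULL, smooth_win_s = 0.009,
                         peak_halfwin_s = 0.04) {
  r <- abs(x)
  n <- length(r)
  k <- max(1L, as.integer(round(peak_halfwin_s * fs)))
  # local maxima that dominate their +/-k neighbourhood
  rmax <- r
  for (d in 1:k) {
    rmax <- pmax(rmax, c(r[-(1:d)], rep(-Inf, d)), c(rep(-Inf, d), r[1:(n - d)]))
  }
  pk <- which(r == rmax)
  if (!length(pk)) stop("no peaks found")
  tt <- (seq_len(n) - 1) / fs
  env <- stats::spline(tt[pk], r[pk], xout = tt, ties = "ordered")$y
  nw <- as.integer(round(smooth_win_s * fs))
  if (nw %% 2 == 0) nw <- nw + 1L
  if (nw >= 5) env <- signal::sgolayfilt(env, p = 2, n = nw)
  # band-limit to twice the HF edge before stepping down to the analysis
  # rate: removes spline ripple between peaks while keeping the
  # modulation band and sub-second envelope fluctuations intact
  lp <- signal::butter(4, (0.2 * fa) / (fs / 2), type = "low")
  env <- zerophase(lp, env, pad = 2 * fs)
  if (is.null(t_grid)) t_grid <- seq(0, tt[n], by = 1 / fa)
  pmax(stats::approx(tt, env, pmin(pmax(t_grid, 0), tt[n]), rule = 2, ties = "ordered")$y, 0)
}

#' Interpolated surface-EMG peak series
#'
#' Detects rectified-amplitude peaks above a threshold (a quantile of the
#' rectified signal) with an enforced minimum separation of 0.15 s (the
#' larger of two conflicting peaks wins), then spline-interpolates the
#' retained peak amplitudes onto the analysis grid.
#'
#' @inheritParams compute_emge
#' @param thresh_quantile Rectified-amplitude quantile defining the
#'   detection threshold (default 0.7).
#' @param min_sep_s Minimum inter-peak separation (s, default 0.15).
#' @return Numeric series on `t_grid`.
#' @export
compute_emgi <- function(x, fs = 128, fa = 4, t_grid = NULL,
                         thresh_quantile = 0.7, min_sep_s = 0.15) {
  r <- abs(x)
  n <- length(r)
  thr <- stats::quantile(r, thresh_quantile)
  pk <- which(r[2:(n - 1)] >= r[1:(n - 2)] & r[2:(n - 1)] > r[3:n]) + 1
  pk <- pk[r[pk] > thr]
  if (!length(pk)) stop("no supra-threshold peaks")
  # greedy by amplitude: keep a peak only if no stronger kept peak is within min_sep
  min_gap <- as.integer(ceiling(min_sep_s * fs))
  ord <- pk[order(r[pk], decreasing = TRUE)]
  occ <- logical(n)
  kept <- logical(n)
  for (i in ord) {
    if (!occ[i]) {
      kept[i] <- TRUE
      occ[max(1L, i - min_gap + 1L):min(n, i + min_gap - 1L)] <- TRUE
    }
  }
  kept <- which(kept)
  tt <- (seq_len(n) - 1) / fs
  if (is.null(t_grid)) t_grid <- seq(0, tt[n], by = 1 / fa)
  if (length(kept) < 4) stop("no supra-threshold peaks")
  # spline on the native grid, band-limit (as for the envelope), then sample
  env <- stats::spline(tt[kept], r[kept], xout = tt, ties = "ordered")$y
  lp <- signal::butter(4, (0.2 * fa) / (fs / 2), type = "low")
  env <- zerophase(lp, env, pad = 2 * fs)
  tg <- pmin(pmax(t_grid, tt[kept[1]]), tt[kept[length(kept)]])
  stats::approx(tt, env, tg, rule = 2, ties = "ordered")$y
}

#' Select the representative sEMG channel / ECG lead pair
#'
#' Normalised cross-correlation maximised (signed) over lags up to
#' `max_lag_s`, computed for every (EMG envelope channel, EDR lead) pair;
#' returns the pair with the largest peak correlation. The signed maximum
#' is used because respiratory drive raises QRS amplitude and diaphragmatic
#' envelope together, so genuine coupling is positive at the right lag.
#'
#' @param emge_list List of 5 EMG-envelope series at the analysis rate.
#' @param edr_list List of 3 EDR series at the analysis rate, time-aligned
#'   with the envelopes.
#' @param fa Analysis rate (Hz).
#' @param max_lag_s Maximum lag magnitude searched (s, default 5).
#' @return List with `channel`, `lead`, `xcorr` and the full 5 x 3 matrix
#'   of peak correlations.
#' @export
select_channel_pair <- function(emge_list, edr_list, fa = 4, max_lag_s = 5) {
  L <- as.integer(max_lag_s * fa)
  xc <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    n <- min(length(a), length(b))
    a <- a[seq_len(n)]; b <- b[seq_len(n)]
    best <- -Inf
    # signed maximum over lags: respiratory drive raises both the QRS
    # amplitude and the diaphragmatic envelope, so coupled pairs correlate
    # positively at the right lag; identical series return +1 at lag 0
    for (lag in -L:L) {
      v <- if (lag >= 0) stats::cor(a[1:(n - lag)], b[(1 + lag):n])
           else stats::cor(a[(1 - lag):n], b[1:(n + lag)])
      if (is.finite(v) && v > best) best <- v
    }
    if (is.infinite(best)) NA_real_ else best
  }
  m <- matrix(NA_real_, 5, 3, dimnames = list(paste0("ch", 1:5), c("leadI", "leadII", "leadIII")))
  for (i in 1:5) for (j in 1:3) {
    v <- xc(emge_list[[i]], edr_list[[j]])
    if (is.na(v)) warning("zero-variance series; pair ch", i, "/lead", j, " skipped")
    m[i, j] <- v
  }
  best <- which(m == max(m, na.rm = TRUE), arr.ind = TRUE)[1, ]
  list(channel = unname(best[1]), lead = unname(best[2]),
       xcorr = m[best[1], best[2]], all = m)
}

#' Compute the four derived analysis signals
#'
#' From a preprocessed recording, computes EDR for all three leads and the
#' EMG envelope for all five channels, selects the representative
#' (channel, lead) pair by cross-correlation, then assembles the
#' time-aligned derived set on a common uniform grid at the analysis
#' rate: EDR (selected lead), HRV (beats of the selected lead), EMGe and
#' EMGi (selected channel).
#'
#' @param clean A `wean_clean` from [preprocess_recording()].
#' @param cfg A [wean_config()].
#' @return Object of class `wean_derived` with elements `t`, `EDR`, `HRV`,
#'   `EMGe`, `EMGi`, `fa`, `channel`, `lead`, `xcorr`.
#' @export
derive_signals <- function(clean, cfg = wean_config()) {
  fa <- cfg$fa
  fs <- clean$fs
  # a common grid all series can cover: trim half a window of slack at both ends
  t_lo <- 2; t_hi <- clean$duration - 2
  t_grid <- seq(t_lo, t_hi, by = 1 / fa)
  beats <- lapply(1:3, function(j) detect_r_peaks(clean$channels[, j], fs))
  edr <- lapply(beats, compute_edr, fa = fa, t_grid = t_grid)
  emge <- lapply(1:5, function(j) compute_emge(clean$channels[, 3 + j], fs, fa, t_grid))
  sel <- select_channel_pair(emge, edr, fa)
  hrv <- compute_hrv(beats[[sel$lead]], fa, t_grid)
  emgi <- compute_emgi(clean$channels[, 3 + sel$channel], fs, fa, t_grid,
                       thresh_quantile = cfg$emgi_quantile)
  out <- list(t = t_grid, EDR = edr[[sel$lead]], HRV = hrv,
              EMGe = emge[[sel$channel]], EMGi = emgi,
              fa = fa, channel = sel$channel, lead = sel$lead,
              xcorr = sel$xcorr, xcorr_all = sel$all,
              patient_id = clean$patient_id, group = clean$group)
  stopifnot(all(vapply(out[c("EDR", "HRV", "EMGe", "EMGi")],
                       function(s) all(is.finite(s)), TRUE)))
  structure(out, class = "wean_derived")
}

#' @export
print.wean_derived <- function(x, ...) {
  cat(sprintf("<wean_derived> patient %s (%s): EDR/HRV/EMGe/EMGi @ %g Hz, %d samples\n",
              x$patient_id, x$group, x$fa, length(x$t)))
  cat(sprintf("  selected pair: ch%d / %s (xcorr %.2f)\n", x$channel,
              c("leadI", "leadII", "leadIII")[x$lead], x$xcorr))
  invisible(x)
}
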