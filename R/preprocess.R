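#' Zero-phase IIR filtering
#'
#' Applies a filter forward and backward (zero phase distortion, squared
#' magnitude response) with reflection padding long enough for the filter
#' transient to die out, which matters for very low cutoffs such as the
#' 0.05 Hz baseline high-pass.
#'
#' @param filt A filter object from [signal::butter()] (or any list with
#'   `b` and `a` polynomial coefficients).
#' @param x Numeric series.
#' @param pad Padding length in samples; defaults to three time constants
#'   of the filter's slowest pole, capped at `length(x) - 2`.
#' @return Filtered series, same length as `x`.
#' @export
zerophase <- function(filt, x, pad = NULL) {
  b <- as.numeric(filt$b)
  a <- as.numeric(filt$a)
  n <- length(x)
  if (is.null(pad)) {
    # slowest pole sets the transient scale
    p <- polyroot(rev(a))
    mag <- Mod(p)
    mag <- mag[mag < 1 - 1e-12]
    pad <- if (length(mag)) ceiling(-3 / log(max(mag))) else 3 * max(length(a), length(b))
  }
  pad <- max(3L, min(as.integer(pad), n - 2L))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- filtfilt_cpp(b, a, xp)
  y[(pad + 1):(pad + n)]
}

butter_hp <- function(order, cutoff_hz, fs) {
  if (cutoff_hz >= fs / 2) stop("cutoff at or above Nyquist")
  signal::butter(order, cutoff_hz / (fs / 2), type = "high")
}

butter_notch <- function(f0, q, fs) {
  if (f0 >= fs / 2) stop("notch frequency at or above Nyquist")
  bw <- f0 / q
  signal::butter(2, c(f0 - bw / 2, f0 + bw / 2) / (fs / 2), type = "stop")
}

#' Filter a raw recording
#'
#' Zero-phase filtering of both modalities: a mains notch on every channel,
#' a 0.05 Hz high-pass on the ECG leads (baseline wander), a 20 Hz
#' high-pass on the sEMG channels (motion/ECG contamination floor), then
#' linear detrending. Cutoffs and orders come from the configuration.
#'
#' @param rec A [wean_recording()].
#' @param cfg A [wean_config()].
#' @return A `wean_recording` with filtered channels at the native rates;
#'   the filters applied are appended to `meta$provenance`.
#' @export
apply_filters <- function(rec, cfg = wean_config()) {
  stopifnot(inherits(rec, "wean_recording"))
  detrend <- detrend_cpp
  notch_e <- butter_notch(cfg$notch_hz, cfg$notch_q, rec$fs_ecg)
  hp_e <- butter_hp(cfg$filter_order, cfg$hp_ecg_hz, rec$fs_ecg)
  ecg <- rec$ecg
  for (j in 1:3) ecg[, j] <-
    detrend(zerophase(hp_e, zerophase(notch_e, rec$ecg[, j], pad = 3 * rec$fs_ecg),
                      pad = ceiling(3 * rec$fs_ecg / cfg$hp_ecg_hz)))
  notch_m <- butter_notch(cfg$notch_hz, cfg$notch_q, rec$fs_emg)
  hp_m <- butter_hp(cfg$filter_order, cfg$hp_emg_hz, rec$fs_emg)
  semg <- rec$semg
  for (j in 1:5) semg[, j] <-
    detrend(zerophase(hp_m, zerophase(notch_m, rec$semg[, j], pad = 3 * rec$fs_emg),
                      pad = ceiling(3 * rec$fs_emg / cfg$hp_emg_hz)))
  out <- wean_recording(rec$patient_id, rec$group, ecg, semg,
                        rec$fs_ecg, rec$fs_emg, rec$meta)
  out$meta$provenance <- c(out$meta$provenance,
                           sprintf("notch %g Hz (Q=%g); high-pass ECG %g Hz / sEMG %g Hz (order %d); linear detrend",
                                   cfg$notch_hz, cfg$notch_q, cfg$hp_ecg_hz,
                                   cfg$hp_emg_hz, cfg$filter_order))
  out
}

#' Resample a series to a lower rate
#'
#' Anti-aliased rate conversion: a zero-phase Butterworth low-pass at 80%
#' of the target Nyquist frequency followed by interpolation onto the
#' uniform target grid. Used to bring the 1 kHz sEMG channels onto the
#' 128 Hz ECG time base.
#'
#' @param x Numeric series.
#' @param fs_in,fs_out Input and output sampling rates (Hz).
#' @return Series at `fs_out`; length `floor((length(x)-1)*fs_out/fs_in)+1`.
#' @export
resample_semg <- function(x, fs_in = 1000, fs_out = 128) {
  stopifnot(fs_out < fs_in)
  aa <- signal::butter(8, 0.8 * (fs_out / 2) / (fs_in / 2), type = "low")
  y <- zerophase(aa, x, pad = ceiling(fs_in / 4))
  tin <- (seq_along(x) - 1) / fs_in
  tout <- seq(0, tin[length(tin)], by = 1 / fs_out)
  stats::approx(tin, y, tout, ties = "ordered")$y
}

#' Replace isolated spikes by local interpolation
#'
#' Samples whose robust z-score (deviation from the median, scaled by
#' 1.4826 x MAD) exceeds `z_thresh` are replaced by linear interpolation
#' from the surrounding non-spike samples.
#'
#' @param x Numeric series (length >= 3).
#' @param z_thresh Robust z-score threshold (default 8).
#' @return Series with spikes replaced; the number of replacements is in
#'   `attr(, "n_replaced")`.
#' @export
despike <- function(x, z_thresh = 8) {
  stopifnot(length(x) >= 3)
  med <- stats::median(x)
  s <- stats::mad(x)
  if (s == 0) s <- stats::sd(x)
  if (is.na(s) || s == 0) {
    attr(x, "n_replaced") <- 0L
    return(x) # constant input: nothing to do
  }
  bad <- which(abs(x - med) / s > z_thresh)
  if (length(bad)) {
    good <- setdiff(seq_along(x), bad)
    x[bad] <- stats::approx(good, x[good], xout = bad, rule = 2, ties = "ordered")$y
  }
  attr(x, "n_replaced") <- length(bad)
  x
}

#' Signal-to-noise ratio from a least-squares baseline model
#'
#' Two estimators built on the same local polynomial least-squares
#' (Savitzky-Golay) baseline fit:
#'
#' * `"baseline"` — the smooth fit of the series itself is the signal
#'   estimate and the residual is noise. Appropriate for signals whose
#'   waveform is slow relative to the window (derived respiratory series,
#'   envelopes, slow test tones).
#' * `"power"` — the baseline model is fit to the instantaneous power
#'   `x^2`; the noise power is the quiet floor of that profile (a low
#'   quantile, reached between QRS complexes or diaphragmatic bursts) and
#'   the signal power is the mean excess above it. Appropriate for raw
#'   burst-like ECG/sEMG channels, whose waveform is broadband but whose
#'   activity is intermittent.
#'
#' Both return `10 log10(P_signal / P_noise)` in dB; a zero noise power
#' yields `Inf`.
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz).
#' @param win_s Smoothing window length (s, default 0.5).
#' @param order Polynomial order of the local fit; defaults to 3 for the
#'   `"baseline"` method and 1 for `"power"` (a higher-order fit rings
#'   negative around activity bursts and biases the quiet floor).
#' @param method `"baseline"` or `"power"` (see above).
#' @param quiet_quantile Quantile of the power profile taken as the noise
#'   floor (`"power"` method only, default 0.25: below the active fraction
#'   of burst-like signals but high enough to be robust to smoothing
#'   ripple).
#' @return SNR in dB.
#' @export
compute_snr <- function(x, fs, win_s = 0.5, order = NULL,
                        method = c("baseline", "power"), quiet_quantile = 0.25) {
  method <- match.arg(method)
  if (is.null(order)) order <- if (method == "baseline") 3 else 1
  n <- as.integer(round(win_s * fs))
  if (n %% 2 == 0) n <- n + 1L
  n <- max(n, order + 2L + ((order + 2L) %% 2 == 0L)) # odd, > order
  stopifnot(length(x) >= 2 * n)
  # centre row of the Savitzky-Golay projection = symmetric FIR kernel;
  # statistics use the interior, where the local polynomial fit is exact
  w <- signal::sgolay(p = order, n = n)[(n + 1) / 2, ]
  core <- ((n + 1) / 2):(length(x) - (n - 1) / 2)
  if (method == "baseline") {
    base <- fir_smooth_cpp(x, w)[core]
    p_sig <- mean(base^2)
    p_noise <- mean((x[core] - base)^2)
  } else {
    p <- fir_smooth_cpp(x^2, w)[core]
    p_noise <- max(stats::quantile(p, quiet_quantile, names = FALSE), 0)
    p_sig <- max(mean(p) - p_noise, 0)
  }
  if (p_noise <= 1e-20 * p_sig) return(Inf) # residual at rounding level
  10 * log10(p_sig / p_noise)
}

#' Preprocess a recording onto the common 128 Hz time base
#'
#' Runs the full conditioning chain: zero-phase filtering
#' ([apply_filters()]), sEMG resampling to the ECG rate
#' ([resample_semg()]), spike replacement ([despike()]) and per-channel
#' SNR quantification ([compute_snr()]).
#'
#' @param rec A [wean_recording()].
#' @param cfg A [wean_config()].
#' @return An object of class `wean_clean`: an 8-column matrix `channels`
#'   (leadI, leadII, leadIII, ch1-ch5) at `fs = 128` Hz, per-channel `snr`
#'   in dB, and provenance.
#' @export
preprocess_recording <- function(rec, cfg = wean_config()) {
  filt <- apply_filters(rec, cfg)
  semg128 <- do.call(cbind, lapply(1:5, function(j)
    resample_semg(filt$semg[, j], fs_in = rec$fs_emg, fs_out = rec$fs_ecg)))
  n <- min(nrow(filt$ecg), nrow(semg128))
  channels <- cbind(filt$ecg[seq_len(n), ], semg128[seq_len(n), ])
  # despike the sEMG channels only: on ECG the QRS complexes themselves sit
  # tens of MADs above baseline and a robust spike rule would excise them
  n_spikes <- integer(ncol(channels))
  for (j in 4:8) {
    d <- despike(channels[, j], cfg$despike_z)
    n_spikes[j] <- attr(d, "n_replaced")
    channels[, j] <- d
  }
  # raw channels are burst-like broadband: quiet-floor power SNR
  snr <- apply(channels, 2, compute_snr, fs = rec$fs_ecg, method = "power")
  structure(list(
    patient_id = rec$patient_id, group = rec$group,
    channels = channels, fs = rec$fs_ecg,
    duration = n / rec$fs_ecg,
    snr = snr, n_spikes = n_spikes,
    provenance = c(filt$meta$provenance,
                   sprintf("sEMG resampled %g -> %g Hz; despike z=%g",
                           rec$fs_emg, rec$fs_ecg, cfg$despike_z))
  ), class = "wean_clean")
}

#' @export
print.wean_clean <- function(x, ...) {
  cat(sprintf("<wean_clean> patient %s (%s), 8 channels @ %g Hz, %.1f s\n",
              x$patient_id, x$group, x$fs, x$duration))
  cat("  SNR (dB):", paste(sprintf("%s=%.1f", names(x$snr), x$snr), collapse = " "), "\n")
  invisible(x)
}
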