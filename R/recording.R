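#' Construct a raw weaning recording
#'
#' A `wean_recording` bundles one patient's simultaneous 3-lead ECG and
#' 5-channel diaphragmatic surface EMG. ECG leads are sampled at 128 Hz and
#' sEMG channels at 1 kHz, the acquisition setup the analysis chain assumes.
#' Channel order is canonical and never permuted: ECG leads I, II, III then
#' sEMG channels 1-5.
#'
#' @param patient_id Character scalar identifying the patient.
#' @param group Outcome label: `"success"`, `"failure"` or `"unknown"`.
#' @param ecg Numeric matrix, samples x 3 (leads I, II, III), in mV.
#' @param semg Numeric matrix, samples x 5 (channels 1-5), in mV.
#' @param fs_ecg ECG sampling rate in Hz (default 128).
#' @param fs_emg sEMG sampling rate in Hz (default 1000).
#' @param meta Optional named list of free-form metadata.
#'
#' @return An object of class `wean_recording`.
#' @export
wean_recording <- function(patient_id, group = c("unknown", "success", "failure"),
                           ecg, semg, fs_ecg = 128, fs_emg = 1000, meta = list()) {
  group <- match.arg(group, c("unknown", "success", "failure"))
  ecg <- as.matrix(ecg)
  semg <- as.matrix(semg)
  if (ncol(ecg) != 3L) stop("channel set incomplete: need 3 ECG leads")
  if (ncol(semg) != 5L) stop("channel set incomplete: need 5 sEMG channels")
  if (fs_ecg <= 0 || fs_emg <= 0) stop("sampling rates must be strictly positive")
  dur_ecg <- nrow(ecg) / fs_ecg
  dur_emg <- nrow(semg) / fs_emg
  # durations must agree to within one sample of the slower stream
  if (abs(dur_ecg - dur_emg) > 1 / min(fs_ecg, fs_emg) + 1e-9)
    stop("ECG and sEMG durations inconsistent with sampling rates")
  colnames(ecg) <- c("leadI", "leadII", "leadIII")
  colnames(semg) <- paste0("ch", 1:5)
  structure(list(
    patient_id = as.character(patient_id),
    group = group,
    ecg = ecg, semg = semg,
    fs_ecg = fs_ecg, fs_emg = fs_emg,
    duration = dur_ecg,
    meta = meta
  ), class = "wean_recording")
}

#' @export
print.wean_recording <- function(x, ...) {
  cat(sprintf("<wean_recording> patient %s (%s)\n", x$patient_id, x$group))
  cat(sprintf("  ECG : 3 leads @ %g Hz, %d samples\n", x$fs_ecg, nrow(x$ecg)))
  cat(sprintf("  sEMG: 5 channels @ %g Hz, %d samples\n", x$fs_emg, nrow(x$semg)))
  cat(sprintf("  duration: %.1f s\n", x$duration))
  invisible(x)
}

#' Analysis configuration for the weaning pipeline
#'
#' Collects every tunable constant of the analysis chain in one validated
#' object: filter cutoffs, the common analysis rate of the derived signals,
#' the time-varying window scheme, entropy settings, spectral band edges,
#' feature-selection thresholds and classifier-evaluation settings.
#'
#' Defaults follow standard practice for cardiorespiratory surface
#' recordings: 60 Hz notch; 0.05 Hz (ECG) and 20 Hz (sEMG) high-pass;
#' derived signals on a common 4 Hz grid; 300-s analysis windows with 50%
#' overlap; entropy with embedding length `m = 2` and tolerance
#' `0.15 x SD`; LF = 0.04-0.15 Hz and HF = 0.15-0.4 Hz bands; selection at
#' `alpha = 0.05` and Spearman `|rho| < 0.6`; polynomial-kernel SVM of
#' degree 5; 1000 stratified 70/30 evaluation splits.
#'
#' @param notch_hz Mains notch frequency (Hz).
#' @param notch_q Notch quality factor (centre frequency / -3 dB width).
#' @param hp_ecg_hz,hp_emg_hz High-pass cutoffs for ECG and sEMG (Hz).
#' @param filter_order Butterworth order for the high-pass filters.
#' @param fa Common analysis rate of the derived signals (Hz).
#' @param window_s Outer analysis-window length (s).
#' @param overlap Window overlap fraction, in (0, 1).
#' @param coh_segment_s Welch sub-segment length used for coherence within
#'   each outer window (s).
#' @param entropy_m Embedding length for ApEn/SampEn.
#' @param entropy_r Tolerance multiplier applied to the per-window SD.
#' @param lf,hf Two-element band edges (Hz), LF below HF, non-overlapping.
#' @param coh_fixed_freqs Fixed frequencies (Hz) at which point coherence
#'   values are catalogued.
#' @param alpha Significance level of the group-difference filter.
#' @param rho_max Maximum tolerated absolute Spearman correlation.
#' @param svm_degree Polynomial kernel degree.
#' @param svm_cost SVM regularisation constant.
#' @param knn_k Number of neighbours (odd).
#' @param knn_metric KNN distance metric (see [train_predict()]).
#' @param n_runs Number of repeated stratified evaluation splits.
#' @param split_frac Training fraction of each split.
#' @param despike_z Robust z-score threshold for spike replacement.
#' @param emgi_quantile Rectified-amplitude quantile defining the EMGi peak
#'   threshold.
#'
#' @return A validated list of class `wean_config`.
#' @export
wean_config <- function(notch_hz = 60, notch_q = 35,
                        hp_ecg_hz = 0.05, hp_emg_hz = 20, filter_order = 4,
                        fa = 4,
                        window_s = 300, overlap = 0.5, coh_segment_s = 60,
                        entropy_m = 2, entropy_r = 0.15,
                        lf = c(0.04, 0.15), hf = c(0.15, 0.4),
                        coh_fixed_freqs = c(0.02, 0.04),
                        alpha = 0.05, rho_max = 0.6,
                        svm_degree = 5, svm_cost = 1,
                        knn_k = 5, knn_metric = "spearman",
                        n_runs = 1000, split_frac = 0.7,
                        despike_z = 8, emgi_quantile = 0.7) {
  stopifnot(length(lf) == 2, length(hf) == 2)
  if (!(overlap > 0 && overlap < 1)) stop("overlap fraction must lie in (0, 1)")
  if (!(lf[1] < lf[2] && hf[1] < hf[2] && lf[2] <= hf[1]))
    stop("LF and HF bands must be ordered and non-overlapping")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (!(rho_max > 0 && rho_max <= 1)) stop("rho_max must lie in (0, 1]")
  if (fa < 2 * hf[2]) stop("analysis rate fa must be at least twice the HF upper edge")
  if (entropy_m < 1 || entropy_r <= 0) stop("invalid entropy settings")
  if (knn_k < 1 || knn_k %% 2 == 0) stop("knn_k must be odd and >= 1")
  if (svm_degree < 1) stop("svm_degree must be >= 1")
  if (!(split_frac > 0 && split_frac < 1)) stop("split_frac must lie in (0, 1)")
  structure(as.list(environment()), class = "wean_config")
}
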