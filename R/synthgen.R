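#' Specification of a synthetic weaning cohort
#'
#' Describes a two-group cohort of simulated SBT recordings with the group
#' contrasts the analysis is designed to detect: successful weaners get a
#' deeper respiratory modulation of the QRS amplitude (the ECG-derived
#' respiration substrate), stronger phase locking between diaphragmatic
#' bursts and respiration, and more irregular (higher-entropy) breath-to-
#' breath burst amplitudes; failing weaners get a higher diaphragmatic
#' burst amplitude with more regular, weakly locked bursts.
#'
#' Group-dependent parameters are length-2 vectors `(success, failure)`.
#' Defaults emulate a one-hour pressure-support trial: 60-min recordings,
#' 19 successful and 21 failing patients, 75 bpm mean heart rate with LF
#' and respiratory (HF) rate modulation, 18 breaths/min (0.3 Hz, inside
#' the HF band), and a 15 dB additive-noise floor.
#'
#' @param n_success,n_failure Group sizes.
#' @param duration Recording length in seconds (>= 600 for the spectral
#'   stages, which need at least two 300-s windows).
#' @param mean_rr Mean RR interval (s).
#' @param rr_lf_depth,rr_lf_freq Fractional RR modulation depth and
#'   frequency (Hz) of the low-frequency (baroreflex-like) component.
#' @param rr_hf_depth Fractional RR modulation depth at the respiratory
#'   rate (respiratory sinus arrhythmia).
#' @param rr_jitter Per-group fractional white jitter SD of individual RR
#'   intervals (cardiac complexity contrast: lower in failure).
#' @param resp_rate Respiratory rate (Hz); must sit inside the HF band.
#' @param resp_jitter Per-group fractional slow wander of the respiratory
#'   rate (respiratory complexity contrast: lower in failure).
#' @param edr_depth Per-group QRS peak-to-peak modulation depth in [0, 1).
#' @param qrs_amp QRS peak amplitude (mV).
#' @param emg_burst_amp Per-group overall diaphragmatic activity level
#'   (mV; higher in failure).
#' @param emg_tonic Per-group tonic (non-respiratory) fraction of the
#'   activity envelope; failure is tonic-dominated.
#' @param emg_mod_depth Per-group depth of the respiratory burst
#'   modulation on top of the tonic level; success oscillates more deeply.
#' @param emg_irregularity Per-group fractional breath-to-breath burst
#'   amplitude variability.
#' @param emg_roughness Per-group within-breath envelope roughness
#'   (fractional fast fluctuation of the burst envelope; complexity
#'   contrast: higher in success).
#' @param coupling Per-group coupling in [0, 1] between respiratory phase
#'   and both the EMG bursts and the QRS modulation (coherence substrate).
#' @param snr_db Target additive-noise SNR (dB) for both modalities.
#' @param seed Integer cohort seed; per-patient seeds are derived from it.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_success = 19, n_failure = 21,
                        duration = 3600,
                        mean_rr = 0.8,
                        rr_lf_depth = 0.03, rr_lf_freq = 0.095,
                        rr_hf_depth = 0.04,
                        rr_jitter = c(success = 0.015, failure = 0.008),
                        resp_rate = 0.3,
                        resp_jitter = c(success = 0.14, failure = 0.02),
                        edr_depth = c(success = 0.35, failure = 0.10),
                        qrs_amp = 1.0,
                        emg_burst_amp = c(success = 0.20, failure = 0.35),
                        emg_tonic = c(success = 0.25, failure = 0.40),
                        emg_mod_depth = c(success = 1.0, failure = 0.55),
                        emg_irregularity = c(success = 0.30, failure = 0.03),
                        emg_roughness = c(success = 0.60, failure = 0.02),
                        coupling = c(success = 0.95, failure = 0.75),
                        snr_db = 15, seed = 1L) {
  g2 <- function(v) { v <- rep(v, length.out = 2); names(v) <- c("success", "failure"); v }
  edr_depth <- g2(edr_depth); emg_burst_amp <- g2(emg_burst_amp)
  emg_irregularity <- g2(emg_irregularity); coupling <- g2(coupling)
  emg_roughness <- g2(emg_roughness)
  emg_tonic <- g2(emg_tonic); emg_mod_depth <- g2(emg_mod_depth)
  rr_jitter <- g2(rr_jitter); resp_jitter <- g2(resp_jitter)
  if (n_success < 0 || n_failure < 0) stop("group sizes must be non-negative")
  if (any(edr_depth < 0 | edr_depth >= 1) || rr_lf_depth < 0 || rr_lf_depth >= 1 ||
      rr_hf_depth < 0 || rr_hf_depth >= 1)
    stop("modulation depths must lie in [0, 1)")
  if (resp_rate < 0.15 || resp_rate > 0.4)
    warning("respiratory rate outside the HF band (0.15-0.4 Hz)")
  if (any(coupling < 0 | coupling > 1)) stop("coupling must lie in [0, 1]")
  structure(as.list(environment())[names(formals(cohort_spec))], class = "cohort_spec")
}

# shared respiratory phase: breath-by-breath construction, returned as a
# function of time so both modalities sample the identical phase. Each
# breath period gets a slow (AR(1) across breaths) rate wander plus white
# per-breath jitter; the phase is linear within a breath and crosses 2*pi*k
# at the k-th breath onset.
make_resp_phase <- function(spec, group = "success", fs_grid = 4) {
  nb <- as.integer(ceiling(spec$duration * spec$resp_rate * 2) + 5L)
  w <- stats::rnorm(nb)
  s <- stats::filter(w, 0.9, method = "recursive") * sqrt(1 - 0.9^2)
  slow <- 0.5 * spec$resp_jitter[group] # split the budget: wander + jitter
  breath <- spec$resp_jitter[group]
  T_k <- (1 + breath * stats::rnorm(nb)) / (spec$resp_rate * (1 + slow * as.numeric(s)))
  T_k <- pmax(T_k, 0.3 / spec$resp_rate)
  onsets <- c(0, cumsum(T_k))
  stats::approxfun(onsets, 2 * pi * (0:nb), rule = 2)
}

ricker <- function(t, width) (1 - (t / width)^2) * exp(-t^2 / (2 * width^2))

#' Generate synthetic ECG leads
#'
#' A QRS-like (Ricker wavelet) train whose beat times follow an RR process
#' with LF and respiratory modulation, and whose peak-to-peak amplitude is
#' modulated at the respiratory phase with the group's depth — the
#' substrate from which ECG-derived respiration is later measured. Lead II
#' carries the full modulation depth. Band-limited noise is added at the
#' spec's target SNR.
#'
#' @param spec A [cohort_spec()].
#' @param group `"success"` or `"failure"`.
#' @param resp_phase Function of time returning the shared respiratory
#'   phase (from the internal generator); created if `NULL`.
#' @param fs Sampling rate (Hz, default 128).
#' @param fa Analysis rate the respiratory rate must stay below half of.
#' @return Matrix samples x 3 (leads I, II, III), in mV.
#' @export
generate_ecg <- function(spec, group = "success", resp_phase = NULL, fs = 128, fa = 4) {
  if (spec$resp_rate >= fa / 2) stop("respiratory rate at or above the analysis Nyquist")
  if (is.null(resp_phase)) resp_phase <- make_resp_phase(spec, group)
  dur <- spec$duration
  # beat times from the modulated RR process
  tk <- numeric(ceiling(dur / (spec$mean_rr * 0.5)))
  t <- 0; k <- 0
  while (t < dur) {
    k <- k + 1
    tk[k] <- t
    rr <- spec$mean_rr * (1 +
      spec$rr_lf_depth * sin(2 * pi * spec$rr_lf_freq * t) +
      spec$rr_hf_depth * sin(resp_phase(t)) +
      spec$rr_jitter[group] * stats::rnorm(1))
    t <- t + max(rr, 0.27)
  }
  tk <- tk[seq_len(k)]
  n <- as.integer(round(dur * fs))
  depth <- spec$edr_depth[group]
  # QRS amplitude rides the shared respiratory phase directly (EDR is the
  # respiration surrogate; coupling degrades only the diaphragmatic side)
  amp_k <- 1 + depth * sin(resp_phase(tk))
  lead_gain <- c(leadI = 0.6, leadII = 1.0, leadIII = 0.8)
  lead_depth <- c(0.5, 1.0, 0.7) # EDR is strongest on lead II
  wt <- seq(-0.06, 0.06, by = 1 / fs)
  wave <- ricker(wt, 0.012)
  ecg <- matrix(0, n, 3)
  idx0 <- round(tk * fs) + 1
  off <- seq_along(wt) - (which.max(wave))
  for (L in 1:3) {
    a <- spec$qrs_amp * lead_gain[L] * (1 + lead_depth[L] * (amp_k - 1))
    for (b in seq_along(tk)) {
      ii <- idx0[b] + off
      ok <- ii >= 1 & ii <= n
      ecg[ii[ok], L] <- ecg[ii[ok], L] + a[b] * wave[ok]
    }
  }
  # band-limited additive noise at the target SNR; one common noise level
  # (set by the mean clean power across leads) so weaker leads carry
  # proportionally more noise, as a shared-electronics floor would
  bp <- signal::butter(2, c(0.5, 40) / (fs / 2), type = "pass")
  p_ref <- mean(ecg^2)
  snr_true <- numeric(3)
  for (L in 1:3) {
    noise <- zerophase(bp, stats::rnorm(n), pad = fs)
    noise <- noise * sqrt(p_ref * 10^(-spec$snr_db / 10) / mean(noise^2))
    snr_true[L] <- 10 * log10(mean(ecg[, L]^2) / mean(noise^2))
    ecg[, L] <- ecg[, L] + noise
  }
  colnames(ecg) <- c("leadI", "leadII", "leadIII")
  attr(ecg, "beat_times") <- tk
  attr(ecg, "snr_db_true") <- snr_true
  ecg
}

#' Generate synthetic diaphragmatic sEMG channels
#'
#' Broadband (20-450 Hz) activity amplitude-modulated by respiratory
#' bursts locked to the shared respiratory phase with the group's coupling
#' coefficient. Channel 3 carries the strongest respiratory locking
#' (mirroring the xiphisternal electrode); breath-to-breath burst
#' amplitudes vary with the group's irregularity. Additive noise is scaled
#' to the spec's target SNR.
#'
#' @inheritParams generate_ecg
#' @param fs Sampling rate (Hz, default 1000).
#' @return Matrix samples x 5 (channels 1-5), in mV.
#' @export
generate_semg <- function(spec, group = "success", resp_phase = NULL, fs = 1000) {
  if (is.null(resp_phase)) resp_phase <- make_resp_phase(spec, group)
  dur <- spec$duration
  n <- as.integer(round(dur * fs))
  amp <- spec$emg_burst_amp[group]
  tonic <- spec$emg_tonic[group]
  depth <- spec$emg_mod_depth[group]
  irr <- spec$emg_irregularity[group]
  rough <- spec$emg_roughness[group]
  coup <- spec$coupling[group]
  # envelopes are smooth: build on a 4 Hz grid and interpolate
  fsl <- 4
  tl <- seq(0, dur, by = 1 / fsl)
  burst_env <- function(ph) {
    cyc <- floor(ph / (2 * pi))
    ncyc <- max(cyc) - min(cyc) + 1L
    a_k <- pmax(1 + irr * stats::rnorm(ncyc), 0.05)
    gate <- pmax(sin(ph), 0)^2 # inspiratory half of each cycle
    gate * a_k[cyc - min(cyc) + 1L]
  }
  # envelope-domain mixing: a burst train locked to the shared phase and an
  # unlocked train from an independent phase process; the locked weight is
  # coupling x per-channel locking, so coupling 1 gives perfect locking on
  # channel 3 and coupling 0 leaves every channel independent of the ECG
  e_lock <- burst_env(resp_phase(tl))
  e_free <- burst_env(make_resp_phase(spec, group)(tl))
  # within-breath roughness: white fractional envelope fluctuation on the
  # envelope grid (broadband up to the analysis Nyquist, so it reads as
  # genuine short-scale unpredictability downstream)
  eta <- stats::rnorm(length(tl))
  lock_w <- c(0.45, 0.65, 1.0, 0.65, 0.45) # channel 3 dominates locking
  gain <- c(0.7, 0.85, 1.0, 0.85, 0.7)
  tt <- (seq_len(n) - 1) / fs
  # broadband 20-450 Hz carrier with most power below the 64 Hz analysis
  # Nyquist, so the designed activity envelope survives resampling
  bp_lo <- signal::butter(4, c(20, 60) / (fs / 2), type = "pass")
  bp_hi <- signal::butter(4, c(60, 450) / (fs / 2), type = "pass")
  semg <- matrix(0, n, 5)
  # absolute electrode/amplifier noise floor: calibrated so the quieter
  # (success-level) activity meets the target SNR; louder channels are
  # proportionally cleaner, as with a fixed instrumentation floor
  env_ref2 <- mean((spec$emg_tonic["success"] +
                      spec$emg_mod_depth["success"] * e_lock)^2)
  # the >60 Hz band is removed by the 128 Hz resampling before any analysis,
  # so one high-band realisation is shared across channels
  c_hi <- zerophase(bp_hi, stats::rnorm(n), pad = fs %/% 4)
  c_hi <- c_hi / stats::sd(c_hi)
  snr_true <- numeric(5)
  for (ch in 1:5) {
    wl <- coup * lock_w[ch]
    gate_mix <- wl * e_lock + (1 - wl) * e_free
    env <- pmax((tonic + depth * gate_mix) * (1 + rough * eta), 0)
    env_t <- stats::approx(tl, env, tt, rule = 2, ties = "ordered")$y
    c_lo <- zerophase(bp_lo, stats::rnorm(n), pad = fs %/% 4)
    # stabilise the low band's local amplitude so the activity envelope of
    # the product is the designed envelope, not envelope x Rayleigh fading
    loc <- movavg(c_lo^2, 51L)
    c_lo <- c_lo / sqrt(pmax(loc, 1e-12))
    carrier <- sqrt(0.7) * c_lo / stats::sd(c_lo) + sqrt(0.3) * c_hi
    x <- amp * gain[ch] * env_t * carrier
    p_floor <- (spec$emg_burst_amp["success"] * gain[ch])^2 * env_ref2
    noise <- stats::rnorm(n)
    noise <- noise * sqrt(p_floor * 10^(-spec$snr_db / 10) / mean(noise^2))
    snr_true[ch] <- 10 * log10(mean(x^2) / mean(noise^2))
    semg[, ch] <- x + noise
  }
  colnames(semg) <- paste0("ch", 1:5)
  attr(semg, "snr_db_true") <- snr_true
  semg
}

#' Generate one synthetic patient recording
#'
#' @inheritParams generate_ecg
#' @param patient_id Identifier for the generated patient.
#' @param seed Integer seed; the recording is a deterministic function of
#'   `(spec, group, seed)`.
#' @return A [wean_recording()].
#' @export
generate_recording <- function(spec, group, patient_id = "synth", seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  phase <- make_resp_phase(spec, group)
  ecg <- generate_ecg(spec, group, phase)
  semg <- generate_semg(spec, group, phase)
  wean_recording(patient_id, group, ecg, semg,
                 meta = list(seed = seed, spec_snr_db = spec$snr_db,
                             snr_db_true = c(attr(ecg, "snr_db_true"),
                                             attr(semg, "snr_db_true"))))
}

#' Generate a labelled synthetic cohort
#'
#' Produces `n_success + n_failure` recordings with per-patient seeds
#' derived deterministically from the cohort seed, success patients first.
#'
#' @param spec A [cohort_spec()].
#' @return List of [wean_recording()] objects.
#' @export
generate_cohort <- function(spec) {
  groups <- c(rep("success", spec$n_success), rep("failure", spec$n_failure))
  lapply(seq_along(groups), function(i) {
    generate_recording(spec, groups[i],
                       patient_id = sprintf("P%03d", i),
                       seed = derive_seed(spec$seed, i))
  })
}

#' Base parameters targeted by the synthetic group contrasts
#'
#' The ten base parameters whose group difference the default
#' [cohort_spec()] is designed to induce: EDR modulation power and peak
#' (deeper QRS amplitude modulation in success), EMG-envelope band powers
#' (deeper absolute oscillation in success), EDR-EMGe and HRV-EMGe
#' coherence (stronger cardiorespiratory locking in success), and
#' envelope/cardiac complexity (higher in success). Their `mean_` summary
#' statistics are the expected catches of the significance filter on
#' synthetic cohorts.
#'
#' @return Character vector of 10 base parameter names.
#' @export
informative_parameters <- function() {
  c("PHFEDR", "HpHFEDR", "PLFEMGe", "PHFEMGe",
    "PcohEDREMGe", "RMScohEDREMGe", "PcohHRVEMGe",
    "ApEnEMGe", "SampEnHRV", "ApEnHRV")
}

# save/restore RNG state so generators are pure given their seed
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
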