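# Welch-averaged auto- and cross-spectra on Hann-tapered, mean-removed
# segments. One-sided density normalisation: integral of the PSD over
# [0, Nyquist] approximates the signal variance.
welch_spectra <- function(x, y = NULL, fs, seg_len_s, overlap = 0.5) {
  L <- as.integer(round(seg_len_s * fs))
  n <- length(x)
  if (n < L) stop("series shorter than one segment")
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L)) # periodic Hann
  u <- sum(w^2)
  nf <- L %/% 2 + 1L
  sxx <- numeric(nf); syy <- numeric(nf); sxy <- complex(nf)
  for (s in starts) {
    xs <- x[s:(s + L - 1L)]
    X <- stats::fft(w * (xs - mean(xs)))[1:nf]
    sxx <- sxx + Mod(X)^2
    if (!is.null(y)) {
      ys <- y[s:(s + L - 1L)]
      Y <- stats::fft(w * (ys - mean(ys)))[1:nf]
      syy <- syy + Mod(Y)^2
      sxy <- sxy + Conj(X) * Y
    }
  }
  ns <- length(starts)
  scale <- 1 / (fs * u * ns)
  onesided <- c(1, rep(2, nf - 2L), if (L %% 2 == 0) 1 else 2)
  freq <- (0:(nf - 1L)) * fs / L
  list(freq = freq, sxx = sxx * scale * onesided,
       syy = if (!is.null(y)) syy * scale * onesided,
       sxy = if (!is.null(y)) sxy * scale * onesided,
       n_segments = ns, seg_len_s = seg_len_s, overlap = overlap)
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: Hann-tapered, mean-removed segments of
#' `seg_len_s` seconds with the given overlap, one-sided density
#' normalisation (the integral over frequency approximates the variance).
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz).
#' @param seg_len_s Segment length (s).
#' @param overlap Overlap fraction in `[0, 1)` (default 0.5).
#' @return Object of class `wean_psd`: `freq` (Hz), `power` (x^2/Hz),
#'   `n_segments`, `seg_len_s`, `overlap`.
#' @export
welch_psd <- function(x, fs, seg_len_s, overlap = 0.5) {
  sp <- welch_spectra(x, NULL, fs, seg_len_s, overlap)
  structure(list(freq = sp$freq, power = sp$sxx, n_segments = sp$n_segments,
                 seg_len_s = seg_len_s, overlap = overlap, taper = "hann"),
            class = "wean_psd")
}

#' Band parameters of a spectrum
#'
#' Summarises a (power or coherence) spectrum over a closed frequency band
#' by five descriptors: the highest in-band value `Hp`, its frequency `Fp`
#' (ties broken toward the lowest frequency), the trapezoidal band
#' integral `P`, and the up/down slopes `Us = (Hp - S(f_lo))/(Fp - f_lo)`
#' and `Ds = (S(f_hi) - Hp)/(f_hi - Fp)` from the band edges to the peak.
#' If the peak sits on a band edge the corresponding slope is 0 and the
#' result is flagged.
#'
#' @param psd A `wean_psd` (or any list with `freq` and `power`).
#' @param band Length-2 numeric band edges (Hz).
#' @return List with `Hp`, `Fp`, `P`, `Us`, `Ds` and `edge_peak` flag.
#' @export
band_parameters <- function(psd, band) {
  stopifnot(length(band) == 2, band[1] < band[2])
  idx <- which(psd$freq >= band[1] - 1e-12 & psd$freq <= band[2] + 1e-12)
  if (length(idx) < 3) stop("fewer than 3 bins in band")
  f <- psd$freq[idx]; s <- psd$power[idx]
  imax <- which.max(s) # which.max takes the first (lowest-frequency) tie
  Hp <- s[imax]; Fp <- f[imax]
  P <- trapz(f, s)
  f_lo <- f[1]; f_hi <- f[length(f)]
  edge <- imax == 1L || imax == length(f)
  Us <- if (imax == 1L) 0 else (Hp - s[1]) / (Fp - f_lo)
  Ds <- if (imax == length(f)) 0 else (s[length(s)] - Hp) / (f_hi - Fp)
  list(Hp = Hp, Fp = Fp, P = P, Us = Us, Ds = Ds, edge_peak = edge)
}

#' Magnitude-squared coherence
#'
#' Welch-averaged coherence `K(f) = |Sxy|^2 / (Sxx Syy)`, in [0, 1].
#' At least four averaged segments are required (with a single segment the
#' estimate is identically 1).
#'
#' @param x,y Equal-length numeric series.
#' @param fs Sampling rate (Hz).
#' @param seg_len_s Segment length (s).
#' @param overlap Overlap fraction (default 0.5).
#' @return Object of class `wean_coh`: `freq`, `coh`, `n_segments`.
#' @export
msc <- function(x, y, fs, seg_len_s, overlap = 0.5) {
  stopifnot(length(x) == length(y))
  sp <- welch_spectra(x, y, fs, seg_len_s, overlap)
  if (sp$n_segments < 4) stop("insufficient segments for coherence")
  K <- Mod(sp$sxy)^2 / (sp$sxx * sp$syy)
  K[!is.finite(K)] <- 0
  if (any(K < -1e-12 | K > 1 + 1e-12)) stop("coherence outside [0,1] beyond round-off")
  K <- pmin(pmax(K, 0), 1)
  structure(list(freq = sp$freq, coh = K, n_segments = sp$n_segments,
                 seg_len_s = seg_len_s, overlap = overlap),
            class = "wean_coh")
}

#' Coherence band parameters
#'
#' The five band descriptors of [band_parameters()] applied to a coherence
#' spectrum, plus the in-band root-mean-square coherence and the coherence
#' value at fixed catalogue frequencies (nearest grid bin).
#'
#' @param K A `wean_coh` from [msc()].
#' @param band Length-2 band edges (Hz).
#' @param fixed_freqs Frequencies (Hz) at which point values are read.
#' @return List with `Pcoh`, `Hpcoh`, `Fpcoh`, `Uscoh`, `Dscoh`, `RMScoh`
#'   and one `Hpcoh_<f>` entry per fixed frequency.
#' @export
coherence_parameters <- function(K, band, fixed_freqs = c(0.02, 0.04)) {
  bp <- band_parameters(list(freq = K$freq, power = K$coh), band)
  idx <- which(K$freq >= band[1] - 1e-12 & K$freq <= band[2] + 1e-12)
  out <- list(Pcoh = bp$P, Hpcoh = bp$Hp, Fpcoh = bp$Fp,
              Uscoh = bp$Us, Dscoh = bp$Ds,
              RMScoh = sqrt(mean(K$coh[idx]^2)))
  for (f0 in fixed_freqs) {
    if (f0 < min(K$freq) - 1e-12 || f0 > max(K$freq) + 1e-12)
      stop("fixed frequency outside the coherence grid")
    j <- which.min(abs(K$freq - f0))
    out[[sprintf("Hpcoh_%gHz", f0)]] <- K$coh[j]
  }
  out
}

# canonical signal and pair labels
.dsig_names <- c("EDR", "HRV", "EMGe", "EMGi")
.coh_pairs <- list(EDREMGe = c("EMGe", "EDR"), HRVEMGe = c("EMGe", "HRV"),
                   EDREMGi = c("EMGi", "EDR"), HRVEMGi = c("EMGi", "HRV"))

#' Time-varying spectral and coherence parameters
#'
#' Slides an outer analysis window (default 300 s, 50% overlap) over the
#' derived signal set. Within each window it computes, per signal, the
#' modified periodogram of the whole window and its LF/HF band parameters,
#' and, per signal pair, Welch/MSC from sub-segments (default 60 s, 50%
#' overlap, giving 9 averages) parameterised over the combined modulation
#' band. The result is one time series per base spectral/coherence
#' parameter.
#'
#' @param dset A `wean_derived` from [derive_signals()].
#' @param cfg A [wean_config()].
#' @return Object of class `wean_params`: `window_start` (s) and a
#'   windows x parameters numeric matrix `values` with canonical
#'   catalogue names.
#' @export
windowed_params <- function(dset, cfg = wean_config()) {
  fa <- dset$fa
  dur <- length(dset$t) / fa
  starts <- window_starts(dur, cfg$window_s, cfg$overlap)
  if (length(starts) < 2) stop("recording provides fewer than 2 analysis windows")
  Lw <- as.integer(cfg$window_s * fa)
  cband <- c(cfg$lf[1], cfg$hf[2])
  rows <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    i0 <- as.integer(round(starts[k] * fa)) + 1L
    idx <- i0:(i0 + Lw - 1L)
    vals <- c()
    for (sig in .dsig_names) {
      x <- dset[[sig]][idx]
      psd <- welch_psd(x, fa, seg_len_s = cfg$window_s, overlap = cfg$overlap)
      for (bn in c("LF", "HF")) {
        bp <- band_parameters(psd, if (bn == "LF") cfg$lf else cfg$hf)
        nm <- paste0(c("Hp", "P", "Fp", "Us", "Ds"), bn, sig)
        v <- unlist(bp[c("Hp", "P", "Fp", "Us", "Ds")])
        names(v) <- nm
        vals <- c(vals, v)
      }
    }
    for (pn in names(.coh_pairs)) {
      pr <- .coh_pairs[[pn]]
      K <- msc(dset[[pr[1]]][idx], dset[[pr[2]]][idx], fa,
               seg_len_s = cfg$coh_segment_s, overlap = cfg$overlap)
      cp <- coherence_parameters(K, cband, cfg$coh_fixed_freqs)
      v <- unlist(cp[c("Pcoh", "RMScoh", "Fpcoh", "Hpcoh", "Uscoh", "Dscoh")])
      names(v) <- paste0(c("Pcoh", "RMScoh", "Fpcoh", "Hpcoh", "Uscoh", "Dscoh"), pn)
      fx <- unlist(cp[grep("^Hpcoh_", names(cp))])
      names(fx) <- paste0("Hpcoh", pn, "(", sub("Hpcoh_", "", names(fx)), ")")
      vals <- c(vals, v, fx)
    }
    rows[[k]] <- vals
  }
  values <- do.call(rbind, rows)
  structure(list(window_start = starts, values = values,
                 patient_id = dset$patient_id, group = dset$group),
            class = "wean_params")
}
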