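#' Approximate entropy
#'
#' Regularity statistic of a series: templates of length `m` are compared
#' with every template (including themselves) under the Chebyshev
#' (maximum-component) distance with tolerance `r_abs`, and ApEn is the
#' difference `Phi_m - Phi_(m+1)` of the mean log match frequencies.
#' Self-matching guarantees non-zero counts, so ApEn is always finite.
#'
#' @param x Numeric series (length > m + 1).
#' @param m Embedding (template) length (default 2).
#' @param r_abs Absolute tolerance (same units as `x`).
#' @return Non-negative scalar.
#' @export
apen <- function(x, m = 2, r_abs) {
  apen_cpp(as.numeric(x), as.integer(m), r_abs)
}

#' Sample entropy
#'
#' `-log(A/B)` where `B` counts pairs of distinct `m`-templates within
#' tolerance `r_abs` (Chebyshev distance, self-matches excluded) and `A`
#' counts those whose `(m+1)`-extensions still match. Returns `NA` when
#' either count is zero (the statistic is undefined).
#'
#' @inheritParams apen
#' @return Non-negative scalar, or `NA` if undefined.
#' @export
sampen <- function(x, m = 2, r_abs) {
  sampen_cpp(as.numeric(x), as.integer(m), r_abs)
}

#' Time-varying entropy of the derived signals
#'
#' Slides the same outer windows as [windowed_params()] over the four
#' derived signals and computes sample and approximate entropy per window,
#' with the tolerance recomputed per window as `entropy_r` times that
#' window's standard deviation.
#'
#' @param dset A `wean_derived` from [derive_signals()].
#' @param cfg A [wean_config()].
#' @return Object of class `wean_params` with 8 columns (SampEn/ApEn x
#'   EDR/HRV/EMGe/EMGi); undefined windows are `NA` with a count in
#'   `attr(values, "n_undefined")`.
#' @export
windowed_entropy <- function(dset, cfg = wean_config()) {
  fa <- dset$fa
  dur <- length(dset$t) / fa
  starts <- window_starts(dur, cfg$window_s, cfg$overlap)
  Lw <- as.integer(cfg$window_s * fa)
  if (Lw < 100) stop("entropy windows need at least 100 samples")
  nm <- c(paste0("SampEn", .dsig_names), paste0("ApEn", .dsig_names))
  values <- matrix(NA_real_, length(starts), length(nm), dimnames = list(NULL, nm))
  for (k in seq_along(starts)) {
    i0 <- as.integer(round(starts[k] * fa)) + 1L
    idx <- i0:(i0 + Lw - 1L)
    for (sig in .dsig_names) {
      x <- dset[[sig]][idx]
      s <- stats::sd(x)
      if (s == 0) { # constant window: perfectly regular
        values[k, paste0("SampEn", sig)] <- 0
        values[k, paste0("ApEn", sig)] <- 0
      } else {
        r_abs <- cfg$entropy_r * s
        values[k, paste0("SampEn", sig)] <- sampen(x, cfg$entropy_m, r_abs)
        values[k, paste0("ApEn", sig)] <- apen(x, cfg$entropy_m, r_abs)
      }
    }
  }
  attr(values, "n_undefined") <- sum(is.na(values))
  structure(list(window_start = starts, values = values,
                 patient_id = dset$patient_id, group = dset$group),
            class = "wean_params")
}
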