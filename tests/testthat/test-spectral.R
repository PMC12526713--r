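test_that("Welch PSD has correct segmentation, normalisation and peak location", {
  fa <- 4
  x <- rnorm(3600 * fa, sd = sqrt(2))
  psd <- welch_psd(x, fa, seg_len_s = 300, overlap = 0.5)
  expect_equal(psd$n_segments, 23) # 1 + (3600-300)/150
  df <- diff(psd$freq[1:2])
  expect_equal(sum(psd$power) * df, 2, tolerance = 0.05 * 2) # Parseval
  t <- seq(0, 600 - 1 / fa, by = 1 / fa)
  psd2 <- welch_psd(sin(2 * pi * 0.30 * t), fa, seg_len_s = 300)
  expect_equal(psd2$freq[which.max(psd2$power)], 0.30, tolerance = df + 1e-9)
  expect_error(welch_psd(rnorm(100), fa, seg_len_s = 300), "shorter than one segment")
})

test_that("band parameters match closed-form values on a constructed triangle", {
  f <- seq(0, 0.5, by = 0.01)
  A <- 3; f_lo <- 0.15; f_hi <- 0.40; fp <- 0.25
  s <- numeric(length(f))
  up <- f >= f_lo & f <= fp
  dn <- f > fp & f <= f_hi
  s[up] <- A * (f[up] - f_lo) / (fp - f_lo)
  s[dn] <- A * (f_hi - f[dn]) / (f_hi - fp)
  bp <- band_parameters(list(freq = f, power = s), c(f_lo, f_hi))
  expect_equal(bp$Hp, A)
  expect_equal(bp$Fp, fp)
  expect_equal(bp$Us, A / (fp - f_lo))
  expect_equal(bp$Ds, -A / (f_hi - fp))
  expect_equal(bp$P, 0.5 * A * (f_hi - f_lo), tolerance = 1e-12) # triangle area
  expect_false(bp$edge_peak)
  # flat spectrum: tie broken to the lowest in-band frequency, slope flagged 0
  flat <- band_parameters(list(freq = f, power = rep(2, length(f))), c(f_lo, f_hi))
  expect_equal(flat$Fp, f_lo)
  expect_equal(flat$Us, 0)
  expect_true(flat$edge_peak)
})

test_that("band parameters are scale-equivariant in power", {
  fa <- 4
  set.seed(21)
  x <- rnorm(2400)
  p1 <- welch_psd(x, fa, seg_len_s = 150)
  p2 <- welch_psd(3 * x, fa, seg_len_s = 150)
  b1 <- band_parameters(p1, c(0.15, 0.4))
  b2 <- band_parameters(p2, c(0.15, 0.4))
  expect_equal(b2$Hp / b1$Hp, 9, tolerance = 1e-9)
  expect_equal(b2$P / b1$P, 9, tolerance = 1e-9)
  expect_equal(b2$Fp, b1$Fp)
})

test_that("magnitude-squared coherence is bounded, symmetric and discriminates", {
  fa <- 4
  set.seed(22)
  x <- rnorm(1200)
  K1 <- msc(x, x, fa, seg_len_s = 60, overlap = 0.5)
  expect_true(all(abs(K1$coh - 1) < 1e-9)) # identical inputs
  # delayed copy + small noise: high coherence in band
  y <- c(0, x[-1200]) + rnorm(1200, sd = 0.05)
  K2 <- msc(x, y, fa, seg_len_s = 60)
  inb <- K2$freq >= 0.04 & K2$freq <= 0.4
  expect_gt(mean(K2$coh[inb]), 0.9)
  # symmetry
  K3 <- msc(y, x, fa, seg_len_s = 60)
  expect_equal(K2$coh, K3$coh, tolerance = 1e-12)
  # independent noise with 16 averaged segments: low mean coherence
  v <- replicate(20, {
    a <- rnorm(16 * 240 / 2); b <- rnorm(16 * 240 / 2)
    K <- msc(a, b, fa, seg_len_s = 60, overlap = 0.5)
    mean(K$coh[K$freq >= 0.04 & K$freq <= 0.4])
  })
  expect_lt(mean(v), 0.25)
  expect_error(msc(rnorm(240), rnorm(240), fa, seg_len_s = 60), "insufficient segments")
})

test_that("coherence parameters reduce to closed forms on constant spectra", {
  f <- seq(0, 2, by = 1 / 60)
  K1 <- structure(list(freq = f, coh = rep(1, length(f)), n_segments = 9), class = "wean_coh")
  cp <- coherence_parameters(K1, c(0.04, 0.4), fixed_freqs = c(0.02, 0.04))
  expect_equal(cp$RMScoh, 1)
  expect_equal(cp$Pcoh, 0.4 - f[f >= 0.04][1], tolerance = 1 / 60) # ~band width
  expect_equal(cp$`Hpcoh_0.02Hz`, 1)
  expect_equal(cp$`Hpcoh_0.04Hz`, 1)
  K5 <- structure(list(freq = f, coh = rep(0.5, length(f)), n_segments = 9), class = "wean_coh")
  expect_equal(coherence_parameters(K5, c(0.04, 0.4))$RMScoh, 0.5)
  expect_error(coherence_parameters(K1, c(0.04, 0.4), fixed_freqs = 5), "outside")
})

test_that("windowed parameterisation emits one value per window per base parameter", {
  fa <- 4
  set.seed(23)
  n <- 3600 * fa
  mk <- function() {
    b <- signal::butter(4, 0.3, type = "low")
    abs(zerophase(b, rnorm(n), pad = 100)) + 0.5
  }
  dset <- make_dset(EDR = mk(), HRV = mk(), EMGe = mk(), EMGi = mk(), fa = fa)
  wp <- windowed_params(dset, wean_config())
  expect_equal(length(wp$window_start), 23)
  expect_equal(nrow(wp$values), 23)
  expect_equal(ncol(wp$values), 72) # 40 spectral + 24 coherence + 8 fixed-frequency
  expect_true(all(is.finite(wp$values)))
  # stationary input: band-power series are stable across windows
  expect_lt(sd(wp$values[, "PHFEMGe"]) / mean(wp$values[, "PHFEMGe"]), 0.5)
  # coherence columns bounded
  coh_cols <- grep("^(Hpcoh|RMScoh)", colnames(wp$values), value = TRUE)
  expect_true(all(wp$values[, coh_cols] >= 0 & wp$values[, coh_cols] <= 1))
})
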