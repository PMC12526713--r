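# clean QRS-like train with known beat times/amplitudes
make_train <- function(dur, rr = 1.0, fs = 128, amp_fun = function(t) 1) {
  tk <- seq(0.5, dur - 0.5, by = rr)
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- numeric(length(t))
  wt <- seq(-0.06, 0.06, by = 1 / fs)
  wave <- weanEMG:::ricker(wt, 0.012)
  for (tb in tk) {
    i0 <- round(tb * fs) + 1
    ii <- i0 + seq_along(wt) - which.max(wave)
    ok <- ii >= 1 & ii <= length(x)
    x[ii[ok]] <- x[ii[ok]] + amp_fun(tb) * wave[ok]
  }
  list(x = x, beats = tk)
}

test_that("R peaks are detected with correct count, timing and amplitude modulation", {
  tr <- make_train(120, rr = 1.0)
  b <- detect_r_peaks(tr$x, 128)
  expect_equal(length(b$times), 120, tolerance = 1 / 120)
  expect_equal(mean(b$rr), 1.0, tolerance = 0.01)
  expect_error(detect_r_peaks(rep(0, 128 * 20), 128), "insufficient beats")
  # depth-0.3 modulation: peak-to-peak swing (max-min)/mean ~= 0.6
  trm <- make_train(120, rr = 1.0, amp_fun = function(t) 1 + 0.3 * sin(2 * pi * 0.05 * t))
  bm <- detect_r_peaks(trm$x, 128)
  swing <- (max(bm$pp_amplitude) - min(bm$pp_amplitude)) / mean(bm$pp_amplitude)
  expect_equal(swing, 0.6, tolerance = 0.1 * 0.6)
})

test_that("EDR interpolates beat amplitudes without overshoot and recovers modulation", {
  beats <- structure(list(times = seq(0, 300, by = 0.8),
                          pp_amplitude = rep(2, 376), rr = rep(0.8, 375)),
                     class = "beat_series")
  expect_true(all(abs(compute_edr(beats, fa = 4) - 2) < 1e-12))
  tk <- seq(0, 300, by = 0.8)
  amp <- 1 + 0.3 * sin(2 * pi * 0.3 * tk)
  beats2 <- structure(list(times = tk, pp_amplitude = amp, rr = diff(tk)),
                      class = "beat_series")
  edr <- compute_edr(beats2, fa = 4)
  expect_true(all(edr >= min(amp) - 1e-12 & edr <= max(amp) + 1e-12)) # PCHIP no-overshoot
  psd <- welch_psd(edr - mean(edr), 4, seg_len_s = 75)
  expect_lt(abs(psd$freq[which.max(psd$power)] - 0.3), 0.02)
})

test_that("HRV outlier rule leaves no point deviating more than 18% from the mean", {
  # one long RR among regular beats (40% rate deviation)
  rr <- rep(1, 60); rr[30] <- 1.4
  tk <- c(0, cumsum(rr))
  beats <- structure(list(times = tk, pp_amplitude = rep(1, length(tk)), rr = rr),
                     class = "beat_series")
  hrv <- compute_hrv(beats, fa = 4)
  expect_true(all(abs(hrv - mean(hrv)) <= 0.18 * mean(hrv) + 1e-9))
  # adversarial: clustered and alternating outliers
  set.seed(13)
  rr2 <- rep(0.8, 120)
  rr2[c(20, 21, 22, 60, 90)] <- c(1.6, 1.5, 0.45, 2.0, 0.4)
  beats2 <- structure(list(times = c(0, cumsum(rr2)), pp_amplitude = rep(1, 121), rr = rr2),
                      class = "beat_series")
  hrv2 <- compute_hrv(beats2, fa = 4)
  expect_true(all(abs(hrv2 - mean(hrv2)) <= 0.18 * mean(hrv2) + 1e-9))
  # constant RR: constant unit rate
  beats3 <- structure(list(times = seq(0, 60, 1), pp_amplitude = rep(1, 61), rr = rep(1, 60)),
                      class = "beat_series")
  expect_equal(var(compute_hrv(beats3, fa = 4)), 0, tolerance = 1e-20)
  # modulated RR: HF peak recovered
  tb <- 0; tks <- 0
  while (tail(tks, 1) < 300) tks <- c(tks, tail(tks, 1) + 0.8 * (1 + 0.05 * sin(2 * pi * 0.25 * tail(tks, 1))))
  beats4 <- structure(list(times = tks, pp_amplitude = rep(1, length(tks)), rr = diff(tks)),
                      class = "beat_series")
  hrv4 <- compute_hrv(beats4, fa = 4)
  psd <- welch_psd(hrv4 - mean(hrv4), 4, seg_len_s = 75)
  hf <- psd$freq >= 0.15 & psd$freq <= 0.4
  expect_lt(abs(psd$freq[hf][which.max(psd$power[hf])] - 0.25), 0.02)
})

test_that("EMG envelope tracks burst modulation and is stable on stationary noise", {
  set.seed(14)
  fs <- 128
  t <- seq(0, 300 - 1 / fs, by = 1 / fs)
  carrier <- rnorm(length(t))
  env_true <- 1 + 0.8 * sin(2 * pi * 0.3 * t)
  emge <- compute_emge(env_true * carrier, fs, fa = 4)
  psd <- welch_psd(emge - mean(emge), 4, seg_len_s = 75)
  expect_lt(abs(psd$freq[which.max(psd$power)] - 0.3), 0.02)
  flat <- compute_emge(carrier, fs, fa = 4)
  expect_lt(sd(flat) / mean(flat), 0.2)
  # exact linearity
  expect_equal(compute_emge(2 * env_true * carrier, fs, fa = 4), 2 * emge)
})

test_that("EMGi enforces the 0.15 s separation rule keeping the larger peak", {
  fs <- 128
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  base <- 0.01 * sin(2 * pi * 3 * t) # sub-threshold background with local maxima
  put <- function(x, at, h) { x[round(at * fs) + 1] <- h; x }
  anchors <- function(x) { for (a in seq(2, 18, by = 2)) x <- put(x, a, 1); x }
  # conflicting pair 0.10 s apart: the smaller peak is dropped, so the series
  # is identical to the one built without it
  x_pair <- put(put(anchors(base), 9.0, 1.2), 9.1, 2.0)
  x_solo <- put(anchors(base), 9.1, 2.0)
  expect_equal(compute_emgi(x_pair, fs, fa = 4, thresh_quantile = 0.9),
               compute_emgi(x_solo, fs, fa = 4, thresh_quantile = 0.9),
               tolerance = 1e-9)
  # peaks 0.2 s apart are both retained: removing one changes the series
  y_pair <- put(put(anchors(base), 9.0, 1.5), 9.2, 1.5)
  y_solo <- put(anchors(base), 9.0, 1.5)
  d <- max(abs(compute_emgi(y_pair, fs, fa = 4, thresh_quantile = 0.9) -
                 compute_emgi(y_solo, fs, fa = 4, thresh_quantile = 0.9)))
  expect_gt(d, 0.05)
  expect_error(compute_emgi(rep(0, fs * 20), fs), "peaks")
})

test_that("EMGi and EMGe agree on synthetic diaphragmatic activity", {
  d <- derive_signals(preprocess_recording(generate_recording(tiny_spec(300), "success", seed = 9)))
  expect_gt(cor(d$EMGi, d$EMGe), 0.7)
})

test_that("channel-pair selection maximises cross-correlation and flags the canonical pair", {
  set.seed(15)
  n <- 1200
  base <- sin(2 * pi * 0.3 * (1:n) / 4)
  emge <- lapply(c(0.2, 0.4, 1, 0.4, 0.2),
                 function(w) w * base + rnorm(n, sd = 0.5))
  edr <- lapply(c(0.3, 1, 0.5), function(w) w * base + rnorm(n, sd = 0.5))
  sel <- select_channel_pair(emge, edr, fa = 4)
  expect_equal(sel$channel, 3)
  expect_equal(sel$lead, 2)
  expect_gt(sel$xcorr, 0.4)
  # identical series: exactly 1 at lag 0
  one <- list(base, base, base, base, base)
  sel2 <- select_channel_pair(one, list(base, base, base), fa = 4)
  expect_equal(sel2$xcorr, 1, tolerance = 1e-12)
  # independent noise: weak in expectation
  v <- replicate(20, {
    e <- lapply(1:5, function(i) rnorm(600))
    r <- lapply(1:3, function(i) rnorm(600))
    abs(select_channel_pair(e, r, fa = 4)$xcorr)
  })
  expect_lt(mean(v), 0.2)
})

test_that("the derived set is finite, aligned and canonically selected on synthetic data", {
  d <- derive_signals(preprocess_recording(generate_recording(tiny_spec(240), "success", seed = 10)))
  expect_s3_class(d, "wean_derived")
  lens <- vapply(d[c("EDR", "HRV", "EMGe", "EMGi")], length, 0L)
  expect_true(all(lens == length(d$t)))
  expect_true(all(vapply(d[c("EDR", "HRV", "EMGe", "EMGi")],
                         function(s) all(is.finite(s)), TRUE)))
  expect_equal(d$channel, 3)
  expect_equal(d$lead, 2)
  expect_gt(abs(d$xcorr), 0.4)
})
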