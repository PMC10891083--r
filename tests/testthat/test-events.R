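fast_params <- function(...) {
  event_params(winsz = 12, ...)
}

test_that("the Morlet spectrogram localizes pure tones and scales as amplitude squared", {
  fs <- 256
  pars <- fast_params()
  t <- seq(1 / fs, 12, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  sp <- wavelet_spectrogram(x, fs, pars)
  ridge <- sp$freq[apply(sp$power, 2, which.max)]
  expect_lt(max(abs(ridge[50:(length(ridge) - 50)] - 10)), 1)
  sp2 <- wavelet_spectrogram(2 * x, fs, pars)
  expect_equal(sp2$power, 4 * sp$power, tolerance = 1e-8)
  sp0 <- wavelet_spectrogram(numeric(12 * fs), fs, pars)
  expect_true(all(sp0$power == 0))
  expect_error(wavelet_spectrogram(x, 100, pars), "sampling rate")
  expect_error(wavelet_spectrogram(x[1:100], fs, pars), "shorter")
})

test_that("an injected burst is detected as a single event in its band", {
  fs <- 256
  pars <- fast_params()
  x <- gen_burst_timeseries(12, fs,
                            bursts = data.frame(time = 6, freq = 10,
                                                cycles = 10,
                                                amplitude = 6),
                            background_exponent = 1,
                            background_sd = 1, seed = 2)
  sp <- wavelet_spectrogram(x, fs, pars)
  ev <- detect_events(sp, pars)
  near <- ev[abs(ev$peak_time - 6) < 1 & ev$band == "alpha", ]
  expect_equal(nrow(near), 1)
  expect_lt(abs(near$peak_freq - 10), 1.5)
})

test_that("fully overlapping bursts merge into one surviving event", {
  fs <- 256
  pars <- fast_params()
  b <- data.frame(time = c(6, 6), freq = c(20, 20), cycles = 12,
                  amplitude = c(5, 5))
  x <- gen_burst_timeseries(12, fs, bursts = b, background_sd = 1,
                            seed = 3)
  sp <- wavelet_spectrogram(x, fs, pars)
  ev <- detect_events(sp, pars)
  # threshold exceedances of the stochastic background are expected; the
  # doubled burst must survive as a single strong event
  strong <- ev[ev$peak_norm_power > 10 * pars$medthresh, ]
  expect_equal(sum(abs(strong$peak_time - 6) < 0.8 &
                     strong$band == "beta"), 1)
})

test_that("event boxes never overlap beyond the merge threshold", {
  fs <- 256
  pars <- fast_params()
  x <- gen_burst_timeseries(12, fs,
                            bursts = data.frame(
                              time = c(3, 6, 9), freq = c(8, 15, 35),
                              cycles = c(8, 12, 20),
                              amplitude = c(5, 5, 5)),
                            background_sd = 1, seed = 4)
  sp <- wavelet_spectrogram(x, fs, pars)
  ev <- detect_events(sp, pars)
  if (nrow(ev) > 1) {
    for (i in 1:(nrow(ev) - 1)) for (j in (i + 1):nrow(ev)) {
      ti <- max(0, min(ev$t_end[i], ev$t_end[j]) -
                  max(ev$t_start[i], ev$t_start[j]))
      fi <- max(0, min(ev$f_hi[i], ev$f_hi[j]) -
                  max(ev$f_lo[i], ev$f_lo[j]))
      ai <- (ev$t_end[i] - ev$t_start[i]) * (ev$f_hi[i] - ev$f_lo[i])
      aj <- (ev$t_end[j] - ev$t_start[j]) * (ev$f_hi[j] - ev$f_lo[j])
      expect_lte(ti * fi / max(min(ai, aj), 1e-9), pars$overlapth + 0.25)
    }
  }
})

test_that("detection is scale invariant while wave height scales linearly", {
  fs <- 256
  pars <- fast_params()
  b <- data.frame(time = 6, freq = 10, cycles = 10, amplitude = 6)
  x <- gen_burst_timeseries(12, fs, bursts = b, background_sd = 1,
                            seed = 5)
  sp1 <- wavelet_spectrogram(x, fs, pars)
  sp2 <- wavelet_spectrogram(5 * x, fs, pars)
  e1 <- detect_events(sp1, pars)
  e2 <- detect_events(sp2, pars)
  expect_equal(e1[c("peak_freq", "peak_time", "t_start", "t_end")],
               e2[c("peak_freq", "peak_time", "t_start", "t_end")],
               tolerance = 1e-8)
  f1 <- event_features(e1, x, fs)
  f2 <- event_features(e2, 5 * x, fs)
  expect_equal(f2$wave_height, 5 * f1$wave_height, tolerance = 1e-6)
})

test_that("event features recover the injected ground truth", {
  fs <- 256
  pars <- fast_params()
  b <- data.frame(time = 6, freq = 10, cycles = 10, amplitude = 6)
  x <- gen_burst_timeseries(12, fs, bursts = b, background_sd = 0.5,
                            seed = 6)
  sp <- wavelet_spectrogram(x, fs, pars)
  ev <- detect_events(sp, pars)
  ev <- event_features(ev[abs(ev$peak_time - 6) < 1, ][1, ], x, fs)
  expect_equal(ev$cycle_count, 10, tolerance = 0.45)
  expect_equal(ev$duration, 1, tolerance = 0.45)
  # Hann-windowed burst of amplitude A peaks at ~2A peak-to-trough
  expect_equal(ev$wave_height, 12, tolerance = 0.15 * 12)
})

test_that("band classification follows the half-open table with the gap rule", {
  expect_equal(classify_band(6)[1], "theta")
  expect_equal(classify_band(9)[1], "alpha")     # boundary goes up
  expect_equal(classify_band(35)[1], "lowgamma")
  expect_equal(classify_band(2)[1], "delta")
  expect_equal(classify_band(20)[1], "beta")
  expect_equal(classify_band(45)[1], "gamma")
  expect_equal(classify_band(0.2)[1], "unclassified")
  expect_equal(classify_band(95)[1], "unclassified")
  # 29-30 Hz gap maps to the nearer band and is flagged
  lab <- classify_band(c(29.2, 29.8))
  expect_equal(as.character(lab), c("beta", "lowgamma"))
  expect_true(all(attr(lab, "gap")))
})
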