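# closed-form surface potential of a radial dipole inside an insulated
# homogeneous sphere (independent oracle; derived from the Legendre
# generating function: sum (2n+1) t^(n-1) P_n = ((1-t^2)/D^3 - 1)/t with
# D = sqrt(1 - 2 t cos(theta) + t^2))
homog_sphere_radial <- function(p_Am, sigma, R_m, b_m, theta) {
  t <- b_m / R_m
  D <- sqrt(1 - 2 * t * cos(theta) + t^2)
  s <- ((1 - t^2) / D^3 - 1) / t
  p_Am / (4 * pi * sigma * R_m^2) * s
}

test_that("dipole construction is linear and orientation-summed", {
  expect_equal(compute_dipole(matrix(0, 3, 10)), rep(0, 10))
  a <- rbind(sin(1:10), -sin(1:10))
  expect_equal(compute_dipole(a), rep(0, 10))       # cancellation
  one <- matrix(2, 1, 5)
  expect_equal(compute_dipole(one, separation_um = 400), rep(800, 5))
  expect_equal(compute_dipole(2 * one), 2 * compute_dipole(one))
})

test_that("four-sphere solution reduces to the homogeneous sphere when conductivities are equal", {
  sig <- 0.3
  model <- four_sphere_model(radii_mm = c(79, 80, 85, 90),
                             sigma = rep(sig, 4),
                             dipole_depth_mm = 60, n_max = 120)
  for (theta in c(0, 0.4, 1.0)) {
    got <- foursphere_potential(1, model, "radial", theta = theta)  # 1 pA um
    want <- homog_sphere_radial(1e-18, sig, 0.090, 0.060, theta) * 1e3
    expect_rel_equal(got, want, 0.01)
  }
})

test_that("four-sphere potential is linear in the dipole and scales as 1/conductivity", {
  model <- four_sphere_model()
  p <- sin(seq(0, 2 * pi, length.out = 50))
  v <- foursphere_potential(p, model)
  expect_equal(foursphere_potential(3 * p, model), 3 * v)
  m2 <- four_sphere_model(sigma = 2 * model$sigma)
  expect_equal(foursphere_potential(p, m2), v / 2, tolerance = 1e-10)
})

test_that("a radial dipole beneath the electrode beats the tangential one", {
  model <- four_sphere_model(dipole_depth_mm = 70)
  vr <- abs(foursphere_potential(1, model, "radial", theta = 0.05))
  vt <- abs(foursphere_potential(1, model, "tangential", theta = 0.05,
                                 phi = 0))
  expect_gt(vr, vt)
  # tangential dipole vanishes on the axis
  expect_equal(foursphere_potential(1, model, "tangential", theta = 0), 0)
})

test_that("Welch PSD satisfies Parseval on sinusoids and is flat for white noise", {
  fs <- 1000
  t <- seq(0, 20, by = 1 / fs)[-1]
  x <- sin(2 * pi * 10 * t)
  psd <- welch_psd(x, fs)
  expect_equal(psd$nperseg, 3500)
  total <- pracma::trapz(psd$freq, psd$power)
  expect_rel_equal(total, 0.5, 0.02)
  # spectral resolution fs/nperseg ~ 0.286 Hz
  expect_equal(diff(psd$freq)[1], fs / 3500)
  # white noise: mean level = variance / (fs/2) within 5%
  set.seed(4)
  wn <- rnorm(40 * fs, sd = 2)
  pw <- welch_psd(wn, fs)
  expect_rel_equal(mean(pw$power[-1]), 4 / (fs / 2), 0.05)
  expect_true(all(welch_psd(numeric(7000), fs)$power == 0))
  expect_error(welch_psd(rnorm(1000), fs), "shorter")
})

test_that("band power integrates the PSD over the requested band", {
  psd <- list(freq = seq(0, 100, by = 0.25), power = rep(2, 401))
  expect_equal(band_power(psd, c(4, 8)), 8)          # flat: height x width
  expect_error(band_power(psd, c(90, 120)), "range")
  fs <- 1000
  t <- seq(1 / fs, 25, by = 1 / fs)
  psd2 <- welch_psd(sin(2 * pi * 10 * t), fs)
  expect_gt(band_power(psd2, c(8, 12)),
            100 * (band_power(psd2, c(4, 8)) +
                     band_power(psd2, c(12, 21))))
})

test_that("spike-train PSD shows the Poisson floor and injected modulation", {
  sdp <- gen_poisson_population(30, rate = 4, duration = 60000, seed = 3)
  psd <- spike_psd(sdp, fs = 1000)
  # summed-binary-train Poisson floor: flat at (total rate)/fs per-bin
  # variance over the high-frequency half
  hi <- psd$freq > 100
  floor_expected <- 30 * 4 / 1000 / (1000 / 2)  # var per bin / (fs/2)
  expect_rel_equal(mean(psd$power[hi]), floor_expected, 0.1)
  sdm <- gen_poisson_population(30, rate = 4, duration = 60000, seed = 3,
                                mod_freq = 10, mod_depth = 0.8)
  psdm <- spike_psd(sdm, fs = 1000)
  sel <- psdm$freq > 9 & psdm$freq < 11
  off <- psdm$freq > 15 & psdm$freq < 25
  expect_gt(mean(psdm$power[sel]), 3 * mean(psdm$power[off]))
})

test_that("bootstrap of per-seed spectra is seeded and degenerate-safe", {
  m <- matrix(rep(c(1, 2, 3, 4), each = 5), nrow = 4, byrow = TRUE)
  m[] <- 1
  ci <- bootstrap_mean_ci(m, n_boot = 50, seed = 1)
  expect_true(all(ci$hi - ci$lo == 0))
  set.seed(2)
  mm <- matrix(rnorm(200), 10, 20)
  c1 <- bootstrap_mean_ci(mm, seed = 9)
  c2 <- bootstrap_mean_ci(mm, seed = 9)
  expect_identical(c1, c2)
  expect_true(all(c1$lo <= c1$mean & c1$mean <= c1$hi))
})

test_that("bootstrap interval covers the true mean at roughly the nominal rate", {
  set.seed(31)
  cover <- replicate(80, {
    mm <- matrix(rnorm(60 * 3, mean = 5), 60, 3)
    ci <- bootstrap_mean_ci(mm, n_boot = 200,
                            seed = sample.int(1e6, 1))
    all(ci$lo <= 5 & ci$hi >= 5)
  })
  expect_gt(mean(cover), 0.8)
})
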