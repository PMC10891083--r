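mk_spikes <- function(df, n, duration, type = "Pyr") {
  structure(list(spikes = df, duration = duration,
                 counts = stats::setNames(n, type), dt = NA,
                 condition = "synthetic", seed = 1),
            class = "spike_data")
}

test_that("sliding-window rates count spikes per neuron per second", {
  sd1 <- mk_spikes(data.frame(neuron_id = 1, type = "Pyr", time_ms = 25),
                   n = 1, duration = 100)
  r <- window_rates(sd1, c(0, 100), window = 50, step = 1)
  expect_equal(length(r), 51)
  # one spike inside a 50 ms window of a single neuron = 20 Hz
  expect_equal(max(r), 20)
  expect_true(all(r %in% c(0, 20)))
  # empty data gives all-zero samples
  sd0 <- mk_spikes(data.frame(neuron_id = integer(0), type = character(0),
                              time_ms = numeric(0)), 4, 4000)
  expect_true(all(window_rates(sd0, c(0, 3000)) == 0))
  # a 3 s interval yields 2951 windows
  expect_length(window_rates(sd0, c(0, 3000)), 2951)
  expect_error(window_rates(sd0, c(0, 30)), "shorter")
})

test_that("window rates of a Poisson population converge to the true rate", {
  sd <- gen_poisson_population(20, rate = 5, duration = 60000, seed = 2)
  r <- window_rates(sd, c(0, 60000))
  expect_equal(mean(r), 5, tolerance = 0.05)
})

test_that("skew-normal MLE recovers generating parameters", {
  set.seed(11)
  # symmetric data: shape estimate near zero
  xs <- rnorm(1e5)
  f0 <- fit_skew_normal(xs)
  expect_lt(abs(f0$shape), 0.5)
  # skewed data: parameters within 5%
  xg <- rskewnorm(1e5, location = 1, scale = 0.3, shape = 4)
  fg <- fit_skew_normal(xg)
  expect_rel_equal(fg$location, 1, 0.05)
  expect_rel_equal(fg$scale, 0.3, 0.05)
  expect_rel_equal(fg$shape, 4, 0.15)
  expect_error(fit_skew_normal(rep(1, 500)), "degenerate|zero-variance")
  expect_error(fit_skew_normal(rnorm(50)), "at least")
})

test_that("decision threshold sits at the density intersection", {
  # two unit-variance normals, means 0 and 4: threshold at 2 by symmetry
  pre <- structure(list(location = 0, scale = 1, shape = 0),
                   class = "skew_normal_fit")
  post <- structure(list(location = 4, scale = 1, shape = 0),
                    class = "skew_normal_fit")
  expect_equal(decision_threshold(pre, post), 2, tolerance = 1e-6)
  # unequal variances: compare with the closed-form quadratic root
  post2 <- structure(list(location = 4, scale = 2, shape = 0),
                     class = "skew_normal_fit")
  # solve log-density equality: (3/8) x^2 + x - 2 - log(2) = 0
  a <- 1 / 2 - 1 / 8
  b <- 1
  cc <- -(4^2 / 8) - log(2)
  roots <- (-b + c(-1, 1) * sqrt(b^2 - 4 * a * cc)) / (2 * a)
  expected <- roots[roots > 0 & roots < 4]
  expect_equal(decision_threshold(pre, post2), expected,
               tolerance = 1e-6)
  # identical distributions: no unique intersection
  expect_error(decision_threshold(pre, pre), "mean")
})

test_that("error rates equal Gaussian tail masses and match quadrature", {
  pre <- structure(list(location = 0, scale = 1, shape = 0),
                   class = "skew_normal_fit")
  post <- structure(list(location = 4, scale = 1, shape = 0),
                    class = "skew_normal_fit")
  er <- error_rates(pre, post, threshold = 2)
  expect_equal(er$P_false, pnorm(-2), tolerance = 1e-9)
  expect_equal(er$P_failed, pnorm(-2), tolerance = 1e-9)
  # degenerate threshold limits
  er_inf <- error_rates(pre, post, threshold = 30)
  expect_lt(er_inf$P_false, 1e-10)
  expect_gt(er_inf$P_failed, 1 - 1e-10)
  # skewed fits: agree with brute-force numerical integration of the pdf
  fits <- list(
    structure(list(location = 0.5, scale = 0.4, shape = 3),
              class = "skew_normal_fit"),
    structure(list(location = 2, scale = 1.1, shape = -2),
              class = "skew_normal_fit"))
  for (f in fits) {
    thr <- f$location + 0.3
    num <- integrate(function(x) dskewnorm(x, f$location, f$scale,
                                           f$shape),
                     lower = -Inf, upper = thr, rel.tol = 1e-12)$value
    expect_equal(pskewnorm(thr, f$location, f$scale, f$shape), num,
                 tolerance = 1e-6)
  }
})

test_that("threshold and error-rate monotonicity under post shifts", {
  pre <- structure(list(location = 0, scale = 1, shape = 0),
                   class = "skew_normal_fit")
  shifts <- c(2.5, 3.5, 4.5, 6)
  failed <- sapply(shifts, function(m) {
    post <- structure(list(location = m, scale = 1, shape = 0),
                      class = "skew_normal_fit")
    thr <- decision_threshold(pre, post)
    error_rates(pre, post, thr)$P_failed
  })
  false <- sapply(shifts, function(m) {
    post <- structure(list(location = m, scale = 1, shape = 0),
                      class = "skew_normal_fit")
    thr <- decision_threshold(pre, post)
    error_rates(pre, post, thr)$P_false
  })
  expect_true(all(diff(failed) < 0))
  expect_true(all(diff(false) < 0))
})

test_that("SNR follows its definition", {
  pre <- c(1, 2, 3, 4, 5)
  expect_equal(compute_snr(pre, pre), 0)
  expect_equal(compute_snr(pre, mean(pre) + 2 * sd(pre)), 2)
  expect_equal(compute_snr(pre, 6, method = "ratio"), 2)
  expect_error(compute_snr(rep(1, 5), 2), "SD")
})

test_that("mean pairwise correlation behaves on constructed trains", {
  # identical trains correlate perfectly
  tt <- seq(10, 990, by = 20)
  df <- rbind(data.frame(neuron_id = 1, type = "Pyr", time_ms = tt),
              data.frame(neuron_id = 2, type = "Pyr", time_ms = tt))
  sd2 <- mk_spikes(df, 2, 1000)
  expect_equal(mean_pairwise_correlation(sd2)$mean_r, 1)
  # anti-phase regular trains anti-correlate
  df2 <- rbind(data.frame(neuron_id = 1, type = "Pyr", time_ms = tt),
               data.frame(neuron_id = 2, type = "Pyr", time_ms = tt + 10))
  expect_lt(mean_pairwise_correlation(mk_spikes(df2, 2, 1000))$mean_r, 0)
  # independent Poisson trains decorrelate on long runs
  sdp <- gen_poisson_population(12, rate = 8, duration = 120000, seed = 5)
  expect_lt(abs(mean_pairwise_correlation(sdp)$mean_r), 0.005)
  # shared slow modulation induces positive correlations
  sdm <- gen_poisson_population(12, rate = 8, duration = 60000, seed = 6,
                                mod_freq = 10, mod_depth = 0.8)
  expect_gt(mean_pairwise_correlation(sdm)$mean_r,
            mean_pairwise_correlation(sdp)$mean_r + 0.002)
})

test_that("pooled detection analysis fits pre per circuit and post across circuits", {
  cfg <- circuit_config(duration = 4500)
  sims <- lapply(1:4, function(s) {
    circ <- attach_stimulus(build_circuit(cfg, seed = s),
                            stimulus_protocol("basal"), seed = s)
    simulate_circuit(circ, seed = s)
  })
  det <- detection_analysis(sims)
  expect_equal(nrow(det$per_circuit), 4)
  expect_length(det$pre_fits, 4)
  # each pre fit pools 2951 windows; the post fit pools one value/circuit
  expect_equal(det$pre_fits[[1]]$n, 2951)
  expect_equal(det$post_fit$n, 4)
  expect_true(all(det$per_circuit$P_failed >= 0 &
                    det$per_circuit$P_failed <= 1))
  expect_true(all(det$per_circuit$P_false >= 0 &
                    det$per_circuit$P_false <= 1))
  expect_true(all(det$per_circuit$post_rate > det$per_circuit$pre_mean))
})
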