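#' Four-sphere head volume-conductor model
#'
#' Concentric-sphere head model (grey matter, CSF, skull, scalp) with
#' homogeneous, isotropic, frequency-independent conductivities.  The
#' current dipole sits on the vertical axis inside the innermost sphere;
#' the electrode sits on the scalp surface.
#'
#' @param radii_mm outer radii of the four spheres (mm), strictly
#'   increasing.
#' @param sigma conductivities (S/m), one per sphere.
#' @param dipole_depth_mm radial position of the dipole (mm), inside the
#'   innermost sphere; default just beneath the grey-matter surface.
#' @param n_max number of terms of the spherical-harmonic expansion; the
#'   series is also truncated once terms fall below `1e-12` relative.
#' @return object of class `four_sphere_model`.
#' @export
four_sphere_model <- function(radii_mm = c(79, 80, 85, 90),
                              sigma = c(0.047, 1.71, 0.02, 0.41),
                              dipole_depth_mm = 78, n_max = 100) {
  if (any(diff(radii_mm) <= 0)) stop("radii must be strictly increasing")
  if (any(sigma <= 0)) stop("conductivities must be positive")
  if (dipole_depth_mm <= 0 || dipole_depth_mm >= radii_mm[1])
    stop("dipole must lie inside the innermost sphere")
  structure(list(radii_mm = radii_mm, sigma = sigma,
                 dipole_depth_mm = dipole_depth_mm, n_max = n_max),
            class = "four_sphere_model")
}

# associated Legendre P_n^1(x) for n = 1..nmax by recurrence
assoc_legendre1 <- function(nmax, x) {
  out <- numeric(nmax)
  s <- sqrt(max(1 - x^2, 0))
  p_prev <- -s                      # P_1^1
  p_prev2 <- 0                      # P_0^1
  out[1] <- p_prev
  if (nmax >= 2) {
    for (n in 2:nmax) {
      p <- ((2 * n - 1) * x * p_prev - n * p_prev2) / (n - 1)
      out[n] <- p
      p_prev2 <- p_prev
      p_prev <- p
    }
  }
  out
}

legendre_p <- function(nmax, x) {
  out <- numeric(nmax)
  p_prev2 <- 1; p_prev <- x
  out[1] <- x
  if (nmax >= 2) {
    for (n in 2:nmax) {
      p <- ((2 * n - 1) * x * p_prev - (n - 1) * p_prev2) / n
      out[n] <- p
      p_prev2 <- p_prev
      p_prev <- p
    }
  }
  out
}

# scalp-surface expansion coefficients: for each harmonic order solve the
# boundary-value problem (potential and radial current continuity at the
# three inner interfaces, zero current through the scalp surface)
foursphere_scalp_coefs <- function(model) {
  r <- model$radii_mm / model$radii_mm[4]   # scale by scalp radius
  sig <- model$sigma
  u <- model$dipole_depth_mm / model$radii_mm[4]
  nmax <- model$n_max
  coef <- numeric(nmax)
  for (n in seq_len(nmax)) {
    # unknowns: A1, A2, B2, A3, B3, A4, B4 (source term in sphere 1 has
    # unit coefficient; scaled afterwards)
    M <- matrix(0, 7, 7)
    b <- numeric(7)
    row <- 0
    for (k in 1:3) {
      rk <- r[k]
      ia <- c(1, 2, 4, 6)[k]      # A_k index
      # continuity of potential
      row <- row + 1
      M[row, ia] <- rk^n
      if (k > 1) M[row, ia + 1] <- rk^(-(n + 1))
      M[row, ia + (if (k == 1) 1 else 2)] <- -rk^n
      M[row, ia + (if (k == 1) 2 else 3)] <- -rk^(-(n + 1))
      if (k == 1) b[row] <- -rk^(-(n + 1))
      # continuity of radial current density
      row <- row + 1
      M[row, ia] <- sig[k] * n * rk^(n - 1)
      if (k > 1) M[row, ia + 1] <- -sig[k] * (n + 1) * rk^(-(n + 2))
      M[row, ia + (if (k == 1) 1 else 2)] <- -sig[k + 1] * n * rk^(n - 1)
      M[row, ia + (if (k == 1) 2 else 3)] <-
        sig[k + 1] * (n + 1) * rk^(-(n + 2))
      if (k == 1) b[row] <- sig[1] * (n + 1) * rk^(-(n + 2))
    }
    # insulated outer boundary at r = 1
    M[7, 6] <- n
    M[7, 7] <- -(n + 1)
    sol <- solve(M, b)
    coef[n] <- sol[6] + sol[7]      # A4 + B4 at the scalp surface (r = 1)
  }
  coef
}

#' Scalp potential of a current dipole in the four-sphere model
#'
#' Quasi-static spherical-harmonic solution, linear in the dipole moment.
#' The dipole is decomposed into a radial component (along the depth axis)
#' and a tangential component; the electrode position is given by the polar
#' angle from the dipole axis.
#'
#' @param p dipole moment time series (pA um); scalar or vector.
#' @param model a [four_sphere_model()].
#' @param orientation `"radial"` or `"tangential"`.
#' @param theta polar angle of the electrode from the dipole axis
#'   (radians); 0 is the scalp apex directly above the dipole.
#' @param phi azimuth (radians), relevant for tangential dipoles.
#' @return EEG potential (mV), same length as `p`.
#' @export
foursphere_potential <- function(p, model,
                                 orientation = c("radial", "tangential"),
                                 theta = 0, phi = 0) {
  stopifnot(inherits(model, "four_sphere_model"))
  orientation <- match.arg(orientation)
  coef <- foursphere_scalp_coefs(model)
  nmax <- model$n_max
  u <- model$dipole_depth_mm / model$radii_mm[4]
  ns <- seq_len(nmax)
  if (orientation == "radial") {
    src <- ns * u^(ns - 1)
    ang <- legendre_p(nmax, cos(theta))
  } else {
    src <- -u^(ns - 1)
    ang <- assoc_legendre1(nmax, cos(theta)) * cos(phi) / ns
  }
  terms <- coef * src * ang
  # drop the tail once terms are negligible relative to the partial sum
  csum <- cumsum(terms)
  small <- abs(terms) < 1e-12 * pmax(abs(csum), .Machine$double.xmin)
  last <- if (any(!small)) max(which(!small)) else nmax
  k_sum <- csum[last]
  r4_m <- model$radii_mm[4] * 1e-3
  # pA um = 1e-18 A m; potential in volts, reported in mV
  transfer <- k_sum / (4 * pi * model$sigma[1] * r4_m^2) * 1e-18 * 1e3
  p * transfer
}

#' Dipole moment from pyramidal axial currents
#'
#' The equivalent current dipole of the population is the sum over Pyr
#' neurons of the somato-apical axial current times the compartment
#' separation, oriented along the cortical depth axis (apical above soma).
#'
#' @param axial axial current traces (pA): a matrix (neurons x time) or an
#'   already-summed vector.
#' @param separation_um somato-apical separation (um).
#' @return dipole moment time series (pA um).
#' @export
compute_dipole <- function(axial, separation_um = 400) {
  if (is.matrix(axial)) axial <- colSums(axial)
  axial * separation_um
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann taper, 50% overlap, per-segment mean
#' removal, density scaling (power per Hz).  The segment length defaults to
#' 3.5 s times the sampling rate so the spectral resolution (~0.286 Hz) is
#' preserved across sampling rates.
#'
#' @param x signal (e.g. EEG in mV).
#' @param fs sampling rate (Hz).
#' @param seg_seconds segment length in seconds.
#' @param overlap fractional segment overlap.
#' @return object of class `psd`: list with `freq` (Hz), `power`
#'   (signal-units^2 per Hz), `fs`, `nperseg`, `n_segments`.
#' @export
welch_psd <- function(x, fs, seg_seconds = 3.5, overlap = 0.5) {
  nper <- round(seg_seconds * fs)
  if (length(x) < nper)
    stop("signal shorter than one segment (", nper, " samples)")
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nper - 1) / nper)  # periodic Hann
  step <- max(1, round(nper * (1 - overlap)))
  starts <- seq(1, length(x) - nper + 1, by = step)
  nfreq <- nper %/% 2 + 1
  acc <- numeric(nfreq)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nper - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- stats::fft(seg)[seq_len(nfreq)]
    acc <- acc + Re(sp * Conj(sp))
  }
  pxx <- acc / length(starts) / (fs * sum(w^2))
  # one-sided: double everything except DC (and Nyquist when nper is even)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nper %% 2 == 0) dbl[nfreq] <- 1
  structure(list(freq = seq(0, nfreq - 1) * fs / nper, power = pxx * dbl,
                 fs = fs, nperseg = nper, n_segments = length(starts)),
            class = "psd")
}

#' Band-integrated spectral power
#'
#' Trapezoidal integral of the PSD over a frequency band (canonical bands:
#' theta 4-8 Hz, alpha 8-12 Hz, lower beta 12-21 Hz).
#'
#' @param psd a `psd` object (or list with `freq` and `power`).
#' @param band `c(f_lo, f_hi)` in Hz, inside the PSD range.
#' @return integrated power (signal-units^2).
#' @export
band_power <- function(psd, band) {
  f <- psd$freq; p <- psd$power
  if (band[1] < min(f) || band[2] > max(f))
    stop("band outside the PSD frequency range")
  inside <- f > band[1] & f < band[2]
  fb <- c(band[1], f[inside], band[2])
  pb <- c(stats::approx(f, p, band[1])$y, p[inside],
          stats::approx(f, p, band[2])$y)
  pracma::trapz(fb, pb)
}

#' Power spectrum of the summed population spike train
#'
#' Spike times are binned into binary per-neuron vectors at the requested
#' rate, summed across the population, and passed through [welch_psd()]
#' with the same segment rule as the EEG.
#'
#' @param sd a `spike_data` object.
#' @param fs binning rate (Hz).
#' @param population neuron type.
#' @param seg_seconds Welch segment length (s).
#' @param interval analysis interval (ms); defaults to the full run.
#' @return a `psd` object.
#' @export
spike_psd <- function(sd, fs = 1000, population = "Pyr",
                      seg_seconds = 3.5, interval = NULL) {
  if (is.null(interval)) interval <- c(0, sd$duration)
  nb <- floor(diff(interval) * fs / 1000)
  sp <- sd$spikes[sd$spikes$type == population &
                    sd$spikes$time_ms > interval[1] &
                    sd$spikes$time_ms <= interval[2], ]
  uid <- unique(sp$neuron_id)
  train <- numeric(nb)
  for (id in uid) {
    b <- pmin(nb, floor((sp$time_ms[sp$neuron_id == id] - interval[1]) *
                          fs / 1000) + 1L)
    train[unique(b)] <- train[unique(b)] + 1   # binary per neuron
  }
  welch_psd(train, fs, seg_seconds)
}

#' Bootstrapped mean and confidence interval of per-seed spectra
#'
#' Percentile bootstrap (resampling seeds with replacement) of the mean
#' power at each frequency.
#'
#' @param psds matrix of PSDs, one row per seed, columns = frequencies.
#' @param n_boot bootstrap iterations.
#' @param level confidence level.
#' @param seed RNG seed.
#' @return list with `mean`, `lo`, `hi` (vectors over frequency).
#' @export
bootstrap_mean_ci <- function(psds, n_boot = 100, level = 0.95, seed = 1) {
  stopifnot(is.matrix(psds), nrow(psds) >= 2)
  set.seed(seed)
  ns <- nrow(psds)
  boots <- matrix(NA_real_, n_boot, ncol(psds))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(ns, ns, replace = TRUE)
    boots[b, ] <- colMeans(psds[idx, , drop = FALSE])
  }
  a <- (1 - level) / 2
  list(mean = colMeans(psds),
       lo = apply(boots, 2, stats::quantile, probs = a),
       hi = apply(boots, 2, stats::quantile, probs = 1 - a))
}
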