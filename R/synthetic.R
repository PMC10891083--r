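#' Synthetic Poisson spike-train population
#'
#' Independent homogeneous Poisson trains, optionally rate-modulated by a
#' common sinusoid (for correlation and spectral tests).  Output mimics the
#' simulator's `spike_data` container so every analysis stage accepts it.
#'
#' @param n_neurons number of neurons.
#' @param rate firing rate (Hz), scalar or per neuron.
#' @param duration duration (ms).
#' @param seed RNG seed.
#' @param mod_freq optional common modulation frequency (Hz).
#' @param mod_depth modulation depth in `[0, 1]` (rate is
#'   `rate * (1 + depth * sin)` with thinning).
#' @param type type label given to all neurons.
#' @return a `spike_data` object.
#' @export
gen_poisson_population <- function(n_neurons, rate, duration, seed = 1,
                                   mod_freq = NULL, mod_depth = 0,
                                   type = "Pyr") {
  if (any(rate < 0)) stop("rates must be non-negative")
  set.seed(seed)
  rate <- rep_len(rate, n_neurons)
  sp <- list()
  for (i in seq_len(n_neurons)) {
    rmax <- rate[i] * (1 + mod_depth)
    nexp <- stats::rpois(1, rmax * duration / 1000)
    tt <- sort(stats::runif(nexp, 0, duration))
    if (!is.null(mod_freq) && length(tt) > 0) {
      lam <- rate[i] * (1 + mod_depth *
                          sin(2 * pi * mod_freq * tt / 1000))
      tt <- tt[stats::runif(length(tt)) < lam / rmax]
    }
    if (length(tt) > 0)
      sp[[length(sp) + 1]] <- data.frame(neuron_id = i, type = type,
                                         time_ms = tt)
  }
  spikes <- if (length(sp)) do.call(rbind, sp) else
    data.frame(neuron_id = integer(0), type = character(0),
               time_ms = numeric(0))
  spikes <- spikes[order(spikes$time_ms), ]
  counts <- stats::setNames(n_neurons, type)
  structure(list(spikes = spikes, duration = duration, dt = NA,
                 onset = NULL, counts = counts, condition = "synthetic",
                 seed = seed),
            class = "spike_data")
}

#' Synthetic power-law spectrum with Gaussian peaks
#'
#' Inverse model of the spectral parameterization:
#' `P(f) = 10^offset * f^-chi * 10^(sum of Gaussian peaks in log space)`
#' times multiplicative log-normal noise.
#'
#' @param freqs frequency grid (Hz), positive.
#' @param offset log10 power offset.
#' @param exponent aperiodic exponent chi.
#' @param peaks data.frame with `cf`, `bw`, `height` (log10-power units);
#'   `NULL` for none.
#' @param noise_sd SD of the log10-power noise.
#' @param seed RNG seed.
#' @return list with `freq` and `power` (consumable by [fit_spectrum()]).
#' @export
gen_powerlaw_psd <- function(freqs, offset, exponent, peaks = NULL,
                             noise_sd = 0, seed = 1) {
  if (any(freqs <= 0)) stop("frequencies must be positive")
  set.seed(seed)
  lp <- offset - exponent * log10(freqs)
  if (!is.null(peaks) && nrow(peaks) > 0)
    for (j in seq_len(nrow(peaks)))
      lp <- lp + peaks$height[j] *
        exp(-(freqs - peaks$cf[j])^2 / (2 * (peaks$bw[j] / 2)^2))
  if (noise_sd > 0)
    lp <- lp + stats::rnorm(length(freqs), 0, noise_sd)
  list(freq = freqs, power = 10^lp)
}

#' Synthetic burst time series on a colored-noise background
#'
#' 1/f-shaped background (spectral shaping of white noise by an FFT
#' filter) plus Hann-windowed sinusoidal bursts at specified times;
#' ground truth for the oscillation-event detector.
#'
#' @param duration duration (s).
#' @param fs sampling rate (Hz).
#' @param bursts data.frame with `time` (center, s), `freq` (Hz),
#'   `cycles`, `amplitude`; `NULL` for background only.
#' @param background_exponent spectral exponent of the background.
#' @param background_sd background SD (signal units).
#' @param seed RNG seed.
#' @return numeric signal of length `duration * fs`.
#' @export
gen_burst_timeseries <- function(duration, fs, bursts = NULL,
                                 background_exponent = 1,
                                 background_sd = 1, seed = 1) {
  set.seed(seed)
  n <- round(duration * fs)
  wn <- stats::rnorm(n)
  W <- stats::fft(wn)
  fgrid <- abs(c(seq(0, floor(n / 2)),
                 seq(-ceiling(n / 2) + 1, -1))) * fs / n
  shape <- ifelse(fgrid > 0, fgrid^(-background_exponent / 2), 0)
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x <- x / stats::sd(x) * background_sd
  if (!is.null(bursts) && nrow(bursts) > 0) {
    for (b in seq_len(nrow(bursts))) {
      len <- bursts$cycles[b] / bursts$freq[b]
      if (bursts$time[b] - len / 2 < 0 ||
          bursts$time[b] + len / 2 > duration)
        stop("burst extends outside the signal")
      nb <- round(len * fs)
      tt <- seq_len(nb) / fs
      env <- 0.5 - 0.5 * cos(2 * pi * seq(0, nb - 1) / (nb - 1))
      wave <- bursts$amplitude[b] *
        sin(2 * pi * bursts$freq[b] * tt) * env
      i0 <- round((bursts$time[b] - len / 2) * fs)
      x[i0 + seq_len(nb)] <- x[i0 + seq_len(nb)] + wave
    }
  }
  x
}

#' Synthetic voltage-clamp current trace
#'
#' Piecewise-constant current levels for the GABA, alpha5-PAM + GABA and
#' picrotoxin conditions plus Gaussian noise, with condition annotations;
#' per-condition mean extraction (relative to the picrotoxin segment)
#' recovers the levels.
#'
#' @param levels named current levels (pA): `GABA`, `a5pam`, `PTX`.
#' @param noise_sd Gaussian noise SD (pA).
#' @param fs sampling rate (Hz).
#' @param seg_seconds duration of each condition segment (s).
#' @param seed RNG seed.
#' @param baseline constant offset added to the whole trace (pA); the
#'   PTX-relative extraction is invariant to it.
#' @return data.frame with `time_ms`, `current_pA`, `condition`.
#' @export
gen_clamp_trace <- function(levels = c(GABA = -65.9, a5pam = -95.3,
                                       PTX = 0),
                            noise_sd = 5, fs = 1000, seg_seconds = 2,
                            seed = 1, baseline = 0) {
  stopifnot(all(is.finite(levels)),
            all(c("GABA", "a5pam", "PTX") %in% names(levels)))
  set.seed(seed)
  nseg <- round(seg_seconds * fs)
  conds <- c("GABA", "a5pam", "PTX")
  out <- list()
  for (k in seq_along(conds)) {
    cur <- baseline + levels[[conds[k]]] +
      stats::rnorm(nseg, 0, noise_sd)
    t0 <- (k - 1) * seg_seconds * 1000
    out[[k]] <- data.frame(time_ms = t0 + seq_len(nseg) * 1000 / fs,
                           current_pA = cur, condition = conds[k])
  }
  do.call(rbind, out)
}

#' Extract PTX-relative current levels from a clamp trace
#'
#' @param trace a [gen_clamp_trace()]-style data.frame.
#' @return named levels (pA) relative to the picrotoxin segment mean.
#' @export
extract_clamp_levels <- function(trace) {
  m <- tapply(trace$current_pA, trace$condition, mean)
  ref <- m[["PTX"]]
  c(GABA = m[["GABA"]] - ref, a5pam = m[["a5pam"]] - ref)
}
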