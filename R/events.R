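#' Oscillation-event detection parameters
#'
#' @param medthresh median-normalized power threshold for event peaks
#'   (> 1).
#' @param freq_range analyzed frequency range (Hz).
#' @param freq_step frequency grid step (Hz).
#' @param winsz analysis window (s); signals are processed in consecutive
#'   windows of this size.
#' @param overlapth maximal allowed bounding-box overlap fraction; of two
#'   events overlapping more, the one with the higher peak survives.
#' @param cycles Morlet wavelet width (cycles).
#' @return object of class `event_params`.
#' @export
event_params <- function(medthresh = 4.0, freq_range = c(1, 100),
                         freq_step = 0.5, winsz = 24, overlapth = 0.5,
                         cycles = 7) {
  if (medthresh <= 1) stop("medthresh must exceed 1")
  if (overlapth < 0 || overlapth > 1) stop("overlapth must lie in [0, 1]")
  structure(list(medthresh = medthresh, freq_range = freq_range,
                 freq_step = freq_step, winsz = winsz,
                 overlapth = overlapth, cycles = cycles),
            class = "event_params")
}

#' Morlet-wavelet spectrogram
#'
#' Complex Morlet transform via FFT-domain Gaussian filtering (analytic
#' signal convention, unit gain at the center frequency), evaluated on the
#' configured frequency grid.  Signals longer than one analysis window are
#' processed in consecutive windows whose spectrograms are concatenated; a
#' trailing remainder shorter than half a window is dropped.
#'
#' @param x signal.
#' @param fs sampling rate (Hz); must exceed twice the maximum frequency.
#' @param params an [event_params()].
#' @return list with `t` (s), `freq` (Hz) and `power` (freq x time).
#' @export
wavelet_spectrogram <- function(x, fs, params = event_params()) {
  stopifnot(inherits(params, "event_params"))
  if (fs < 2 * params$freq_range[2])
    stop("sampling rate too low for the maximum frequency")
  nwin <- round(params$winsz * fs)
  if (length(x) < nwin)
    stop("signal shorter than the analysis window")
  freqs <- seq(params$freq_range[1], params$freq_range[2],
               by = params$freq_step)
  starts <- seq(1, length(x) - nwin + 1, by = nwin)
  blocks <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    seg <- x[starts[b]:(starts[b] + nwin - 1)]
    X <- stats::fft(seg)
    fgrid <- c(seq(0, floor(nwin / 2)),
               seq(-ceiling(nwin / 2) + 1, -1)) * fs / nwin
    P <- matrix(NA_real_, length(freqs), nwin)
    for (i in seq_along(freqs)) {
      f0 <- freqs[i]
      s <- params$cycles / (2 * pi * f0)
      H <- 2 * exp(-0.5 * (2 * pi * (fgrid - f0))^2 * s^2)
      H[fgrid < 0] <- 0
      w <- stats::fft(X * H, inverse = TRUE) / nwin
      P[i, ] <- Mod(w)^2
    }
    blocks[[b]] <- P
  }
  power <- do.call(cbind, blocks)
  list(t = seq_len(ncol(power)) / fs, freq = freqs, power = power)
}

#' Detect oscillatory events in a spectrogram
#'
#' Each frequency row is normalized by its median power; local maxima of
#' the normalized spectrogram exceeding `medthresh` seed events.  A
#' bounding box is grown from each seed along time (at the peak frequency)
#' and along frequency (at the peak time) until the normalized power falls
#' below half the peak's normalized value.  Seeds are processed in
#' descending peak order; an event whose box overlaps an accepted event's
#' box by more than `overlapth` (intersection over the smaller box) is
#' discarded.
#'
#' @param spec a [wavelet_spectrogram()] result.
#' @param params an [event_params()].
#' @return data.frame of events: `peak_freq`, `peak_time`, `t_start`,
#'   `t_end`, `f_lo`, `f_hi`, `peak_norm_power`, `band`; zero rows when
#'   nothing crosses threshold.
#' @export
detect_events <- function(spec, params = event_params()) {
  P <- spec$power
  nf <- nrow(P); nt <- ncol(P)
  med <- apply(P, 1, stats::median)
  if (all(med == 0) || all(P == 0)) return(empty_events())
  med[med == 0] <- min(med[med > 0])
  N <- P / med

  above <- N > params$medthresh
  if (!any(above)) return(empty_events())
  idx <- which(above, arr.ind = TRUE)
  is_max <- vapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1]; j <- idx[k, 2]
    v <- N[i, j]
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nf && jj >= 1 && jj <= nt &&
          !(di == 0 && dj == 0) && N[ii, jj] > v) return(FALSE)
    }
    TRUE
  }, logical(1))
  seeds <- idx[is_max, , drop = FALSE]
  if (nrow(seeds) == 0) return(empty_events())
  ord <- order(-N[seeds])
  seeds <- seeds[ord, , drop = FALSE]

  grow <- function(i, j) {
    # boundary: power below half the peak, or back at the threshold level
    # for strong events (whichever is reached first going outward)
    edge <- min(N[i, j] / 2, params$medthresh)
    t0 <- j; while (t0 > 1 && N[i, t0 - 1] >= edge) t0 <- t0 - 1
    t1 <- j; while (t1 < nt && N[i, t1 + 1] >= edge) t1 <- t1 + 1
    f0 <- i; while (f0 > 1 && N[f0 - 1, j] >= edge) f0 <- f0 - 1
    f1 <- i; while (f1 < nf && N[f1 + 1, j] >= edge) f1 <- f1 + 1
    c(t0, t1, f0, f1)
  }
  overlap_frac <- function(a, b) {
    ti <- max(0, min(a[2], b[2]) - max(a[1], b[1]) + 1)
    fi <- max(0, min(a[4], b[4]) - max(a[3], b[3]) + 1)
    inter <- ti * fi
    inter / min((a[2] - a[1] + 1) * (a[4] - a[3] + 1),
                (b[2] - b[1] + 1) * (b[4] - b[3] + 1))
  }
  kept <- list(); boxes <- list()
  for (k in seq_len(nrow(seeds))) {
    i <- seeds[k, 1]; j <- seeds[k, 2]
    # a seed inside an accepted event's box belongs to that event
    inside <- FALSE
    for (b in boxes)
      if (j >= b[1] && j <= b[2] && i >= b[3] && i <= b[4]) {
        inside <- TRUE; break
      }
    if (inside) next
    bx <- grow(i, j)
    dup <- FALSE
    for (b in boxes)
      if (overlap_frac(bx, b) > params$overlapth) { dup <- TRUE; break }
    if (dup) next
    boxes <- c(boxes, list(bx))
    kept[[length(kept) + 1]] <- data.frame(
      peak_freq = spec$freq[i], peak_time = spec$t[j],
      t_start = spec$t[bx[1]], t_end = spec$t[bx[2]],
      f_lo = spec$freq[bx[3]], f_hi = spec$freq[bx[4]],
      peak_norm_power = N[i, j])
  }
  if (length(kept) == 0) return(empty_events())
  ev <- do.call(rbind, kept)
  ev$band <- classify_band(ev$peak_freq)
  ev
}

empty_events <- function() {
  data.frame(peak_freq = numeric(0), peak_time = numeric(0),
             t_start = numeric(0), t_end = numeric(0),
             f_lo = numeric(0), f_hi = numeric(0),
             peak_norm_power = numeric(0), band = character(0))
}

#' Per-event features
#'
#' Fills duration (s), frequency span (Hz), cycle count (duration times
#' peak frequency) and wave height: the maximal peak-to-trough amplitude of
#' the raw signal band-pass filtered to the event's frequency box (FFT
#' brick-wall filter), within the event's time window.
#'
#' @param events a [detect_events()] result.
#' @param x the raw signal the spectrogram came from.
#' @param fs sampling rate (Hz).
#' @return `events` with columns `duration`, `freq_span`, `cycle_count`,
#'   `wave_height` added.
#' @export
event_features <- function(events, x, fs) {
  n <- nrow(events)
  events$duration <- events$t_end - events$t_start
  events$freq_span <- events$f_hi - events$f_lo
  events$cycle_count <- events$duration * events$peak_freq
  wh <- numeric(n)
  if (n > 0) {
    X <- stats::fft(x)
    len <- length(x)
    fgrid <- abs(c(seq(0, floor(len / 2)),
                   seq(-ceiling(len / 2) + 1, -1))) * fs / len
    for (k in seq_len(n)) {
      mask <- fgrid >= events$f_lo[k] & fgrid <= events$f_hi[k]
      xb <- Re(stats::fft(X * mask, inverse = TRUE)) / len
      i0 <- max(1, floor(events$t_start[k] * fs))
      i1 <- min(len, ceiling(events$t_end[k] * fs))
      wh[k] <- max(xb[i0:i1]) - min(xb[i0:i1])
    }
  }
  events$wave_height <- wh
  events
}

#' Classify a peak frequency into a canonical band
#'
#' Half-open intervals `[lo, hi)`: delta 0.5-4, theta 4-9, alpha 9-15,
#' beta 15-29, low gamma 30-40, gamma 40-80 Hz.  The 29-30 Hz gap between
#' beta and low gamma is preserved: peaks inside it map to the nearer band
#' and are flagged via the `"gap"` attribute.  Frequencies outside
#' 0.5-80 Hz return `"unclassified"`.
#'
#' @param freq peak frequencies (Hz), vectorized.
#' @return character vector of band labels.
#' @export
classify_band <- function(freq) {
  lab <- rep("unclassified", length(freq))
  lab[freq >= 0.5 & freq < 4] <- "delta"
  lab[freq >= 4 & freq < 9] <- "theta"
  lab[freq >= 9 & freq < 15] <- "alpha"
  lab[freq >= 15 & freq < 29] <- "beta"
  lab[freq >= 30 & freq < 40] <- "lowgamma"
  lab[freq >= 40 & freq <= 80] <- "gamma"
  gap <- freq >= 29 & freq < 30
  lab[gap & freq < 29.5] <- "beta"
  lab[gap & freq >= 29.5] <- "lowgamma"
  attr(lab, "gap") <- gap
  lab
}
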