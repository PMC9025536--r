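#' Synthetic spike-train seizure signal
#'
#' A train of discrete impulses, the model for spike-like seizure activity:
#' zeros except unit-amplitude pulses at the samples nearest the requested
#' spike times. A Gaussian `width` (seconds) spreads each pulse over a few
#' samples, which is what real spikes look like after anti-alias filtering;
#' `width = 0` gives single-sample impulses.
#'
#' @param spike_times numeric vector of spike times in seconds (may be
#'   empty); must fall inside `[0, duration)`.
#' @param rate sampling rate in Hz.
#' @param duration signal duration in seconds.
#' @param amplitude pulse amplitude.
#' @param width Gaussian pulse standard deviation in seconds (0 = impulse).
#' @return a `sampled_signal`.
#' @examples
#' x <- gen_spike_train(c(1, 3.5, 6), rate = 32, duration = 8)
#' which(x$samples != 0)
#' @export
gen_spike_train <- function(spike_times, rate, duration, amplitude = 1,
                            width = 0) {
  n <- round(rate * duration)
  if (length(spike_times) &&
      (any(spike_times < 0) || any(spike_times >= duration)))
    stop_invalid("spike times must lie inside [0, duration)")
  x <- numeric(n)
  t <- (seq_len(n) - 1) / rate
  for (tn in spike_times) {
    if (width > 0) {
      x <- x + amplitude * exp(-(t - tn)^2 / (2 * width^2))
    } else {
      x[round(tn * rate) + 1] <- x[round(tn * rate) + 1] + amplitude
    }
  }
  sampled_signal(x, rate)
}

#' Synthetic harmonic chirp-sum seizure signal
#'
#' A sum of harmonically related, phase-continuous frequency-modulated
#' chirps: component `n` is `(amplitude / n^decay) * cos(2 pi n phi(t))`
#' where `phi(t)` is the running integral of the piecewise-linear
#' fundamental instantaneous frequency `f0(t)`. This is the model for the
#' rhythmic seizure class: a slowly varying fundamental below ~4 Hz plus
#' weaker harmonics (the default `decay = 1` is the roll-off of a
#' sawtooth-like slow wave).
#'
#' @param breakpoints two-column matrix or data.frame `(time_s, f0_hz)`
#'   defining the piecewise-linear fundamental; a single row gives a
#'   constant frequency.
#' @param n_harmonics number of harmonic components `N >= 1`.
#' @param rate sampling rate in Hz.
#' @param duration duration in seconds.
#' @param amplitude amplitude of the fundamental.
#' @param decay harmonic amplitude roll-off exponent (amplitude of the
#'   n-th harmonic is `amplitude / n^decay`).
#' @return a `sampled_signal`.
#' @examples
#' x <- gen_chirp_sum(cbind(c(0, 8), c(1, 3)), n_harmonics = 1,
#'                    rate = 32, duration = 8)
#' @export
gen_chirp_sum <- function(breakpoints, n_harmonics = 3, rate, duration,
                          amplitude = 1, decay = 1) {
  bp <- as.matrix(breakpoints)
  if (ncol(bp) != 2) stop_invalid("breakpoints must have columns (time, f0)")
  if (any(bp[, 2] <= 0)) stop_invalid("f0 must stay positive")
  if (n_harmonics < 1) stop_invalid("n_harmonics must be >= 1")
  if (n_harmonics * max(bp[, 2]) >= rate / 2)
    stop_invalid("highest harmonic would alias (n * max f0 >= rate/2)")
  n <- round(rate * duration)
  t <- (seq_len(n) - 1) / rate
  f0 <- if (nrow(bp) == 1) rep(bp[1, 2], n)
        else stats::approx(bp[, 1], bp[, 2], xout = t, rule = 2)$y
  # phase-continuous FM: trapezoidal running integral of f0
  phi <- c(0, cumsum((f0[-1] + f0[-n]) / 2)) / rate
  x <- numeric(n)
  for (k in seq_len(n_harmonics))
    x <- x + (amplitude / k^decay) * cos(2 * pi * k * phi)
  sampled_signal(x, rate)
}

#' Synthetic background noise
#'
#' Seeded broadband background: white Gaussian noise or power-law
#' (`1/f^exponent` power spectrum) coloured noise, whose time-frequency
#' ridges point in random directions -- the non-seizure class.
#'
#' @param rate sampling rate in Hz.
#' @param duration duration in seconds.
#' @param amplitude target sample standard deviation (0 gives silence).
#' @param model `"white"` or `"powerlaw"`.
#' @param exponent power-spectrum exponent for `model = "powerlaw"`.
#' @param seed integer seed; the same seed always yields the same signal.
#' @return a `sampled_signal`.
#' @export
gen_background <- function(rate, duration, amplitude = 1,
                           model = c("white", "powerlaw"), exponent = 1,
                           seed = 1) {
  model <- match.arg(model)
  if (amplitude < 0) stop_invalid("amplitude must be >= 0")
  n <- round(rate * duration)
  x <- with_seed(seed, stats::rnorm(n))
  if (model == "powerlaw") {
    f <- c(1, seq_len(n - 1))                     # DC guarded
    f <- pmin(f, n - f + 1)                       # two-sided bin distance
    shape <- f^(-exponent / 2)
    x <- Re(stats::fft(stats::fft(x) * shape, inverse = TRUE)) / n
  }
  s <- stats::sd(x)
  if (amplitude == 0 || s == 0) x <- numeric(n) else x <- x * amplitude / s
  sampled_signal(x, rate)
}

#' Multi-channel EEG recording container
#'
#' @param channels numeric matrix, channels x samples, in microvolts.
#' @param rate sampling rate in Hz.
#' @param channel_labels character vector of 10-20 electrode names.
#' @param patient_id patient identifier.
#' @param annotations data.frame with columns `start_s`, `end_s` giving
#'   seizure intervals (half-open, seconds from record start).
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(channels, rate, channel_labels = NULL,
                          patient_id = "P1",
                          annotations = data.frame(start_s = numeric(),
                                                   end_s = numeric())) {
  channels <- as.matrix(channels)
  if (nrow(channels) < 1 || ncol(channels) < 2)
    stop_invalid("recording needs >= 1 channel and >= 2 samples")
  if (rate <= 0) stop_invalid("rate must be positive")
  if (is.null(channel_labels))
    channel_labels <- paste0("CH", seq_len(nrow(channels)))
  dur <- ncol(channels) / rate
  ann <- as.data.frame(annotations)
  if (nrow(ann)) {
    if (any(ann$start_s < 0) || any(ann$end_s <= ann$start_s))
      stop_invalid("annotations must satisfy 0 <= start_s < end_s")
    if (any(ann$end_s > dur + 1e-9))
      stop_invalid("annotation extends beyond record duration")
  }
  structure(list(channels = channels, rate = rate,
                 channel_labels = channel_labels,
                 patient_id = as.character(patient_id),
                 annotations = ann),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s), %d seizure interval(s)\n",
    x$patient_id, nrow(x$channels), ncol(x$channels), x$rate,
    ncol(x$channels) / x$rate, nrow(x$annotations)))
  invisible(x)
}

# default electrode subset of the 10-20 system
.default_montage <- c("Fp1", "Fp2", "C3", "C4", "T3", "T4", "O1", "O2")

#' Seeded synthetic multi-patient EEG dataset
#'
#' Generates reproducible multi-channel recordings with labelled seizure
#' intervals: each patient gets independent coloured-noise background per
#' channel plus one seizure waveform (a spike train or a harmonic chirp
#' sum) mixed into all channels with per-channel gains. Defaults encode
#' the synthetic study conditions used throughout the package: 6 patients,
#' 192 s at 256 Hz, 8 channels, one seizure interval `[48, 152)` s,
#' seizure amplitude 4 against background standard deviation 1, spike
#' trains (~1 Hz, 20 ms width) for even-numbered patients and chirp sums
#' (N = 3 harmonics, fundamental wandering in 1-3 Hz) for odd-numbered
#' ones.
#'
#' @param n_patients number of patients.
#' @param duration_s record duration per patient, seconds.
#' @param rate sampling rate in Hz.
#' @param n_channels channels per recording.
#' @param seizure_interval numeric `c(start, end)` seconds, identical for
#'   every patient (kept simple and segment-aligned), or a list of one
#'   interval per patient. Intervals must not overlap within a patient.
#' @param seizure_amplitude seizure waveform amplitude.
#' @param background_amplitude background noise standard deviation.
#' @param background_model `"powerlaw"` (default, 1/f) or `"white"`.
#' @param seed master seed; everything derives from it.
#' @return list of `eeg_recording` objects, one per patient.
#' @examples
#' recs <- gen_recording(n_patients = 2, duration_s = 48,
#'                       seizure_interval = c(16, 32), seed = 7)
#' recs[[1]]
#' @export
gen_recording <- function(n_patients = 6, duration_s = 192, rate = 256,
                          n_channels = 8,
                          seizure_interval = c(48, 152),
                          seizure_amplitude = 4,
                          background_amplitude = 1,
                          background_model = c("powerlaw", "white"),
                          seed = 1) {
  background_model <- match.arg(background_model)
  if (n_patients < 1) stop_invalid("need at least one patient")
  if (!is.list(seizure_interval))
    seizure_interval <- rep(list(seizure_interval), n_patients)
  lapply(seq_len(n_patients), function(p) {
    pid <- sprintf("P%02d", p)
    iv <- seizure_interval[[p]]
    if (!is.null(iv)) {
      iv <- matrix(unlist(iv), ncol = 2, byrow = !is.matrix(iv))
      o <- order(iv[, 1])
      iv <- iv[o, , drop = FALSE]
      if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2]))
        stop_invalid("seizure intervals overlap for patient ", pid)
      if (any(iv[, 1] < 0) || any(iv[, 2] > duration_s))
        stop_invalid("seizure interval outside the record for patient ", pid)
    }
    pseed <- derive_seed(seed, pid)
    n <- round(duration_s * rate)
    seiz <- numeric(n)
    ann <- data.frame(start_s = numeric(), end_s = numeric())
    if (!is.null(iv) && nrow(iv)) {
      for (r in seq_len(nrow(iv))) {
        s0 <- iv[r, 1]; s1 <- iv[r, 2]
        len <- s1 - s0
        wav <- if (p %% 2 == 0) {
          times <- with_seed(pseed + r, {
            tt <- seq(0.5, len - 0.5, by = 1)
            pmax(0, pmin(len - 1 / rate, tt + stats::runif(length(tt), -0.1, 0.1)))
          })
          gen_spike_train(times, rate, len, amplitude = seizure_amplitude,
                          width = 0.02)
        } else {
          bp <- with_seed(pseed + r, {
            tt <- seq(0, len, by = 20)
            if (tt[length(tt)] < len) tt <- c(tt, len)
            cbind(tt, stats::runif(length(tt), 1, 3))
          })
          gen_chirp_sum(bp, n_harmonics = 3, rate = rate, duration = len,
                        amplitude = seizure_amplitude, decay = 1)
        }
        i0 <- round(s0 * rate) + 1
        seiz[i0:(i0 + length(wav$samples) - 1)] <- wav$samples
        ann <- rbind(ann, data.frame(start_s = s0, end_s = s1))
      }
    }
    gains <- with_seed(pseed + 101, stats::runif(n_channels, 0.7, 1.3))
    ch <- matrix(0, n_channels, n)
    for (c_ in seq_len(n_channels)) {
      bg <- gen_background(rate, duration_s, amplitude = background_amplitude,
                           model = background_model, exponent = 1,
                           seed = pseed + 200 + c_)
      ch[c_, ] <- gains[c_] * seiz + bg$samples
    }
    labels <- make.unique(rep(.default_montage, length.out = n_channels))
    eeg_recording(ch, rate, labels, pid, ann)
  })
}
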