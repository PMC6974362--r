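#' Epoch and average a continuous recording
#'
#' Cuts the recording into consecutive non-overlapping epochs and averages
#' them point-wise. The default epoch length is derived from the stimulus:
#' exactly two inter-transition intervals (`2 / alt_rate_hz`, 294.1 ms for the
#' 6.8 Hz transition rate -- one shift out of phase and one back), so that a
#' 300-epoch run spans 1.47 min and both the 6.8 Hz and 40.8 Hz components
#' complete integer numbers of cycles per epoch. Epoching starts at a
#' diotic-to-dichotic transition (the phase origin of synthetic recordings);
#' `offset_s` realigns imported data.
#'
#' @param rec a [continuous_recording()].
#' @param epoch_s epoch duration, s; default `2 / alt_rate_hz` from the
#'   stimulus spec (0.2941 s), or 0.2943 s if no spec is attached.
#' @param n_epochs number of epochs to average.
#' @param offset_s alignment offset from the start of the recording, s.
#' @return a [waveform()] of one averaged epoch.
#' @export
epoch_and_average <- function(rec, epoch_s = NULL, n_epochs = 300,
                              offset_s = 0) {
  stopifnot(inherits(rec, "continuous_recording"))
  fs <- rec$sample_rate_hz
  if (is.null(epoch_s))
    epoch_s <- if (!is.null(rec$stimulus_spec))
      2 / rec$stimulus_spec$alt_rate_hz else 0.2943
  n0 <- round(offset_s * fs)
  need <- n0 + round(n_epochs * epoch_s * fs)
  if (length(rec$samples) < need)
    stop(sprintf("recording too short: need %.2f s (%d epochs x %.4f s), have %.2f s",
                 need / fs, n_epochs, epoch_s, length(rec$samples) / fs))
  # per-epoch rounded starts: keeps alignment error < 1 sample even when the
  # epoch duration is not an integer number of samples
  n_len <- floor(epoch_s * fs)
  starts <- n0 + round((seq_len(n_epochs) - 1) * epoch_s * fs)
  acc <- rep(0, n_len)
  for (s in starts) acc <- acc + rec$samples[(s + 1):(s + n_len)]
  waveform(acc / n_epochs, fs)
}

#' IPDFR and envelope-following spectral amplitudes
#'
#' Amplitudes of the interaural-phase-difference following response (at the
#' transition rate, 6.8 Hz) and the envelope following response (at the AM
#' rate, 40.8 Hz) of an averaged epoch, computed by sine/cosine projection at
#' the exact target frequencies rather than an FFT bin lookup (the 294 ms
#' epoch puts neither target on the DFT grid). The normalized response is
#' their ratio, which cancels overall gain (head size, electrode impedance).
#'
#' @param avg a [waveform()] from [epoch_and_average()].
#' @param ipd_hz,efr_hz target frequencies, Hz.
#' @return a list of class `ipdfr_result`: `ipdfr_amp`, `efr_amp`,
#'   `normalized`.
#' @export
spectral_amplitudes <- function(avg, ipd_hz = 6.8, efr_hz = 40.8) {
  stopifnot(inherits(avg, "waveform"))
  amps <- projection_amplitude(avg, c(ipd_hz, efr_hz))
  if (amps[2] <= 1e-12 * stats::sd(as.numeric(avg)))
    stop("normalization error: envelope following response amplitude is ~0")
  structure(list(ipdfr_amp = amps[1], efr_amp = amps[2],
                 normalized = amps[1] / amps[2]),
            class = "ipdfr_result")
}

#' Peak frequency of an averaged epoch within a band
#'
#' Identifies the dominant spectral component of an epoch-averaged response
#' inside `band_hz`. A single averaged epoch is short (294 ms, ~3.4 Hz
#' resolution), so the raw-window argmax can be pushed off the true line
#' frequency by edge truncation and neighboring components; since the average
#' estimates one period of the steady-state response, its periodic extension
#' (`n_tile` repetitions) is analyzed instead, which sharpens each spectral
#' line by a factor `n_tile` without adding information. The amplitude
#' spectrum is evaluated on a fine grid via a zero-padded FFT (identical to
#' sine/cosine projection on that grid).
#'
#' @param avg a [waveform()] from [epoch_and_average()].
#' @param band_hz two-element frequency band to search, Hz.
#' @param n_tile number of periodic repetitions to analyze.
#' @param resolution_hz upper bound on the frequency-grid spacing.
#' @return list with `freq_hz` (peak location) and `amplitude`.
#' @export
spectral_peak <- function(avg, band_hz, n_tile = 20, resolution_hz = 0.01) {
  stopifnot(inherits(avg, "waveform"), length(band_hz) == 2)
  fs <- sample_rate(avg)
  x <- rep(as.numeric(avg) - mean(avg), n_tile)
  nfft <- 2^ceiling(log2(fs / resolution_hz))
  nfft <- max(nfft, length(x))
  X <- fft(c(x, rep(0, nfft - length(x))))
  f <- (0:(nfft - 1)) * fs / nfft
  keep <- which(f >= band_hz[1] & f <= band_hz[2])
  mag <- Mod(X[keep])
  i <- which.max(mag)
  list(freq_hz = f[keep[i]], amplitude = 2 * mag[i] / length(x))
}

#' Normalized IPDFR growth curve over total interaural difference
#'
#' Assembles per-condition normalized IPDFR amplitudes into a growth curve on
#' the *total* IPD axis (twice the per-ear shift, since shifts are applied to
#' the two ears in opposing polarity), ready for [fit_sigmoid()] and
#' [slope_metric()].
#'
#' @param results list of `ipdfr_result` objects.
#' @param per_ear_shift_deg per-ear shifts (degrees) matching `results`; must
#'   include 0 and at least three conditions.
#' @return a [growth_curve()] over total IPD (degrees).
#' @export
ipdfr_growth <- function(results, per_ear_shift_deg) {
  stopifnot(length(results) == length(per_ear_shift_deg))
  if (length(results) < 3 || !any(per_ear_shift_deg == 0))
    stop("need >= 3 shift conditions including 0 degrees")
  y <- vapply(results, function(r) r$normalized, numeric(1))
  o <- order(per_ear_shift_deg)
  growth_curve(2 * per_ear_shift_deg[o], y[o],
               x_label = "total IPD (deg)", y_label = "IPDFR (re EFR)")
}
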