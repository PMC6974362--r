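#' Grand-average ABR waveform
#'
#' Mean across all epochs of both polarities; the polarity-flipping stimulus
#' artifact cancels, neural deflections remain at their generating amplitude.
#'
#' @param resp an [epoched_response()].
#' @return a [waveform()].
#' @export
abr_average <- function(resp) {
  stopifnot(inherits(resp, "epoched_response"))
  avg <- (colMeans(resp$epochs_pos) + colMeans(resp$epochs_neg)) / 2
  waveform(avg, resp$sample_rate_hz)
}

#' Zero-phase band-pass filter for averaged ABRs
#'
#' Forward-backward (zero-phase) Butterworth band-pass, 300 Hz to 3 kHz by
#' default, applied to the averaged waveform before peak picking. Zero-phase
#' filtering preserves peak latencies.
#'
#' @param avg a [waveform()].
#' @param lo,hi band edges, Hz.
#' @param order Butterworth prototype order (each of the high- and low-pass
#'   sections; filtfilt doubles the effective attenuation).
#' @return the filtered [waveform()].
#' @export
bandpass_abr <- function(avg, lo = 300, hi = 3000, order = 4) {
  stopifnot(inherits(avg, "waveform"))
  fs <- sample_rate(avg)
  if (!(lo > 0 && hi > lo)) stop("invalid band")
  if (fs <= 2 * hi) stop("sample rate must exceed twice the upper band edge")
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  x <- as.numeric(avg)
  # pad by reflection so the IIR transient does not wrap into the short epoch
  np <- min(length(x) - 1, 3 * order * 10)
  xp <- c(rev(x[seq_len(np)]), x, rev(x[length(x) - seq_len(np) + 1]))
  y <- signal::filtfilt(bf, xp)[(np + 1):(np + length(x))]
  waveform(y, fs)
}

#' Pick ABR wave 1 (peak minus following trough)
#'
#' Automated stand-in for manual wave marking: the peak is the maximum within
#' a fixed search window (1-3 ms by default, bracketing the auditory-nerve
#' wave), and the trough is the minimum within `trough_horizon_ms` after the
#' peak. Wave-1 amplitude is peak minus trough, so it is invariant to DC
#' offset. A waveform with no local extrema in the window (e.g. flat or
#' monotone) raises a no-pick error rather than returning zero.
#'
#' @param filtered a band-passed [waveform()] (see [bandpass_abr()]).
#' @param search_window_ms two-element window for the peak, ms.
#' @param trough_horizon_ms how far past the peak to search for the trough, ms.
#' @return a list of class `wave_pick`: `peak_latency_ms`, `peak_amp`,
#'   `trough_latency_ms`, `trough_amp`, `wave1_amp`.
#' @export
pick_wave1 <- function(filtered, search_window_ms = c(1, 3),
                       trough_horizon_ms = 1.5) {
  stopifnot(inherits(filtered, "waveform"))
  fs <- sample_rate(filtered)
  x <- as.numeric(filtered)
  t_ms <- time_axis(length(x), fs) * 1000
  if (search_window_ms[2] > max(t_ms)) stop("search window outside epoch")
  win <- which(t_ms >= search_window_ms[1] & t_ms <= search_window_ms[2])
  # require a genuine local maximum inside the window
  interior <- win[win > 1 & win < length(x)]
  is_max <- x[interior] > x[interior - 1] & x[interior] >= x[interior + 1]
  if (!any(is_max) || diff(range(x[win])) == 0)
    stop("no-pick: no local maximum in the search window")
  cand <- interior[is_max]
  ipk <- cand[which.max(x[cand])]
  horizon <- which(t_ms > t_ms[ipk] &
                     t_ms <= t_ms[ipk] + trough_horizon_ms)
  if (length(horizon) == 0) stop("no-pick: no samples after peak")
  itr <- horizon[which.min(x[horizon])]
  structure(list(peak_latency_ms = t_ms[ipk], peak_amp = x[ipk],
                 trough_latency_ms = t_ms[itr], trough_amp = x[itr],
                 wave1_amp = x[ipk] - x[itr]),
            class = "wave_pick")
}
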