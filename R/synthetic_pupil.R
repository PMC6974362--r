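#' Simulate a pupillometry session for the digits-in-noise task
#'
#' Emits 30 Hz pupil-diameter traces for a blocked session of the multi-talker
#' digits task. Each trial is 2 s baseline, 2 s digit presentation, 2 s wait.
#' The task-evoked dilation is a gamma-shaped bump peaking ~1.2 s after digit
#' onset whose *fractional* peak grows linearly as SNR falls:
#' `peak_frac(snr) = effort_gain * (12 - snr) / 12`, so `effort_gain` is the
#' fractional dilation at 0 dB SNR and harder blocks always dilate more.
#' Blinks appear as runs of missing samples, plus occasional single-sample
#' spikes. A bright/dark light-calibration pair is included, defining the
#' subject's full dynamic range.
#'
#' @param snr_schedule block SNRs in dB; default 40 blocks with each cycle of
#'   four a random permutation of 9, 6, 3, 0 (the task's block order).
#' @param trials_per_block scored trials per block.
#' @param effort_gain fractional dilation at the hardest SNR (0 dB).
#' @param blink_rate blink events per second.
#' @param spike_rate single-sample outlier events per second.
#' @param noise_sd additive measurement noise SD (mm).
#' @param baseline_mm resting pupil diameter (mm).
#' @param drift_amp_mm amplitude of slow session-scale baseline drift (mm).
#' @param bright_mm,dark_mm diameters under the bright and dark calibration
#'   screens (mm); their difference is the light-induced range.
#' @param seed integer seed.
#' @param sample_rate_hz sampling rate; the pupillometer runs at 30 Hz.
#' @return an object of class `pupil_session`: a list with `trace` (data frame
#'   with time, diameter, missing, block, trial, snr, phase), `sample_rate_hz`,
#'   `light` (bright/dark/range), and `ground_truth` (per-SNR fractional
#'   peaks).
#' @export
simulate_pupil_session <- function(snr_schedule = NULL, trials_per_block = 5,
                                   effort_gain = 0.2, blink_rate = 0.05,
                                   spike_rate = 0.01, noise_sd = 0.02,
                                   baseline_mm = 4.5, drift_amp_mm = 0.15,
                                   bright_mm = 2, dark_mm = 7, seed = 1L,
                                   sample_rate_hz = 30) {
  set.seed(as.integer(seed))
  if (is.null(snr_schedule))
    snr_schedule <- as.vector(replicate(10, sample(c(9, 6, 3, 0))))
  stopifnot(all(snr_schedule %in% c(9, 6, 3, 0)))
  fs <- sample_rate_hz
  phase_s <- c(baseline = 2, digits = 2, wait = 2)
  n_trial <- round(sum(phase_s) * fs)
  t_trial <- time_axis(n_trial, fs)
  phase <- cut(t_trial, breaks = c(0, cumsum(phase_s)), right = FALSE,
               labels = c("baseline", "digits", "wait"))
  peak_frac <- function(snr) effort_gain * (12 - snr) / 12
  # evoked kernel: unit-peak gamma bump from digit onset, peak at 1.2 s
  tp <- 1.2
  kern <- pmax(t_trial - phase_s[["baseline"]], 0) / tp
  kern <- kern * exp(1 - kern)
  n_blocks <- length(snr_schedule)
  total_trials <- n_blocks * trials_per_block
  rows <- vector("list", total_trials)
  k <- 0
  for (b in seq_len(n_blocks)) {
    for (tr in seq_len(trials_per_block)) {
      k <- k + 1
      drift <- drift_amp_mm * sin(2 * pi * k / total_trials)
      b0 <- baseline_mm + drift
      d <- b0 + b0 * peak_frac(snr_schedule[b]) * kern
      if (noise_sd > 0) d <- d + rnorm(n_trial, sd = noise_sd)
      miss <- rep(FALSE, n_trial)
      n_blinks <- rpois(1, blink_rate * sum(phase_s))
      for (i in seq_len(n_blinks)) {
        st <- sample.int(n_trial - 10, 1)
        len <- round(runif(1, 0.1, 0.3) * fs)
        idx <- st:min(st + len, n_trial - 1)   # keep trace edges observed
        idx <- idx[idx > 1]
        miss[idx] <- TRUE
      }
      n_spikes <- rpois(1, spike_rate * sum(phase_s))
      if (n_spikes > 0) {
        at <- sample(which(!miss), n_spikes)
        d[at] <- d[at] + sample(c(-1, 1), n_spikes, TRUE) * runif(n_spikes, 1.5, 2.5)
      }
      d[miss] <- NA_real_
      rows[[k]] <- data.frame(
        time = (k - 1) * sum(phase_s) + t_trial, diameter = d, missing = miss,
        block = b, trial = tr, snr = snr_schedule[b],
        phase = as.character(phase))
    }
  }
  gt_snrs <- sort(unique(snr_schedule), decreasing = TRUE)
  structure(list(trace = do.call(rbind, rows), sample_rate_hz = fs,
                 light = list(bright_mm = bright_mm, dark_mm = dark_mm,
                              range_mm = dark_mm - bright_mm),
                 ground_truth = list(
                   snr = gt_snrs,
                   peak_frac = peak_frac(gt_snrs),
                   effort_gain = effort_gain)),
            class = "pupil_session")
}

#' @export
print.pupil_session <- function(x, ...) {
  cat(sprintf("<pupil_session: %d blocks, %d samples @ %g Hz, light range %g mm>\n",
              max(x$trace$block), nrow(x$trace), x$sample_rate_hz,
              x$light$range_mm))
  invisible(x)
}
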