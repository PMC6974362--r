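#' Preprocess a pupil-diameter trace
#'
#' Cleaning chain applied, in order: (1) cubic-spline interpolation across
#' blinks and missing periods; (2) Hampel filter (rolling median/MAD outlier
#' replacement) to remove spikes; (3) centered 5-point moving average. Gaps
#' touching the trace boundary cannot be spline-interpolated; with
#' `edge_mode = "nearest"` they are filled with the nearest observed value,
#' otherwise they raise an error.
#'
#' @param diameter numeric vector of diameters, `NA` where missing.
#' @param missing optional logical mask (defaults to `is.na(diameter)`).
#' @param hampel_k half-width of the Hampel window in samples (window =
#'   `2k + 1` = 7 samples, ~233 ms at 30 Hz).
#' @param hampel_t0 Hampel threshold in scaled MADs.
#' @param ma_points moving-average length (odd).
#' @param edge_mode `"error"` or `"nearest"`.
#' @return numeric vector, same length, no missing values.
#' @export
preprocess_pupil <- function(diameter, missing = NULL, hampel_k = 3,
                             hampel_t0 = 3, ma_points = 5,
                             edge_mode = c("error", "nearest")) {
  edge_mode <- match.arg(edge_mode)
  x <- as.numeric(diameter)
  miss <- if (is.null(missing)) is.na(x) else (missing | is.na(x))
  if (all(miss)) stop("no observed samples to interpolate from")
  if (any(miss)) {
    if ((miss[1] || miss[length(x)]) && edge_mode == "error")
      stop("gap touches the trace boundary; set edge_mode = 'nearest'")
    obs <- which(!miss)
    x[miss] <- spline(obs, x[obs], xout = which(miss), method = "natural")$y
    if (miss[1]) x[seq_len(obs[1] - 1)] <- x[obs[1]]
    if (miss[length(x)]) {
      last <- obs[length(obs)]
      x[(last + 1):length(x)] <- x[last]
    }
  }
  if (length(x) > 2 * hampel_k + 1)
    x <- pracma::hampel(x, k = hampel_k, t0 = hampel_t0)$y
  if (ma_points > 1) {
    half <- (ma_points - 1) / 2
    n <- length(x)
    # centered moving average; edges handled by reflection so a locally
    # linear trend passes through unbiased
    xp <- c(2 * x[1] - x[(half + 1):2], x, 2 * x[n] - x[(n - 1):(n - half)])
    x <- as.numeric(stats::filter(xp, rep(1 / ma_points, ma_points),
                                  sides = 2))[(half + 1):(half + n)]
  }
  x
}

#' Per-SNR peak fractional pupil change
#'
#' For each block, the baseline is the mean preprocessed diameter over the
#' last `baseline_window_s` of the pre-trial baseline period, averaged across
#' the block's trials. Each trial's fractional series over the digits window is
#' `(diameter - baseline) / baseline`; the per-SNR value is the *peak of the
#' across-trial average* fractional series for that SNR (not the average of
#' per-trial peaks).
#'
#' @param session a [simulate_pupil_session()] result, or any object with the
#'   same `trace`/`sample_rate_hz` structure.
#' @param baseline_window_s portion of the baseline period entering the
#'   baseline mean (last 0.5 s).
#' @param baseline_per `"block"` (default, as acquired) or `"trial"`.
#' @param ... passed to [preprocess_pupil()].
#' @return data frame with one row per SNR: `snr`, `peak_frac`, `n_trials`,
#'   ordered from easiest (highest SNR) to hardest.
#' @export
fractional_change <- function(session, baseline_window_s = 0.5,
                              baseline_per = c("block", "trial"), ...) {
  baseline_per <- match.arg(baseline_per)
  tr <- session$trace
  fs <- session$sample_rate_hz
  # preprocess per trial (each trial is recorded as a contiguous trace)
  key <- interaction(tr$block, tr$trial, drop = TRUE)
  cleaned <- unsplit(lapply(split(seq_len(nrow(tr)), key), function(idx) {
    preprocess_pupil(tr$diameter[idx], tr$missing[idx], ...)
  }), key)
  tr$clean <- cleaned
  base_of <- function(idx) {
    bl <- idx[tr$phase[idx] == "baseline"]
    nb <- round(baseline_window_s * fs)
    mean(tr$clean[tail(bl, nb)])
  }
  trial_ids <- unique(tr[, c("block", "trial", "snr")])
  trial_ids$baseline <- NA_real_
  for (i in seq_len(nrow(trial_ids))) {
    idx <- which(tr$block == trial_ids$block[i] & tr$trial == trial_ids$trial[i])
    trial_ids$baseline[i] <- base_of(idx)
  }
  if (baseline_per == "block") {
    bmean <- aggregate(baseline ~ block, trial_ids, mean)
    trial_ids$baseline <- bmean$baseline[match(trial_ids$block, bmean$block)]
  }
  if (any(trial_ids$baseline <= 0)) stop("non-positive baseline diameter")
  snrs <- sort(unique(tr$snr), decreasing = TRUE)
  out <- data.frame(snr = snrs, peak_frac = NA_real_, n_trials = NA_integer_)
  for (j in seq_along(snrs)) {
    ids <- trial_ids[trial_ids$snr == snrs[j], ]
    series <- NULL
    for (i in seq_len(nrow(ids))) {
      idx <- which(tr$block == ids$block[i] & tr$trial == ids$trial[i] &
                     tr$phase == "digits")
      frac <- (tr$clean[idx] - ids$baseline[i]) / ids$baseline[i]
      series <- if (is.null(series)) frac else series + frac
    }
    out$peak_frac[j] <- max(series / nrow(ids))
    out$n_trials[j] <- nrow(ids)
  }
  out
}

#' Pupil growth curve and effort slope metric
#'
#' Normalizes the per-SNR peak fractional changes by the subject's
#' light-induced pupil range (bright/dark calibration), puts them on a task
#' difficulty axis oriented so effort grows to the right
#' (`difficulty = max(snr) - snr`, dB), and returns the growth curve for
#' [fit_sigmoid()] / [slope_metric()]. Subjects with a non-positive light
#' range have unusable pupil data and are excluded with an error.
#'
#' @param peaks data frame from [fractional_change()].
#' @param light_range_mm bright-to-dark diameter span (> 0).
#' @return a [growth_curve()] over difficulty (dB below the easiest SNR).
#' @export
pupil_growth <- function(peaks, light_range_mm) {
  if (!is.finite(light_range_mm) || light_range_mm <= 0)
    stop("subject excluded: non-positive light-induced pupil range")
  if (nrow(peaks) < 3) stop("need >= 3 SNR conditions")
  difficulty <- max(peaks$snr) - peaks$snr
  o <- order(difficulty)
  growth_curve(difficulty[o], peaks$peak_frac[o] / light_range_mm,
               x_label = "difficulty (dB below easiest SNR)",
               y_label = "peak fractional change (re light range)")
}
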