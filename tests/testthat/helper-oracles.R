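# Independent oracles used to cross-check the package's estimators.
# These deliberately avoid the code paths they validate.

# Instantaneous frequency of a signal's component inside `band` (Hz) by
# finite differences of the analytic-signal phase: brick-wall band selection
# in the DFT, then Arg/unwrap/diff. Edges trimmed. For a multi-harmonic input
# (e.g. a rectified average: DC + 2F + 4F ...) the band isolates the single
# line whose frequency modulation is being measured.
inst_freq_oracle <- function(x, fs, band = NULL, trim_s = 0.05) {
  x <- as.numeric(x)
  n <- length(x)
  X <- stats::fft(x)
  half <- floor(n / 2)
  X[(half + 2):n] <- 0
  X[2:half] <- 2 * X[2:half]
  if (!is.null(band)) {
    f <- (0:(n - 1)) * fs / n
    X[f < band[1] | f > band[2]] <- 0
  }
  z <- stats::fft(X, inverse = TRUE) / n
  ph <- signal::unwrap(Arg(z))
  f_inst <- diff(ph) * fs / (2 * pi)
  k <- round(trim_s * fs)
  f_inst[(k + 1):(length(f_inst) - k)]
}

# FM excursion recovered from the rectified (2F) average: the 2F component
# swings +-2d about 2*carrier, so the excursion is (max - min) / 4 of the
# instantaneous frequency after smoothing out ripple.
excursion_oracle <- function(avg, fs, smooth_s = 0.02) {
  fi <- inst_freq_oracle(avg, fs, band = c(700, 1300))
  k <- round(smooth_s * fs)
  fi <- stats::filter(fi, rep(1 / k, k), sides = 2)
  fi <- fi[!is.na(fi)]
  (max(fi) - min(fi)) / 4
}

# Hampel filter by direct rolling median/MAD computation.
hampel_oracle <- function(x, k = 3, t0 = 3) {
  y <- x
  n <- length(x)
  for (i in (k + 1):(n - k)) {
    w <- x[(i - k):(i + k)]
    m <- median(w)
    s <- 1.4826 * median(abs(w - m))
    if (abs(x[i] - m) > t0 * s) y[i] <- m
  }
  y
}

# OLS R^2 via the normal equations, no lm().
ols_r2_oracle <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  beta <- solve(t(X1) %*% X1, t(X1) %*% y)
  yhat <- X1 %*% beta
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

# Build a synthetic pupil_session-shaped object from explicit trial traces.
# traces: list of numeric vectors (one per trial, all same length = 6 s * fs).
manual_pupil_session <- function(traces, snrs, fs = 30) {
  stopifnot(length(traces) == length(snrs))
  n <- length(traces[[1]])
  t_trial <- (0:(n - 1)) / fs
  phase <- cut(t_trial, breaks = c(0, 2, 4, 6), right = FALSE,
               labels = c("baseline", "digits", "wait"))
  rows <- lapply(seq_along(traces), function(k) {
    data.frame(time = (k - 1) * 6 + t_trial, diameter = traces[[k]],
               missing = FALSE, block = k, trial = 1, snr = snrs[k],
               phase = as.character(phase))
  })
  structure(list(trace = do.call(rbind, rows), sample_rate_hz = fs,
                 light = list(bright_mm = 2, dark_mm = 7, range_mm = 5)),
            class = "pupil_session")
}
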