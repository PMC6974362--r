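#' Simulated psychophysical observer
#'
#' A Bernoulli observer with a logistic psychometric function, anchored so
#' that performance at `true_threshold` is exactly 70.71% correct -- the
#' convergence point of a 2-down-1-up staircase. For the FM and IPD tasks the
#' logistic operates on log stimulus magnitude (matching the staircases'
#' multiplicative steps); for the speech task it operates on linear dB SNR.
#'
#' @param true_threshold stimulus magnitude (Hz, degrees, or dB SNR) at which
#'   the observer scores 70.71% correct.
#' @param slope logistic steepness (per log-unit for `log` scale, per dB for
#'   `linear`).
#' @param guess_rate chance performance (0.5 for 2AFC; `(1/8)^4` for the
#'   four-digit report task).
#' @param lapse_rate lapse probability in \[0, 0.1\].
#' @param scale `"log"` (FM/IPD magnitudes) or `"linear"` (dB SNR).
#' @return an object of class `observer_spec`.
#' @export
observer_spec <- function(true_threshold, slope = 4, guess_rate = 0.5,
                          lapse_rate = 0, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  stopifnot(guess_rate >= 0, guess_rate < 1,
            lapse_rate >= 0, lapse_rate <= 0.1, slope > 0)
  p_target <- sqrt(0.5)
  q <- (p_target - guess_rate) / (1 - guess_rate - lapse_rate)
  if (q <= 0 || q >= 1)
    stop("guess/lapse rates leave the 70.71% point unreachable")
  anchor <- if (scale == "log") log(true_threshold) else true_threshold
  # x0 such that p(true_threshold) = sqrt(1/2)
  x0 <- anchor - qlogis(q) / slope
  structure(list(true_threshold = true_threshold, slope = slope,
                 guess_rate = guess_rate, lapse_rate = lapse_rate,
                 scale = scale, x0 = x0),
            class = "observer_spec")
}

#' Probability of a correct response at a given stimulus magnitude
#'
#' @param obs an [observer_spec()].
#' @param magnitude stimulus magnitude(s); for `"log"`-scale observers these
#'   must be positive. Larger magnitudes (deeper excursions, wider IPDs,
#'   higher SNRs) are always easier.
#' @return probability/ies of a correct response.
#' @export
observer_p_correct <- function(obs, magnitude) {
  stopifnot(inherits(obs, "observer_spec"))
  x <- if (obs$scale == "log") log(magnitude) else magnitude
  obs$guess_rate + (1 - obs$guess_rate - obs$lapse_rate) *
    plogis(obs$slope * (x - obs$x0))
}

#' Draw a Bernoulli response from a simulated observer
#'
#' Uses the current RNG stream; seed control belongs to the caller (the
#' staircase/protocol drivers take explicit seeds).
#'
#' @inheritParams observer_p_correct
#' @return logical: was the trial correct?
#' @export
simulate_observer_response <- function(obs, magnitude) {
  stopifnot(all(magnitude >= 0))
  rbinom(length(magnitude), 1, observer_p_correct(obs, magnitude)) == 1
}
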