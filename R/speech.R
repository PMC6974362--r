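#' Multi-talker digits task protocol
#'
#' Trial schedule for the competing-digits task: practice blocks with feedback
#' (logged, never scored into the fit), then `n_blocks` test blocks of
#' `n_refresher + n_test` trials. Refreshers present the target at 20 dB SNR
#' to re-familiarize the listener; the remaining trials run at the block SNR.
#' Block SNRs cycle through `test_snrs_db` in a freshly randomized order every
#' `length(test_snrs_db)` blocks. A trial is correct only if all four reported
#' digits match; with 8 alternatives per digit, chance is `(1/8)^4`.
#'
#' @param n_blocks number of test blocks (40).
#' @param n_refresher refresher trials opening each block (3, at 20 dB SNR).
#' @param n_test test trials closing each block (5, at the block SNR).
#' @param test_snrs_db the cycled block SNRs (9, 6, 3, 0 dB).
#' @param refresher_snr_db refresher SNR (20 dB).
#' @param practice_snrs_db SNRs of the four 5-trial practice blocks
#'   (`Inf` = target only).
#' @param practice_trials trials per practice block.
#' @return an object of class `speech_protocol`.
#' @export
speech_protocol <- function(n_blocks = 40, n_refresher = 3, n_test = 5,
                            test_snrs_db = c(9, 6, 3, 0),
                            refresher_snr_db = 20,
                            practice_snrs_db = c(Inf, 20, 9, 3),
                            practice_trials = 5) {
  stopifnot(n_blocks %% length(test_snrs_db) == 0)
  structure(list(n_blocks = n_blocks, n_refresher = n_refresher,
                 n_test = n_test, test_snrs_db = test_snrs_db,
                 refresher_snr_db = refresher_snr_db,
                 practice_snrs_db = practice_snrs_db,
                 practice_trials = practice_trials),
            class = "speech_protocol")
}

#' Chance level of the four-digit report task
#'
#' Eight response alternatives per digit, four digits, all-correct scoring.
#' @return `(1/8)^4`.
#' @export
digits_guess_rate <- function() (1 / 8)^4

#' Simulate a full digits-task session
#'
#' Runs the protocol against a linear-dB-SNR observer and returns the complete
#' trial ledger. Practice and refresher trials are flagged so that threshold
#' fitting can exclude them. Observers are evaluated at `Inf` SNR (target
#' only) via their asymptote.
#'
#' @param protocol a [speech_protocol()].
#' @param observer an [observer_spec()] with `scale = "linear"` over dB SNR.
#' @param seed integer seed (block-order randomization and responses).
#' @return data frame of class `speech_trials`: `stage` (practice/test),
#'   `block`, `trial`, `snr_db`, `role` (practice/refresher/test), `correct`.
#' @export
run_speech_session <- function(protocol, observer, seed = 1L) {
  stopifnot(inherits(protocol, "speech_protocol"),
            inherits(observer, "observer_spec"),
            observer$scale == "linear")
  set.seed(as.integer(seed))
  p_correct <- function(snr) {
    if (is.infinite(snr)) 1 - observer$lapse_rate else
      observer_p_correct(observer, snr)
  }
  rows <- list()
  for (b in seq_along(protocol$practice_snrs_db)) {
    snr <- protocol$practice_snrs_db[b]
    for (tr in seq_len(protocol$practice_trials))
      rows[[length(rows) + 1]] <- data.frame(
        stage = "practice", block = b, trial = tr, snr_db = snr,
        role = "practice", correct = rbinom(1, 1, p_correct(snr)) == 1)
  }
  n_cycle <- length(protocol$test_snrs_db)
  block_snrs <- as.vector(vapply(seq_len(protocol$n_blocks / n_cycle),
                                 function(i) sample(protocol$test_snrs_db),
                                 numeric(n_cycle)))
  for (b in seq_len(protocol$n_blocks)) {
    snrs <- c(rep(protocol$refresher_snr_db, protocol$n_refresher),
              rep(block_snrs[b], protocol$n_test))
    roles <- c(rep("refresher", protocol$n_refresher),
               rep("test", protocol$n_test))
    for (tr in seq_along(snrs))
      rows[[length(rows) + 1]] <- data.frame(
        stage = "test", block = b, trial = tr, snr_db = snrs[tr],
        role = roles[tr], correct = rbinom(1, 1, p_correct(snrs[tr])) == 1)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("speech_trials", class(out))
  out
}

#' Speech reception threshold from a trial ledger
#'
#' Fits a logistic response curve between chance and an upper asymptote by
#' maximum likelihood over the Bernoulli trial outcomes (test-role trials
#' only, unless `include_refreshers`), then solves for the SNR at which the
#' fitted curve crosses the criterion (70.71%, the 2-down-1-up convergence
#' point, for comparability with the adaptive tasks). Thresholds better than
#' 0 dB SNR are clamped to 0; if the fitted curve never reaches criterion
#' within `snr_range` the subject is flagged as above range (`srt_db = NA`,
#' `above_range = TRUE`) rather than given a number.
#'
#' @param trials a `speech_trials` ledger from [run_speech_session()].
#' @param criterion target proportion correct (default `sqrt(0.5)`).
#' @param guess_rate chance level; default [digits_guess_rate()].
#' @param include_refreshers include 20 dB refresher trials in the fit.
#' @param snr_range interval (dB) within which the crossing must occur.
#' @return a list of class `speech_result`: `srt_db`, `above_range`,
#'   `percent_correct` (by SNR), `fit` (slope, midpoint, lapse), `n_trials`.
#' @export
speech_threshold <- function(trials, criterion = sqrt(0.5),
                             guess_rate = digits_guess_rate(),
                             include_refreshers = FALSE,
                             snr_range = c(0, 20)) {
  keep <- trials$role == "test"
  if (include_refreshers) keep <- keep | trials$role == "refresher"
  d <- trials[keep & is.finite(trials$snr_db), ]
  tab <- aggregate(correct ~ snr_db, d, mean)
  if (nrow(tab) < 2) stop("need >= 2 SNR levels with scored trials")
  # MLE of logistic between guess and (1 - lapse); lapse bounded at 0.1
  nll <- function(par) {
    mid <- par[1]; slope <- exp(par[2]); lapse <- plogis(par[3]) * 0.1
    p <- guess_rate + (1 - guess_rate - lapse) *
      plogis(slope * (d$snr_db - mid))
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(ifelse(d$correct, log(p), log(1 - p)))
  }
  fit <- optim(c(mid = median(d$snr_db), logslope = log(0.5), lq = -2), nll,
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  mid <- fit$par[1]; slope <- exp(fit$par[2]); lapse <- plogis(fit$par[3]) * 0.1
  # SNR where the fitted curve crosses the criterion
  q <- (criterion - guess_rate) / (1 - guess_rate - lapse)
  above <- FALSE; srt <- NA_real_
  if (q >= 1) {                        # lapse keeps the curve below criterion
    above <- TRUE
  } else {
    x <- mid + qlogis(q) / slope
    if (x > snr_range[2]) above <- TRUE
    else srt <- max(x, 0)              # better-than-0-dB thresholds marked 0
  }
  structure(list(srt_db = srt, above_range = above,
                 percent_correct = setNames(100 * tab$correct,
                                            paste0(tab$snr_db, " dB")),
                 fit = list(midpoint_db = mid, slope = slope, lapse = lapse,
                            guess = guess_rate, criterion = criterion),
                 n_trials = nrow(d)),
            class = "speech_result")
}
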