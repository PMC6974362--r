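#' Transformed up-down staircase configuration
#'
#' The 2-down-1-up rule with geometric steps: after two consecutive correct
#' responses the level is divided by the current factor, after any incorrect
#' response it is multiplied by it. A direction change marks a reversal. The
#' step factor is coarse (1.5) until `coarse_reversals` reversals have been
#' logged, then fine (1.2) for the remaining `fine_reversals`. The run value is
#' the geometric mean of the last `threshold_reversals` reversal levels.
#' Defaults for the two tasks: FM starts at 75 Hz with 5 coarse + 7 fine
#' reversals; IPD starts at 81 degrees with 4 coarse + 6 fine.
#'
#' @param task `"fm"` or `"ipd"`, which fills the task defaults; individual
#'   fields may be overridden.
#' @param initial_level starting stimulus magnitude.
#' @param coarse_factor,fine_factor multiplicative step sizes (> 1).
#' @param coarse_reversals,fine_reversals reversal counts in each regime.
#' @param threshold_reversals how many final reversals enter the run value.
#' @param level_floor hard lower bound on the level (> 0).
#' @param level_ceiling hard upper bound (e.g. 180 degrees for IPD).
#' @param max_trials non-convergence cap.
#' @return an object of class `staircase_config`.
#' @export
staircase_config <- function(task = c("fm", "ipd"), initial_level = NULL,
                             coarse_factor = 1.5, fine_factor = 1.2,
                             coarse_reversals = NULL, fine_reversals = NULL,
                             threshold_reversals = 6, level_floor = 1e-3,
                             level_ceiling = Inf, max_trials = 500) {
  task <- match.arg(task)
  if (is.null(initial_level)) initial_level <- c(fm = 75, ipd = 81)[[task]]
  if (is.null(coarse_reversals)) coarse_reversals <- c(fm = 5, ipd = 4)[[task]]
  if (is.null(fine_reversals)) fine_reversals <- c(fm = 7, ipd = 6)[[task]]
  stopifnot(coarse_factor > 1, fine_factor > 1, level_floor > 0,
            fine_reversals >= threshold_reversals, initial_level > 0)
  structure(list(task = task, initial_level = initial_level,
                 coarse_factor = coarse_factor, fine_factor = fine_factor,
                 coarse_reversals = coarse_reversals,
                 fine_reversals = fine_reversals,
                 threshold_reversals = threshold_reversals,
                 level_floor = level_floor, level_ceiling = level_ceiling,
                 max_trials = max_trials),
            class = "staircase_config")
}

#' Initialize staircase state
#' @param cfg a [staircase_config()].
#' @return a list of class `staircase_state` holding the current level,
#'   consecutive-correct counter, movement direction, reversal log, and trial
#'   ledger.
#' @export
staircase_init <- function(cfg) {
  structure(list(cfg = cfg, level = cfg$initial_level, n_correct = 0,
                 direction = 0, reversals = numeric(0),
                 trials = data.frame(level = numeric(0), correct = logical(0),
                                     reversal = logical(0)),
                 done = FALSE),
            class = "staircase_state")
}

#' Advance the staircase by one trial
#'
#' Applies the 2-down-1-up rule: the consecutive-correct counter resets after
#' every level change (the standard transformed up-down convention). A move
#' opposite to the previous move logs a reversal at the pre-move level; the
#' step factor used for a move is coarse until the coarse reversal quota was
#' already full *before* this trial.
#'
#' @param state a `staircase_state`.
#' @param correct logical, the observer's response at `state$level`.
#' @return the updated `staircase_state`; `$done` becomes TRUE once
#'   `coarse_reversals + fine_reversals` reversals have accrued.
#' @export
staircase_step <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), !state$done)
  cfg <- state$cfg
  move <- 0
  if (correct) {
    state$n_correct <- state$n_correct + 1
    if (state$n_correct >= 2) move <- -1            # two down
  } else move <- 1                                  # one up
  is_rev <- move != 0 && state$direction != 0 && move != state$direction
  if (is_rev) state$reversals <- c(state$reversals, state$level)
  state$trials <- rbind(state$trials,
                        data.frame(level = state$level, correct = correct,
                                   reversal = is_rev))
  if (move != 0) {
    n_before <- length(state$reversals) - is_rev
    factor <- if (n_before < cfg$coarse_reversals) cfg$coarse_factor else
      cfg$fine_factor
    state$level <- if (move < 0) state$level / factor else
      state$level * factor
    state$level <- min(max(state$level, cfg$level_floor), cfg$level_ceiling)
    state$direction <- move
    state$n_correct <- 0
  }
  if (length(state$reversals) >= cfg$coarse_reversals + cfg$fine_reversals)
    state$done <- TRUE
  state
}

#' Run one adaptive staircase against a simulated observer
#'
#' @param cfg a [staircase_config()].
#' @param observer an [observer_spec()] (log-scale for these tasks).
#' @param seed integer seed for the observer's responses.
#' @return a list of class `staircase_trace`: `trials` (level, correct,
#'   reversal), `reversals` (levels), `run_value` (geometric mean of the last
#'   `threshold_reversals` reversal levels).
#' @export
run_staircase <- function(cfg, observer, seed = 1L) {
  stopifnot(inherits(cfg, "staircase_config"),
            inherits(observer, "observer_spec"))
  set.seed(as.integer(seed))
  state <- staircase_init(cfg)
  n <- 0
  while (!state$done) {
    n <- n + 1
    if (n > cfg$max_trials)
      stop(sprintf("staircase did not converge within %d trials",
                   cfg$max_trials))
    state <- staircase_step(state,
                            simulate_observer_response(observer, state$level))
  }
  last <- tail(state$reversals, cfg$threshold_reversals)
  structure(list(trials = state$trials, reversals = state$reversals,
                 run_value = exp(mean(log(last)))),
            class = "staircase_trace")
}

#' Collect staircase runs under the coefficient-of-variation stopping rule
#'
#' Runs at least `min_runs` staircases; if the coefficient of variation
#' (sd/mean) of the run values exceeds `cv_criterion`, more runs are added
#' until the criterion is met or `max_runs` have been collected, whichever
#' comes first. The threshold is the median of the run values.
#'
#' @param cfg a [staircase_config()].
#' @param observer an [observer_spec()].
#' @param seed integer seed; run `i` uses `seed + i - 1`.
#' @param min_runs,max_runs run-count bounds (3 and 6).
#' @param cv_criterion stopping CV (0.2).
#' @return a list of class `run_set_result`: `run_values`, `n_runs`, `cv`,
#'   `threshold`.
#' @export
collect_runs <- function(cfg, observer, seed = 1L, min_runs = 3,
                         max_runs = 6, cv_criterion = 0.2) {
  run_values <- numeric(0)
  for (i in seq_len(max_runs)) {
    tr <- run_staircase(cfg, observer, seed = as.integer(seed) + i - 1L)
    run_values <- c(run_values, tr$run_value)
    cv <- sd(run_values) / mean(run_values)
    if (i >= min_runs && cv <= cv_criterion) break
  }
  structure(list(run_values = run_values, n_runs = length(run_values),
                 cv = cv, threshold = median(run_values)),
            class = "run_set_result")
}
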