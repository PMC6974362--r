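#' Growth curve container
#'
#' A normalized response amplitude sampled at increasing stimulus magnitudes:
#' FM depth (Hz) for the FMFR, total interaural difference (degrees) for the
#' IPDFR, or task difficulty (dB) for pupil-indexed effort.
#'
#' @param x strictly increasing stimulus-magnitude axis (length >= 3).
#' @param y normalized amplitudes, finite, same length.
#' @param x_label,y_label axis annotations carried into output tables.
#' @return an object of class `growth_curve`.
#' @export
growth_curve <- function(x, y, x_label = "x", y_label = "y") {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (is.unsorted(x, strictly = TRUE)) stop("x must be strictly increasing")
  if (!all(is.finite(y))) stop("y must be finite")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 x_label = x_label, y_label = y_label),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve: %s vs %s>\n", x$y_label, x$x_label))
  print(data.frame(x = x$x, y = x$y))
  invisible(x)
}

#' Fit a four-parameter logistic to a growth curve
#'
#' Least-squares fit of `y = y_min + (y_max - y_min) / (1 + exp(-k (x -
#' x_half)))` with `y_min >= 0`, `k >= 0`, and `x_half` constrained to
#' `[min(x), 2 max(x)]`. Initialization is deterministic: starts are built
#' from data quantiles and a small fixed grid of midpoints/steepnesses, the
#' best converged fit wins, and a flat fit (`k = 0`, `y` at its mean) is the
#' fallback for degenerate data -- the returned residual norm therefore never
#' exceeds the flat fit's.
#'
#' @param curve a [growth_curve()].
#' @return a list of class `sigmoid_fit`: `y_min`, `y_max`, `x_half`, `k`,
#'   `min_max`, `flat` (fallback flag), `rss`, and the input `curve`.
#' @export
fit_sigmoid <- function(curve) {
  stopifnot(inherits(curve, "growth_curve"))
  x <- curve$x; y <- curve$y
  flat_rss <- sum((y - mean(y))^2)
  best <- list(y_min = mean(y), y_max = mean(y), x_half = NA_real_, k = 0,
               rss = flat_rss, flat = TRUE)
  span <- diff(range(x))
  lower <- c(y_min = 0, dy = 0, x_half = min(x), k = 1e-6)
  upper <- c(y_min = max(max(y), 1e-12), dy = Inf, x_half = 2 * max(x),
             k = 1e3 / span)
  starts <- expand.grid(x_half = unname(quantile(x, c(0.25, 0.5, 0.75))),
                        k = c(1, 4, 16) / span)
  d <- data.frame(x = x, y = y)
  for (i in seq_len(nrow(starts))) {
    st <- list(y_min = max(min(y), 0), dy = max(diff(range(y)), 1e-6),
               x_half = starts$x_half[i], k = starts$k[i])
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ y_min + dy / (1 + exp(-k * (x - x_half))),
                        data = d, start = st, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (rss < best$rss - 1e-15 || (best$flat && rss <= best$rss)) {
      p <- coef(fit)
      best <- list(y_min = unname(p["y_min"]),
                   y_max = unname(p["y_min"] + p["dy"]),
                   x_half = unname(p["x_half"]), k = unname(p["k"]),
                   rss = rss, flat = FALSE)
    }
  }
  structure(c(best, list(min_max = best$y_max - best$y_min, curve = curve)),
            class = "sigmoid_fit")
}

#' Min-max / half-max growth slope metric
#'
#' The fitted dynamic range (`y_max - y_min`) divided by the stimulus
#' magnitude at the fit's halfway point (`x_half`), in units of 1/x. Large
#' values mean a wide response range reached early -- a steep, saturating
#' growth function. Flat fits have zero range and return 0.
#'
#' @param fit a [sigmoid_fit()].
#' @return the ratio `min_max / x_half`.
#' @export
slope_metric <- function(fit) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (fit$flat || fit$min_max == 0) return(0)
  if (!is.finite(fit$x_half) || fit$x_half <= 0)
    stop("x_half must be positive for the slope metric")
  fit$min_max / fit$x_half
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_fit: y_min %.4g, y_max %.4g, x_half %.4g, k %.4g%s>\n",
    x$y_min, x$y_max, x$x_half, x$k, if (x$flat) " [flat fallback]" else ""))
  invisible(x)
}

#' Flatten a sigmoid fit to a one-row table
#' @param fit a `sigmoid_fit`.
#' @return one-row data frame with the fit parameters and the slope metric.
#' @export
sigmoid_fit_row <- function(fit) {
  data.frame(y_min = fit$y_min, y_max = fit$y_max, x_half = fit$x_half,
             k = fit$k, min_max = fit$min_max,
             slope_metric = if (fit$flat) 0 else fit$min_max / fit$x_half)
}
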