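#' Pairwise Pearson correlation matrix with p-values
#'
#' Pairwise-complete Pearson correlations among the given columns, with
#' two-sided p-values from the t distribution on `n - 2` degrees of freedom
#' (no multiple-testing correction, so treat the p-values as descriptive).
#'
#' @param table data frame of subject metrics.
#' @param vars columns to correlate; default all numeric columns.
#' @return a list of class `pearson_matrix`: `r`, `p`, `n` (pairwise complete
#'   counts), each a symmetric matrix with unit/NA diagonal conventions.
#' @export
pearson_matrix <- function(table, vars = NULL) {
  if (is.null(vars))
    vars <- names(table)[vapply(table, is.numeric, logical(1))]
  x <- as.matrix(table[vars])
  k <- length(vars)
  r <- diag(1, k); p <- matrix(NA_real_, k, k); n <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- dimnames(n) <- list(vars, vars)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    ok <- complete.cases(x[, c(i, j)])
    if (sum(ok) < 3) stop(sprintf("fewer than 3 complete pairs for %s vs %s",
                                  vars[i], vars[j]))
    if (sd(x[ok, i]) == 0 || sd(x[ok, j]) == 0) {
      r[i, j] <- r[j, i] <- NA_real_   # undefined-r flag
      next
    }
    ct <- cor.test(x[ok, i], x[ok, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
    n[i, j] <- n[j, i] <- sum(ok)
  }
  structure(list(r = r, p = p, n = n), class = "pearson_matrix")
}

#' Adjusted R-squared
#'
#' `1 - (1 - R2) * (N - 1) / (N - p - 1)`: the coefficient of determination
#' penalized for the number of predictors.
#'
#' @param r2 sample R-squared, in \[0, 1\].
#' @param n total sample size (must exceed `p + 1`).
#' @param p number of predictors.
#' @return the adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, p) {
  stopifnot(r2 >= 0, r2 <= 1, p >= 0)
  if (n <= p + 1) stop("n must exceed p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

# complete-case table restricted to outcome + predictors, with rank check
model_frame <- function(table, outcome, predictors) {
  cols <- c(outcome, predictors)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols) > 0)
    stop("columns not in table: ", paste(missing_cols, collapse = ", "))
  d <- table[complete.cases(table[cols]), cols]
  if (nrow(d) < 4) stop("need >= 4 complete rows")
  X <- cbind(1, as.matrix(d[predictors]))
  if (qr(X)$rank < ncol(X)) {
    # name the offending columns: those whose removal restores full rank
    bad <- predictors[vapply(seq_along(predictors), function(i) {
      Xi <- cbind(1, as.matrix(d[predictors[-i]]))
      qr(Xi)$rank == ncol(Xi)
    }, logical(1))]
    stop("singular design; collinear columns: ",
         paste(if (length(bad)) bad else predictors, collapse = ", "))
  }
  d
}

#' Forward multivariable regression ranked by univariate R-squared
#'
#' Ranks candidate predictors by their univariate R-squared against the
#' outcome, then adds them to an ordinary least-squares model one at a time in
#' decreasing order, reporting R-squared and adjusted R-squared at each step.
#' Complete-case rows only (the subjects with every marker measured). Ties in
#' the univariate ranking are broken by the order of `predictors`.
#'
#' @param table data frame of subject metrics.
#' @param outcome outcome column name (speech reception threshold).
#' @param predictors candidate predictor column names.
#' @param max_steps stop after this many predictors (default: all).
#' @return a data frame of class `forward_model`: one row per step with
#'   `step`, `predictor`, `univariate_r2`, `r2`, `adj_r2`, `n`, `p`.
#' @export
forward_model <- function(table, outcome, predictors,
                          max_steps = length(predictors)) {
  d <- model_frame(table, outcome, predictors)
  n <- nrow(d)
  uni <- vapply(predictors, function(v)
    summary(lm(as.formula(paste(outcome, "~", v)), data = d))$r.squared,
    numeric(1))
  ord <- predictors[order(-uni)]          # stable: ties keep input order
  steps <- min(max_steps, length(ord))
  out <- data.frame(step = seq_len(steps), predictor = ord[seq_len(steps)],
                    univariate_r2 = uni[ord[seq_len(steps)]],
                    r2 = NA_real_, adj_r2 = NA_real_, n = n,
                    p = seq_len(steps))
  for (k in seq_len(steps)) {
    f <- as.formula(paste(outcome, "~", paste(ord[seq_len(k)], collapse = "+")))
    r2 <- summary(lm(f, data = d))$r.squared
    out$r2[k] <- r2
    out$adj_r2[k] <- adjusted_r2(r2, n, k)
  }
  class(out) <- c("forward_model", class(out))
  out
}

#' Adjusted R-squared of every two-predictor model
#'
#' Fits the outcome on each unordered pair of candidate predictors and reports
#' the pair's adjusted R-squared, to expose order effects in forward selection.
#'
#' @inheritParams forward_model
#' @return data frame with `var1`, `var2`, `r2`, `adj_r2`, `n`, sorted by
#'   decreasing adjusted R-squared.
#' @export
pairwise_models <- function(table, outcome, predictors) {
  d <- model_frame(table, outcome, predictors)
  n <- nrow(d)
  pairs <- utils::combn(predictors, 2)
  out <- data.frame(var1 = pairs[1, ], var2 = pairs[2, ],
                    r2 = NA_real_, adj_r2 = NA_real_, n = n)
  for (i in seq_len(ncol(pairs))) {
    model_frame(d, outcome, pairs[, i])   # collinearity check per pair
    f <- as.formula(paste(outcome, "~", paste(pairs[, i], collapse = "+")))
    r2 <- summary(lm(f, data = d))$r.squared
    out$r2[i] <- r2
    out$adj_r2[i] <- adjusted_r2(r2, n, 2)
  }
  out[order(-out$adj_r2), ]
}
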