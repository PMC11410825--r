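# Evaluation metrics and run-level statistics.

#' Regression-style error metrics of predicted scores
#'
#' Computes, for error `e = y - yhat` and floor `eps = 1e-8`:
#' MAE `mean(|e|)`, MSE `mean(e^2)`, RMSE `sqrt(MSE)`,
#' MARE `mean(|e| / max(|y|, eps))`, MSRE `mean(e^2 / max(y^2, eps))`,
#' RAE `sum(|e|) / sum(|y - mean(y)|)`, and MASE `MAE / mean(|y_i - y_{i-1}|)`
#' (naive one-step scale). A zero RAE or MASE denominator reports `NaN` with
#' a warning.
#'
#' @param actual Actual values.
#' @param predicted Predicted values.
#' @return Named list with elements `mae`, `mse`, `rmse`, `mare`, `msre`,
#'   `rae`, `mase`.
#' @examples
#' regression_metrics(c(0, 1), c(0.5, 0.5))  # MAE 0.5, MSE 0.25, RMSE 0.5
#' @export
regression_metrics <- function(actual, predicted) {
  n <- length(actual)
  if (n == 0L) stop2("empty input")
  if (n != length(predicted)) stop2("actual/predicted length mismatch")
  eps <- 1e-8
  e <- actual - predicted
  mae <- mean(abs(e))
  mse <- mean(e^2)
  rae_den <- sum(abs(actual - mean(actual)))
  if (rae_den == 0) {
    warning("RAE denominator is zero; reporting NaN", call. = FALSE)
    rae <- NaN
  } else {
    rae <- sum(abs(e)) / rae_den
  }
  if (n < 2L || mean(abs(diff(actual))) == 0) {
    warning("MASE denominator is zero; reporting NaN", call. = FALSE)
    mase <- NaN
  } else {
    mase <- mae / mean(abs(diff(actual)))
  }
  list(mae = mae,
       mse = mse,
       rmse = sqrt(mse),
       mare = mean(abs(e) / pmax(abs(actual), eps)),
       msre = mean(e^2 / pmax(actual^2, eps)),
       rae = rae,
       mase = mase)
}

#' Classification accuracy of thresholded scores
#'
#' Fraction of pairs whose thresholded score (`score >= threshold` counts
#' positive, so ties are positive) matches the label.
#'
#' @param labels 0/1 labels.
#' @param scores Predicted scores.
#' @param threshold Decision threshold (default 0.5).
#' @return Fraction in \[0, 1\].
#' @export
classification_accuracy <- function(labels, scores, threshold = 0.5) {
  if (length(labels) == 0L) stop2("empty input")
  if (length(labels) != length(scores)) stop2("labels/scores length mismatch")
  if (!all(labels %in% c(0, 1))) stop2("labels must be 0/1")
  mean((scores >= threshold) == (labels == 1))
}

#' Run-level statistics of repeated objective values
#'
#' Minimization convention: best is the minimum, worst the maximum. The
#' standard deviation uses the sample (n-1) denominator and is 0 for a
#' single run.
#'
#' @param values Numeric vector of final objective values over runs.
#' @return Named list `best`, `worst`, `mean`, `median`, `std`.
#' @examples
#' run_statistics(c(1, 2, 3))  # best 1, worst 3, mean 2, median 2, std 1
#' @export
run_statistics <- function(values) {
  if (length(values) == 0L) stop2("empty input")
  list(best = min(values),
       worst = max(values),
       mean = mean(values),
       median = stats::median(values),
       std = if (length(values) == 1L) 0 else stats::sd(values))
}
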