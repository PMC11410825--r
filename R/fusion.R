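# Modified score-level fusion: the two classifiers' scores are combined by a
# convex combination whose weights derive from each model's mean absolute
# percentage error on a validation split.

#' Mean absolute percentage error
#'
#' `100 * mean(|y - yhat| / max(|y|, eps))`. Zero actual values are floored
#' at `eps` with a warning so the result stays finite.
#'
#' @param actual Actual values.
#' @param predicted Predicted values.
#' @param eps Denominator floor (default 1e-8).
#' @return Percentage scalar (>= 0).
#' @examples
#' mape(c(1, 2), c(0.5, 1))  # 50
#' @export
mape <- function(actual, predicted, eps = 1e-8) {
  if (length(actual) == 0L) stop2("empty input")
  if (length(actual) != length(predicted)) stop2("actual/predicted length mismatch")
  check_numeric_vector(predicted, "predicted")
  if (any(abs(actual) < eps)) {
    warning("actual values below eps floored in MAPE denominator", call. = FALSE)
  }
  100 * mean(abs(actual - predicted) / pmax(abs(actual), eps))
}

#' Fusion weights from the two models' MAPEs
#'
#' Literal mode (default): `w1 = mape_mrnn / (mape_dbn + mape_mrnn)` and
#' `w2 = mape_dbn / (mape_dbn + mape_mrnn)`, which hands the larger weight to
#' the model with the larger error. `invert_weights = TRUE` swaps the
#' numerators so the lower-MAPE model receives the larger weight. Two zero
#' MAPEs give (0.5, 0.5).
#'
#' @param mape_mrnn,mape_dbn Non-negative MAPE values of the recurrent and
#'   belief-network models.
#' @param invert_weights Give the smaller-error model the larger weight.
#' @return Numeric vector `c(w1, w2)` summing to 1.
#' @examples
#' fusion_weights(10, 30)                         # c(0.25, 0.75)
#' fusion_weights(10, 30, invert_weights = TRUE)  # c(0.75, 0.25)
#' @export
fusion_weights <- function(mape_mrnn, mape_dbn, invert_weights = FALSE) {
  if (mape_mrnn < 0 || mape_dbn < 0) stop2("MAPE values must be non-negative")
  total <- mape_mrnn + mape_dbn
  if (total == 0) return(c(w1 = 0.5, w2 = 0.5))
  if (invert_weights) {
    c(w1 = mape_dbn / total, w2 = mape_mrnn / total)
  } else {
    c(w1 = mape_mrnn / total, w2 = mape_dbn / total)
  }
}

#' Fuse two score vectors
#'
#' Elementwise convex combination `w1 * s_mrnn + w2 * s_dbn`; the weights
#' must sum to 1. With `w1 = w2 = 0.5` this is the plain score average
#' (`average = TRUE` forces that baseline mode).
#'
#' @param s_mrnn,s_dbn Equal-length score vectors.
#' @param w1,w2 Fusion weights summing to 1.
#' @param average Ignore the weights and use the simple average.
#' @return Fused score vector.
#' @export
fuse_scores <- function(s_mrnn, s_dbn, w1 = 0.5, w2 = 0.5, average = FALSE) {
  if (length(s_mrnn) != length(s_dbn)) stop2("score length mismatch")
  if (average) { w1 <- 0.5; w2 <- 0.5 }
  if (abs(w1 + w2 - 1) > 1e-9) stop2("fusion weights must sum to 1")
  w1 * s_mrnn + w2 * s_dbn
}

#' Full fusion of two models' validation and target scores
#'
#' Computes both models' MAPEs against the validation labels, derives the
#' fusion weights, and fuses the target scores.
#'
#' @param val_labels 0/1 validation labels.
#' @param val_mrnn,val_dbn Validation scores of the two models.
#' @param s_mrnn,s_dbn Scores to fuse (defaults: the validation scores).
#' @param invert_weights Passed to [fusion_weights].
#' @return A `fusion_result`: list with per-model MAPEs, weights `w1`/`w2`
#'   and the `fused` score vector.
#' @export
fuse_models <- function(val_labels, val_mrnn, val_dbn,
                        s_mrnn = val_mrnn, s_dbn = val_dbn,
                        invert_weights = FALSE) {
  m1 <- suppressWarnings(mape(val_labels, val_mrnn))
  m2 <- suppressWarnings(mape(val_labels, val_dbn))
  w <- fusion_weights(m1, m2, invert_weights)
  structure(list(mape_mrnn = m1, mape_dbn = m2,
                 w1 = unname(w[1]), w2 = unname(w[2]),
                 fused = fuse_scores(s_mrnn, s_dbn, w[1], w[2])),
            class = "fusion_result")
}
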