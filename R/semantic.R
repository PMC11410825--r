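# Improved semantic similarity with chaotic cubic-map weights.

#' Deterministic weights from the cubic chaotic map
#'
#' Iterates the cubic map `E <- rho * E * (1 - E^2)` from seed `e0` and
#' returns the first `m` iterates as per-dimension weights. For
#' `rho` in (0, 3*sqrt(3)/2) the map sends (0,1) into (0,1), so every weight
#' lies in (0,1); the default `rho = 2.59` sits in the chaotic regime.
#'
#' @param rho Control parameter, in (0, 3*sqrt(3)/2).
#' @param e0 Seed value in (0, 1).
#' @param m Number of weights to generate.
#' @return Numeric vector of length `m`, all entries in (0, 1).
#' @examples
#' cubic_map_weights(2.59, 0.5, 1)  # 2.59 * 0.5 * 0.75 = 0.97125
#' @export
cubic_map_weights <- function(rho = 2.59, e0 = 0.7, m) {
  if (!is.numeric(rho) || rho <= 0 || rho >= 3 * sqrt(3) / 2) {
    stop2("rho must lie in (0, 3*sqrt(3)/2)")
  }
  if (!is.numeric(e0) || e0 <= 0 || e0 >= 1) stop2("e0 must lie in (0, 1)")
  m <- as.integer(m)
  if (m < 0L) stop2("m must be non-negative")
  w <- numeric(m)
  e <- e0
  for (a in seq_len(m)) {
    e <- rho * e * (1 - e^2)
    w[a] <- e
  }
  w
}

#' Improved semantic similarity of two annotation-weight vectors
#'
#' Computes `sum_a sqrt(Ra_a * Rb_a) * omega_a / (sqrt(sum(Ra)) * sqrt(sum(Ra)))`.
#' The denominator repeats the first vector's sum; setting
#' `symmetric_denominator = TRUE` substitutes `sum(Rb)` in the second factor,
#' which makes the score symmetric under swapping the two proteins. If either
#' vector is all zeros the similarity is defined as 0.
#'
#' @param Ra,Rb Equal-length non-negative numeric vectors (cluster-indexed
#'   annotation weights, see [term_vector]).
#' @param omega Weight vector of the same length, e.g. from
#'   [cubic_map_weights].
#' @param symmetric_denominator Use `sum(Rb)` in the second denominator
#'   factor (default `FALSE`).
#' @return Non-negative scalar.
#' @export
improved_semantic_similarity <- function(Ra, Rb, omega,
                                         symmetric_denominator = FALSE) {
  if (length(Ra) != length(Rb) || length(Ra) != length(omega)) {
    stop2("Ra, Rb and omega must have equal lengths")
  }
  check_numeric_vector(Ra, "Ra", non_negative = TRUE)
  check_numeric_vector(Rb, "Rb", non_negative = TRUE)
  sa <- sum(Ra)
  sb <- sum(Rb)
  if (sa == 0 || sb == 0) return(0)
  denom <- if (symmetric_denominator) sqrt(sa) * sqrt(sb) else sqrt(sa) * sqrt(sa)
  sum(sqrt(Ra * Rb) * omega) / denom
}

#' Relation-weighted cosine similarity
#'
#' Cosine similarity of two vectors after transformation by a square relation
#' matrix `SR`; with the identity default and unit-norm inputs this reduces
#' to the plain cosine. Provided as a reference baseline.
#'
#' @param Ra,Rb Equal-length numeric vectors.
#' @param SR Square relation matrix (default identity).
#' @return Scalar in \[-1, 1\]; 0 when either transformed vector has zero
#'   norm.
#' @export
ssd_cosine <- function(Ra, Rb, SR = NULL) {
  if (length(Ra) != length(Rb)) stop2("Ra and Rb must have equal lengths")
  if (is.null(SR)) SR <- diag(length(Ra))
  if (!is.matrix(SR) || nrow(SR) != ncol(SR) || nrow(SR) != length(Ra)) {
    stop2("SR must be a square matrix matching the vector length")
  }
  ta <- as.vector(SR %*% Ra)
  tb <- as.vector(SR %*% Rb)
  na <- sqrt(sum(ta^2))
  nb <- sqrt(sum(tb^2))
  if (na == 0 || nb == 0) return(0)
  sum(ta * tb) / (na * nb)
}
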