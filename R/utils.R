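# Internal helpers shared across modules.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Canonically order a protein pair
#'
#' Orders the two identifiers of an unordered pair lexicographically so that
#' pair-level features are independent of the order the pair was written in.
#'
#' @param id_u,id_v Character identifiers.
#' @return Character vector of length 2, smaller id first.
#' @keywords internal
canonical_pair <- function(id_u, id_v) {
  if (id_u <= id_v) c(id_u, id_v) else c(id_v, id_u)
}

# key for an unordered pair, used for duplicate detection
pair_key <- function(id_u, id_v) {
  ifelse(id_u <= id_v, paste(id_u, id_v, sep = "\r"), paste(id_v, id_u, sep = "\r"))
}

check_numeric_vector <- function(x, name, non_negative = FALSE) {
  if (!is.numeric(x)) stop2(name, " must be numeric")
  if (anyNA(x) || any(!is.finite(x))) stop2(name, " contains non-finite values")
  if (non_negative && any(x < 0)) stop2(name, " contains negative entries")
  invisible(x)
}
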