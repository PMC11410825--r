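# Auto-covariance compression of physicochemical scale signals.
#
# A protein of length L becomes an L x k matrix of per-residue scale values,
# then a k*G vector of lag-g auto-covariances: for scale l and gap g,
#   AC[l,g] = 1/(L-g) * sum_{m=1}^{L-g} (P[l,m] - mean_l) * (P[l,m+g] - mean_l)
# with mean_l the mean of scale l over the FULL sequence length. AC is
# translation-invariant in each scale column and scales quadratically with it.

#' Encode a protein sequence on physicochemical scales
#'
#' Converts each residue into its vector of scale values, giving an L x k
#' matrix (L = sequence length, k = number of scales).
#'
#' @param sequence Character scalar, canonical amino-acid letters.
#' @param scales Scale table matrix from [load_scale_table].
#' @return Numeric L x k matrix; row m holds the scale values of residue m.
#' @examples
#' residue_encode("ACD", load_scale_table())  # 3 x 14
#' @export
residue_encode <- function(sequence, scales) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  validate_scale_table(scales)
  res <- strsplit(toupper(sequence), "")[[1]]
  if (length(res) == 0) stop2("empty sequence")
  bad <- which(!res %in% rownames(scales))
  if (length(bad) > 0) {
    stop2("residue '", res[bad[1]], "' at position ", bad[1], " not in scale table")
  }
  m <- scales[res, , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Auto-covariance vector of an encoded protein
#'
#' Compresses an L x k per-residue encoding into a fixed-length vector of
#' k*G auto-covariances, one per (scale, gap) combination, ordered
#' scale-major: scale 1 gaps 1..G, then scale 2, and so on. The per-scale
#' mean is taken over the full length L.
#'
#' @param encoded L x k numeric matrix from [residue_encode].
#' @param G Maximum gap (positive integer); requires L > G.
#' @param protein_id Optional id used in error messages.
#' @return Numeric vector of length `k * G`, named `<scale>.g<g>`.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), ncol = 1)
#' auto_covariance(m, G = 1)  # 1.25 / 3
#' @export
auto_covariance <- function(encoded, G, protein_id = NULL) {
  stopifnot(is.matrix(encoded), is.numeric(encoded))
  G <- as.integer(G)
  if (G < 1L) stop2("G must be >= 1")
  L <- nrow(encoded)
  if (L <= G) {
    stop2("sequence too short for gap G = ", G,
          if (!is.null(protein_id)) paste0(" (protein '", protein_id, "', L = ", L, ")")
          else paste0(" (L = ", L, ")"))
  }
  k <- ncol(encoded)
  centered <- sweep(encoded, 2L, colMeans(encoded))
  out <- matrix(0, nrow = G, ncol = k)
  for (g in seq_len(G)) {
    n <- L - g
    out[g, ] <- colSums(centered[1:n, , drop = FALSE] *
                        centered[(1 + g):L, , drop = FALSE]) / n
  }
  v <- as.vector(out)  # gap fastest within scale-major layout: out is G x k
  scale_names <- colnames(encoded) %||% paste0("scale", seq_len(k))
  names(v) <- paste0(rep(scale_names, each = G), ".g", rep(seq_len(G), times = k))
  v
}

#' Auto-covariance features for a protein collection
#'
#' @param proteins data.frame with `id` and `sequence` columns.
#' @param scales Scale table matrix.
#' @param G Maximum gap (default 2, giving 14 x 2 = 28 values per protein
#'   with the bundled table).
#' @return Numeric matrix, one row per protein (rownames = ids), `k * G`
#'   columns.
#' @export
ac_features <- function(proteins, scales, G = 2L) {
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    auto_covariance(residue_encode(proteins$sequence[i], scales), G,
                    protein_id = proteins$id[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- proteins$id
  out
}

#' Fit the two-step feature scaler on training auto-covariances
#'
#' Standardizes each feature column to zero mean and unit standard deviation
#' (sample, n-1 denominator), then min-max rescales the standardized values
#' to \[0, 1\] using the training minimum and maximum. The fitted statistics
#' are reusable on held-out proteins, whose rescaled values are clipped to
#' \[0, 1\]. Columns with zero standard deviation map to constant 0 with a
#' warning.
#'
#' @param train_ac Numeric matrix of raw training AC values (rows = proteins).
#' @return An `ac_scaler` object with the fitted statistics.
#' @export
fit_ac_scaler <- function(train_ac) {
  stopifnot(is.matrix(train_ac))
  if (nrow(train_ac) < 2L) stop2("need at least 2 training proteins to fit the scaler")
  mu <- colMeans(train_ac)
  sd_ <- apply(train_ac, 2L, stats::sd)
  degenerate <- sd_ <= .Machine$double.eps
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance feature column(s) mapped to constant 0",
            call. = FALSE)
    sd_[degenerate] <- 1
  }
  z <- sweep(sweep(train_ac, 2L, mu), 2L, sd_, "/")
  zmin <- apply(z, 2L, min)
  zmax <- apply(z, 2L, max)
  span <- zmax - zmin
  span[span <= .Machine$double.eps] <- 1
  structure(list(mean = mu, sd = sd_, min = zmin, max = zmax, span = span,
                 degenerate = degenerate),
            class = "ac_scaler")
}

#' Apply a fitted scaler to auto-covariance values
#'
#' @param ac Numeric matrix (or vector) of raw AC values.
#' @param scaler An `ac_scaler` from [fit_ac_scaler].
#' @return Matrix of the same shape with all values in \[0, 1\].
#' @export
apply_ac_scaler <- function(ac, scaler) {
  stopifnot(inherits(scaler, "ac_scaler"))
  if (is.null(dim(ac))) ac <- matrix(ac, nrow = 1L)
  z <- sweep(sweep(ac, 2L, scaler$mean), 2L, scaler$sd, "/")
  scaled <- sweep(sweep(z, 2L, scaler$min), 2L, scaler$span, "/")
  scaled[, scaler$degenerate] <- 0
  clamp(scaled, 0, 1)
}

#' Concatenated pair feature from two per-protein AC vectors
#'
#' Concatenates the scaled AC vectors of the two proteins of a pair (first
#' protein of the canonical order first). With the defaults (k = 14, G = 2)
#' each protein contributes 28 values and the pair vector has length 56.
#'
#' @param ac_u,ac_v Equal-length numeric vectors scaled by the same fitted
#'   scaler.
#' @return Numeric vector of length `2 * length(ac_u)`.
#' @export
pair_feature <- function(ac_u, ac_v) {
  if (length(ac_u) != length(ac_v)) {
    stop2("AC vector length mismatch: ", length(ac_u), " vs ", length(ac_v))
  }
  out <- c(ac_u, ac_v)
  names(out) <- c(paste0("u.", names(ac_u) %||% seq_along(ac_u)),
                  paste0("v.", names(ac_v) %||% seq_along(ac_v)))
  out
}
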