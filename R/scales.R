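#' Load a physicochemical scale table
#'
#' Reads a 20-amino-acid by 14-scale table of physicochemical property values.
#' The bundled default covers the twelve properties commonly used for
#' sequence-based interaction prediction -- hydrophilicity, flexibility,
#' accessibility, turn propensity, exposed surface, polarizability, antigenic
#' propensity, hydrophobicity, net charge index of the side chain, polarity,
#' solvent-accessible surface area and side-chain volume -- with hydrophobicity
#' and polarity each measured on two distinct published scales, for a total of
#' fourteen columns. Values are assembled from standard published amino-acid
#' indices (Hopp-Woods, Bhaskaran-Ponnuswamy, Janin, Chou-Fasman,
#' Charton-Charton, Welling, Kyte-Doolittle, Eisenberg, Grantham, Zimmerman
#' and related compilations).
#'
#' @param path Path to a CSV whose first column (`aa`) holds the one-letter
#'   amino-acid code and whose remaining columns hold named scale values.
#'   `NULL` (default) loads the bundled table.
#' @param k Required number of scale columns (default 14). Set to `NULL` to
#'   accept tables with any number of scales.
#' @return Numeric matrix with 20 rows (amino acids) and one column per scale.
#' @examples
#' scales <- load_scale_table()
#' dim(scales)  # 20 x 14
#' @export
load_scale_table <- function(path = NULL, k = 14L) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_scales.csv", package = "ppifuse")
  }
  if (!file.exists(path)) stop2("scale table file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"aa" %in% names(df)) stop2("scale table must have an 'aa' column")
  aa <- toupper(df$aa)
  mat <- as.matrix(df[, setdiff(names(df), "aa"), drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- aa
  validate_scale_table(mat)
  if (!is.null(k) && ncol(mat) != k) {
    stop2("scale table has ", ncol(mat), " scale columns, expected ", k)
  }
  mat
}

#' Validate a scale table
#'
#' Checks the invariants a scale table must satisfy: exactly the 20 canonical
#' amino acids as rows, uniquely named columns, no missing values.
#'
#' @param scales Numeric matrix, rows named by one-letter amino-acid code.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_scale_table <- function(scales) {
  if (!is.matrix(scales) || !is.numeric(scales)) {
    stop2("scale table must be a numeric matrix")
  }
  if (nrow(scales) != 20L) stop2("scale table must have exactly 20 rows, got ", nrow(scales))
  if (!setequal(rownames(scales), AA_ALPHABET)) {
    stop2("scale table rows must be the 20 canonical amino acids")
  }
  if (is.null(colnames(scales)) || anyDuplicated(colnames(scales))) {
    stop2("scale table columns must be uniquely named")
  }
  if (anyNA(scales)) stop2("scale table contains missing values")
  invisible(scales)
}
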