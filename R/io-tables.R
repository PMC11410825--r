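#' Read protein-to-GO annotations from a TSV file
#'
#' Reads a two-column tab-separated file (`protein_id`, `go_id`) into an
#' annotation table: a map from protein id to its set of GO terms. Terms are
#' validated against the loaded ontology; duplicate rows deduplicate into
#' sets.
#'
#' @param path Path to the TSV file (no header).
#' @param dag A [go_dag] against which GO ids are validated.
#' @param on_unknown `"error"` (default) aborts on a GO id absent from the
#'   DAG; `"drop"` discards such rows with a warning reporting the count.
#' @return An `annotation_table`: list with element `sets`, a named list of
#'   sorted character vectors of term ids.
#' @export
read_annotations <- function(path, dag, on_unknown = c("error", "drop")) {
  on_unknown <- match.arg(on_unknown)
  if (!file.exists(path)) stop2("annotation file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("protein_id", "go_id"),
                          colClasses = "character", quote = "")
  annotation_table(df, dag, on_unknown)
}

#' Build an annotation table from a data.frame
#'
#' @param df data.frame with columns `protein_id` and `go_id`.
#' @inheritParams read_annotations
#' @return An `annotation_table`.
#' @export
annotation_table <- function(df, dag, on_unknown = c("error", "drop")) {
  on_unknown <- match.arg(on_unknown)
  stopifnot(all(c("protein_id", "go_id") %in% names(df)))
  unknown <- !(df$go_id %in% dag$nodes$id)
  if (any(unknown)) {
    if (on_unknown == "error") {
      stop2("annotation references unknown GO term: ", df$go_id[unknown][1])
    }
    warning("dropped ", sum(unknown), " annotation row(s) with unknown GO terms",
            call. = FALSE)
    df <- df[!unknown, , drop = FALSE]
  }
  sets <- lapply(split(df$go_id, df$protein_id), function(x) sort(unique(x)))
  sets <- sets[order(names(sets))]
  structure(list(sets = sets), class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("Annotation table:", length(x$sets), "proteins,",
      sum(lengths(x$sets)), "annotations\n")
  invisible(x)
}

#' Terms annotated to a protein
#'
#' @param ann An `annotation_table`.
#' @param protein_id Protein identifier.
#' @param dag Optional [go_dag]; when given, restricts to one namespace.
#' @param namespace Optional namespace name (requires `dag`).
#' @return Character vector of term ids (possibly empty).
#' @export
annotation_terms <- function(ann, protein_id, dag = NULL, namespace = NULL) {
  terms <- ann$sets[[protein_id]] %||% character(0)
  if (!is.null(namespace)) {
    stopifnot(!is.null(dag))
    terms <- terms[dag$namespace[terms] == namespace]
  }
  terms
}

#' Write an annotation table to TSV
#'
#' Deterministic inverse of [read_annotations]: proteins in id order, terms
#' sorted within each protein.
#'
#' @param ann An `annotation_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  ids <- rep(names(ann$sets), lengths(ann$sets))
  terms <- unlist(ann$sets, use.names = FALSE)
  utils::write.table(data.frame(ids, terms), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read annotations from a GAF-like file
#'
#' Convenience reader for the Gene Association File layout: comment lines
#' start with `!`, protein id in column 2, GO id in column 5. Only those two
#' columns are used.
#'
#' @inheritParams read_annotations
#' @return An `annotation_table`.
#' @export
read_gaf <- function(path, dag, on_unknown = c("error", "drop")) {
  if (!file.exists(path)) stop2("GAF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 0L) < 5L
  if (any(short)) stop2("GAF line with fewer than 5 columns: line ", which(short)[1])
  df <- data.frame(protein_id = vapply(fields, `[[`, "", 2L),
                   go_id = vapply(fields, `[[`, "", 5L),
                   stringsAsFactors = FALSE)
  annotation_table(df, dag, match.arg(on_unknown))
}

#' Read a labeled protein-pair list
#'
#' Reads a three-column tab-separated file (`id_u`, `id_v`, `label`) of
#' candidate interacting pairs. Both ids must resolve against the loaded
#' protein collection, labels must be 0/1, and each unordered pair may appear
#' at most once. Pairs are stored with the lexicographically smaller id first
#' so downstream features are deterministic.
#'
#' @param path Path to the TSV file (no header).
#' @param proteins data.frame of proteins as returned by [read_fasta].
#' @return data.frame with columns `id_u`, `id_v`, `label` (integer 0/1).
#' @export
read_pairs <- function(path, proteins) {
  if (!file.exists(path)) stop2("pair file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("id_u", "id_v", "label"),
                          colClasses = c("character", "character", "character"),
                          quote = "")
  pair_list(df, proteins)
}

#' Validate and canonicalize a pair list
#'
#' @param df data.frame with columns `id_u`, `id_v`, `label`.
#' @param proteins data.frame of proteins with an `id` column, or `NULL` to
#'   skip id resolution.
#' @return Canonicalized pair data.frame.
#' @export
pair_list <- function(df, proteins = NULL) {
  stopifnot(all(c("id_u", "id_v", "label") %in% names(df)))
  lab <- suppressWarnings(as.numeric(df$label))
  bad <- is.na(lab) | !(lab %in% c(0, 1))
  if (any(bad)) stop2("label outside {0,1} at row ", which(bad)[1])
  if (!is.null(proteins)) {
    unknown <- setdiff(c(df$id_u, df$id_v), proteins$id)
    if (length(unknown) > 0) stop2("pair references unknown protein: ", unknown[1])
  }
  swap <- df$id_u > df$id_v
  tmp <- df$id_u[swap]
  df$id_u[swap] <- df$id_v[swap]
  df$id_v[swap] <- tmp
  keys <- pair_key(df$id_u, df$id_v)
  if (anyDuplicated(keys)) {
    d <- which(duplicated(keys))[1]
    stop2("duplicate unordered pair: (", df$id_u[d], ", ", df$id_v[d], ")")
  }
  data.frame(id_u = df$id_u, id_v = df$id_v, label = as.integer(lab),
             stringsAsFactors = FALSE)
}

#' Write a pair list to TSV
#'
#' @param pairs data.frame with columns `id_u`, `id_v`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs[, c("id_u", "id_v", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a pair feature matrix to CSV
#'
#' One row per pair, a header row of feature names, and leading `id_u`/`id_v`
#' columns.
#'
#' @param features Numeric matrix, one row per pair, named columns.
#' @param pairs Matching pair data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, pairs, path) {
  stopifnot(nrow(features) == nrow(pairs))
  df <- cbind(pairs[, c("id_u", "id_v")], as.data.frame(features))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pair feature matrix written by [write_feature_matrix]
#'
#' @param path CSV path.
#' @return List with `pairs` (data.frame of `id_u`, `id_v`) and `features`
#'   (numeric matrix).
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  feats <- as.matrix(df[, setdiff(names(df), c("id_u", "id_v")), drop = FALSE])
  storage.mode(feats) <- "double"
  list(pairs = df[, c("id_u", "id_v")], features = feats)
}
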