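#' Read an ontology from an OBO 1.2 file
#'
#' Parses the OBO subset sufficient for GO feature extraction: `[Term]`
#' stanzas with `id`, `name`, `namespace`, `is_a`, `relationship: part_of`
#' and `is_obsolete` tags. Obsolete terms are dropped together with their
#' edges; all other relations are ignored. The result is a rooted DAG per
#' namespace with child-to-parent edges.
#'
#' @param path Path to an OBO file containing at least one `[Term]` stanza.
#' @return A [go_dag] object.
#' @export
read_go_obo <- function(path) {
  if (!file.exists(path)) stop2("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- grep("^\\[", lines)
  if (length(stanza_starts) == 0) stop2("no stanzas found in OBO file")
  term_starts <- stanza_starts[lines[stanza_starts] == "[Term]"]
  if (length(term_starts) == 0) stop2("no [Term] stanzas found in OBO file")

  bounds <- c(stanza_starts, length(lines) + 1L)
  terms <- list()
  for (s in term_starts) {
    e <- bounds[which(bounds == s) + 1L] - 1L
    body <- lines[(s + 1L):e]
    body <- body[nzchar(body)]
    tag_val <- function(tag) {
      v <- body[startsWith(body, paste0(tag, ":"))]
      sub("\\s*!.*$", "", trimws(substring(v, nchar(tag) + 2L)))
    }
    id <- tag_val("id")
    if (length(id) != 1L) stop2("[Term] stanza without exactly one id near line ", s)
    is_a <- tag_val("is_a")
    rel <- tag_val("relationship")
    part_of <- sub("^part_of\\s+", "", rel[grepl("^part_of\\s", rel)])
    obsolete <- any(tolower(tag_val("is_obsolete")) == "true")
    terms[[id]] <- list(
      id = id,
      name = if (length(tag_val("name"))) tag_val("name")[1] else id,
      namespace = if (length(tag_val("namespace"))) tag_val("namespace")[1] else "default",
      is_a = is_a, part_of = part_of, obsolete = obsolete)
  }

  keep <- Filter(function(t) !t$obsolete, terms)
  if (length(keep) == 0) stop2("all terms in OBO file are obsolete")
  nodes <- data.frame(
    id = vapply(keep, `[[`, "", "id"),
    name = vapply(keep, `[[`, "", "name"),
    namespace = vapply(keep, `[[`, "", "namespace"),
    stringsAsFactors = FALSE, row.names = NULL)
  edge_list <- lapply(keep, function(t) {
    par <- c(t$is_a, t$part_of)
    if (length(par) == 0) return(NULL)
    data.frame(child = t$id, parent = par,
               rel = c(rep("is_a", length(t$is_a)), rep("part_of", length(t$part_of))),
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, edge_list)
  if (is.null(edges)) {
    edges <- data.frame(child = character(0), parent = character(0),
                        rel = character(0), stringsAsFactors = FALSE)
  }
  # parents referencing obsolete/unknown terms: obsolete parents are an error
  # only if genuinely absent from the kept set
  missing_par <- setdiff(edges$parent, nodes$id)
  if (length(missing_par) > 0) {
    stop2("is_a/part_of references missing term: ", missing_par[1])
  }
  go_dag(nodes, edges)
}

#' Write an ontology to an OBO 1.2 file
#'
#' Serializes a [go_dag] back to the OBO subset read by [read_go_obo]. The
#' output is deterministic: terms are written in id order, parent references
#' in sorted order.
#'
#' @param dag A [go_dag].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_go_obo <- function(dag, path) {
  stopifnot(inherits(dag, "go_dag"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  nodes <- dag$nodes[order(dag$nodes$id), ]
  for (i in seq_len(nrow(nodes))) {
    id <- nodes$id[i]
    writeLines("[Term]", con)
    writeLines(paste0("id: ", id), con)
    writeLines(paste0("name: ", nodes$name[i]), con)
    writeLines(paste0("namespace: ", nodes$namespace[i]), con)
    e <- dag$edges[dag$edges$child == id, , drop = FALSE]
    e <- e[order(e$parent), , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      if (e$rel[j] == "part_of") {
        writeLines(paste0("relationship: part_of ", e$parent[j]), con)
      } else {
        writeLines(paste0("is_a: ", e$parent[j]), con)
      }
    }
    writeLines("", con)
  }
  invisible(path)
}
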