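# LCA-cluster features.
#
# For every training pair the lowest common ancestor (LCA) of the union of
# the two proteins' annotation sets is computed per namespace. The deduplicated
# anchors are sorted deepest-first and each claims its descendant subgraph
# minus terms already claimed, partitioning the covered portion of the DAG
# into mutually disjoint clusters. A pair's feature value for cluster j sums,
# over every occurrence of a term of either protein lying in cluster j, the
# node count of the shortest ascending path from the term to the cluster
# anchor (a term sitting at its own anchor contributes 1).

#' Build an LCA cluster index from training pairs
#'
#' Computes the per-pair LCA of the union of both proteins' term sets in each
#' namespace, deduplicates the anchors, sorts them deepest-first (ties broken
#' by id), and walks the sorted list claiming each anchor's descendant
#' subgraph minus previously claimed terms. Anchors already claimed by an
#' earlier (deeper) cluster are skipped. Clusters are therefore mutually
#' disjoint and every surviving anchor belongs to its own cluster. Clusters
#' are discovered on training pairs only; held-out terms outside every
#' cluster contribute nothing downstream.
#'
#' @param dag A [go_dag] (may contain several namespaces).
#' @param pairs data.frame of training pairs (`id_u`, `id_v`).
#' @param annotations An `annotation_table`.
#' @return An `lca_index`: list with `anchors` (ordered anchor ids),
#'   `term2cluster` (named integer vector mapping term id to cluster index),
#'   `anchor_ns` (namespace of each anchor) and `m` (cluster count).
#' @export
build_lca_index <- function(dag, pairs, annotations) {
  anchors <- character(0)
  for (i in seq_len(nrow(pairs))) {
    gu <- annotation_terms(annotations, pairs$id_u[i])
    gv <- annotation_terms(annotations, pairs$id_v[i])
    terms <- union(gu, gv)
    if (length(terms) == 0) {
      warning("pair (", pairs$id_u[i], ", ", pairs$id_v[i],
              ") has no annotations on either side; skipped", call. = FALSE)
      next
    }
    for (ns in unique(dag$namespace[terms])) {
      anchors <- c(anchors, lowest_common_ancestor(dag, terms[dag$namespace[terms] == ns]))
    }
  }
  anchors <- unique(anchors)
  if (length(anchors) == 0) stop2("no annotated training pairs; cannot build LCA index")
  # deepest first, ties by id, for deterministic and specific clusters
  anchors <- anchors[order(-dag$depth[anchors], anchors)]

  claimed <- character(0)
  kept <- character(0)
  term2cluster <- integer(0)
  for (a in anchors) {
    if (a %in% claimed) next
    members <- setdiff(go_descendants(dag, a), claimed)
    kept <- c(kept, a)
    term2cluster[members] <- length(kept)
    claimed <- c(claimed, members)
  }
  structure(list(anchors = kept,
                 term2cluster = term2cluster,
                 anchor_ns = unname(dag$namespace[kept]),
                 m = length(kept)),
            class = "lca_index")
}

#' @export
print.lca_index <- function(x, ...) {
  cat("LCA index:", x$m, "clusters covering", length(x$term2cluster), "terms\n")
  invisible(x)
}

#' GO cluster feature vector for a protein pair
#'
#' For each cluster, sums over every occurrence of a term in the multiset
#' union of the two proteins' term sets (a term annotated to both proteins
#' counts twice) lying in that cluster, the node count of the shortest
#' ascending path from the term to the cluster anchor, inclusive of both
#' endpoints. Terms outside every cluster contribute nothing; an unannotated
#' pair yields the zero vector.
#'
#' @param index An `lca_index` from [build_lca_index].
#' @param dag The [go_dag] the index was built on.
#' @param Gu,Gv Character vectors of term ids for the two proteins.
#' @return Non-negative numeric vector of length `index$m`, named by anchor.
#' @export
go_feature_vector <- function(index, dag, Gu, Gv) {
  v <- stats::setNames(numeric(index$m), index$anchors)
  for (t in c(Gu, Gv)) {
    j <- index$term2cluster[t]
    if (is.na(j)) next
    v[j] <- v[j] + path_node_count(dag, t, index$anchors[j])
  }
  v
}

#' Per-protein cluster term vector
#'
#' Same path-count accumulation as [go_feature_vector] but for a single
#' protein's term set; used as the annotation-weight vector of the semantic
#' similarity feature.
#'
#' @inheritParams go_feature_vector
#' @param terms Character vector of term ids of one protein.
#' @return Non-negative numeric vector of length `index$m`.
#' @export
term_vector <- function(index, dag, terms) {
  go_feature_vector(index, dag, terms, character(0))
}

#' Serialize an LCA index to JSON
#'
#' @param index An `lca_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lca_index <- function(index, path) {
  jsonlite::write_json(
    list(anchors = index$anchors,
         anchor_ns = index$anchor_ns,
         terms = names(index$term2cluster),
         cluster = unname(index$term2cluster)),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read an LCA index serialized by [write_lca_index]
#'
#' @param path JSON path.
#' @return An `lca_index`.
#' @export
read_lca_index <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(anchors = x$anchors,
                 term2cluster = stats::setNames(as.integer(x$cluster), x$terms),
                 anchor_ns = x$anchor_ns,
                 m = length(x$anchors)),
            class = "lca_index")
}
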