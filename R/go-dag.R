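#' Construct a GO DAG object
#'
#' Builds the rooted directed-acyclic-graph container used for ontology
#' queries. Edges are directed child-to-parent and restricted to `is_a` and
#' `part_of` relations. Each namespace must have exactly one root (a node with
#' no parents); node depth is the longest ascending path to the namespace
#' root, the standard GO level convention, with `depth(root) = 0`.
#'
#' @param nodes data.frame with columns `id`, `name`, `namespace`.
#' @param edges data.frame with columns `child`, `parent` and optionally
#'   `rel` (relation label, defaults to `"is_a"`).
#' @return An object of class `go_dag` with elements `nodes` (including the
#'   computed `depth` column), `edges`, `roots` (namespace -> root id) and
#'   internal parent/child adjacency lists.
#' @export
go_dag <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), all(c("id", "namespace") %in% names(nodes)))
  if (!"name" %in% names(nodes)) nodes$name <- nodes$id
  if (anyDuplicated(nodes$id)) {
    stop2("duplicate term id in DAG: ", nodes$id[duplicated(nodes$id)][1])
  }
  if (nrow(edges) > 0) {
    stopifnot(all(c("child", "parent") %in% names(edges)))
    if (!"rel" %in% names(edges)) edges$rel <- "is_a"
    missing_par <- setdiff(edges$parent, nodes$id)
    if (length(missing_par) > 0) {
      stop2("edge references unknown parent term: ", missing_par[1])
    }
    missing_ch <- setdiff(edges$child, nodes$id)
    if (length(missing_ch) > 0) {
      stop2("edge references unknown child term: ", missing_ch[1])
    }
  } else {
    edges <- data.frame(child = character(0), parent = character(0),
                        rel = character(0), stringsAsFactors = FALSE)
  }

  # acyclicity via igraph; report one cycle if present
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = nodes$id)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    bad <- which(comp$csize > 1)[1]
    cyc <- names(comp$membership)[comp$membership == bad]
    stop2("cycle detected in ontology involving: ", paste(cyc, collapse = " -> "))
  }

  parents <- split(edges$parent, factor(edges$child, levels = nodes$id))
  children <- split(edges$child, factor(edges$parent, levels = nodes$id))

  # roots: one parentless node per namespace
  has_parent <- lengths(parents) > 0
  roots <- character(0)
  for (ns in unique(nodes$namespace)) {
    cand <- nodes$id[nodes$namespace == ns & !has_parent[nodes$id]]
    if (length(cand) != 1L) {
      stop2("namespace '", ns, "' must have exactly one root, found ",
            length(cand), " (", paste(cand, collapse = ", "), ")")
    }
    roots[ns] <- cand
  }

  # namespace consistency along edges
  ns_of <- stats::setNames(nodes$namespace, nodes$id)
  if (nrow(edges) > 0 && any(ns_of[edges$child] != ns_of[edges$parent])) {
    i <- which(ns_of[edges$child] != ns_of[edges$parent])[1]
    stop2("edge crosses namespaces: ", edges$child[i], " -> ", edges$parent[i])
  }

  # depth = longest downward path from the root, by DP over topological order
  topo <- names(igraph::topo_sort(g, mode = "in"))  # parents before children
  depth <- stats::setNames(rep(0L, nrow(nodes)), nodes$id)
  for (id in topo) {
    p <- parents[[id]]
    if (length(p) > 0) depth[id] <- max(depth[p]) + 1L
  }
  nodes$depth <- as.integer(depth[nodes$id])

  structure(list(nodes = nodes, edges = edges, roots = roots,
                 parents = parents, children = children,
                 namespace = ns_of, depth = depth),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat("GO DAG:", nrow(x$nodes), "terms,", nrow(x$edges), "edges,",
      length(x$roots), "namespace(s):", paste(names(x$roots), collapse = ", "), "\n")
  invisible(x)
}

check_terms <- function(dag, terms) {
  unknown <- setdiff(terms, dag$nodes$id)
  if (length(unknown) > 0) stop2("unknown GO term: ", unknown[1])
  invisible(terms)
}

#' Ancestors of a GO term
#'
#' Upward closure of a term along child-to-parent edges.
#'
#' @param dag A `go_dag`.
#' @param term Term id.
#' @param include_self Include the term itself (default `TRUE`).
#' @return Character vector of ancestor ids.
#' @export
go_ancestors <- function(dag, term, include_self = TRUE) {
  check_terms(dag, term)
  seen <- character(0)
  frontier <- term
  while (length(frontier) > 0) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier], use.names = FALSE)), seen)
  }
  if (!include_self) seen <- setdiff(seen, term)
  seen
}

#' Descendants of a GO term
#'
#' Downward closure of a term along parent-to-child edges.
#'
#' @inheritParams go_ancestors
#' @return Character vector of descendant ids.
#' @export
go_descendants <- function(dag, term, include_self = TRUE) {
  check_terms(dag, term)
  seen <- character(0)
  frontier <- term
  while (length(frontier) > 0) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(dag$children[frontier], use.names = FALSE)), seen)
  }
  if (!include_self) seen <- setdiff(seen, term)
  seen
}

#' Lowest common ancestor of a set of GO terms
#'
#' Returns the deepest node that is an ancestor-or-self of every queried term,
#' where depth is the longest ascending distance to the namespace root. Ties
#' are broken by lexicographically smallest id. Terms that share no ancestor
#' other than the root resolve to the namespace root.
#'
#' @param dag A `go_dag`.
#' @param terms Non-empty character vector of term ids, all in one namespace.
#' @return A single term id.
#' @examples
#' dag <- go_dag(
#'   nodes = data.frame(id = c("R", "B", "C", "D"), namespace = "bp"),
#'   edges = data.frame(child = c("B", "C", "D", "D"),
#'                      parent = c("R", "R", "B", "C")))
#' lowest_common_ancestor(dag, c("B", "D"))  # "B"
#' @export
lowest_common_ancestor <- function(dag, terms) {
  terms <- unique(terms)
  if (length(terms) == 0) stop2("term set must be non-empty")
  check_terms(dag, terms)
  ns <- unique(dag$namespace[terms])
  if (length(ns) > 1) {
    stop2("terms span multiple namespaces: ", paste(ns, collapse = ", "))
  }
  common <- go_ancestors(dag, terms[1])
  for (t in terms[-1]) {
    common <- intersect(common, go_ancestors(dag, t))
    if (length(common) == 1) break
  }
  if (length(common) == 0) return(unname(dag$roots[ns]))  # defensive; root is always shared
  d <- dag$depth[common]
  deepest <- common[d == max(d)]
  sort(deepest)[1]
}

#' Node count of the shortest ascending path between a term and an ancestor
#'
#' Counts the nodes on the shortest child-to-parent path from `term` up to
#' `anchor`, inclusive of both endpoints; a term queried at itself counts 1.
#'
#' @param dag A `go_dag`.
#' @param term Start term id.
#' @param anchor Ancestor term id.
#' @return Integer node count, or `NA_integer_` if `anchor` is not an
#'   ancestor-or-self of `term`.
#' @export
path_node_count <- function(dag, term, anchor) {
  check_terms(dag, c(term, anchor))
  if (term == anchor) return(1L)
  # BFS upward
  dist <- 0L
  frontier <- term
  seen <- term
  while (length(frontier) > 0) {
    dist <- dist + 1L
    frontier <- setdiff(unique(unlist(dag$parents[frontier], use.names = FALSE)), seen)
    if (anchor %in% frontier) return(dist + 1L)
    seen <- c(seen, frontier)
  }
  NA_integer_
}
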