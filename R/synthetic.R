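# Synthetic benchmark generator.
#
# Emulates the statistical structure the predictor assumes: proteins with
# group-biased residue composition and group-biased GO annotations over
# random rooted DAGs (one per namespace), and pair labels drawn from a
# logistic model on a planted signal that combines shared annotation terms
# with the correlation of the two proteins' mean physicochemical profiles.
# The signal lives in BOTH feature families so each extractor is
# individually testable.

#' Synthetic data configuration
#'
#' Defaults describe a desk-scale study: 120 proteins of length 50-200, a
#' 40-term DAG per namespace, 5-8 annotation terms per protein and
#' namespace drawn with a 50-fold bias toward the protein's latent
#' functional group (2 groups, each a major branch of every namespace),
#' 400 labeled pairs at a 0.5 positive fraction, and planted signal
#' strength `beta_sig = 3`.
#'
#' @param ... Named overrides of any default.
#' @return A `synth_config` list.
#' @export
synth_config <- function(...) {
  cfg <- utils::modifyList(list(
    n_proteins = 120L, lmin = 50L, lmax = 200L,
    n_pairs = 400L, pos_frac = 0.5,
    dag_size = 40L, terms_min = 5L, terms_max = 8L,
    n_groups = 2L, group_bias = 50, comp_conc = 0.5,
    beta_sig = 3, seed = 1L), list(...))
  if (cfg$lmin <= 2L) stop2("lmin must exceed the default AC gap")
  if (cfg$pos_frac <= 0 || cfg$pos_frac >= 1) stop2("positive fraction must be in (0,1)")
  if (cfg$beta_sig < 0) stop2("beta_sig must be >= 0")
  structure(cfg, class = "synth_config")
}

# Random rooted DAG with the blocky shape of a real ontology namespace: a
# root, `n_branches` major branches beneath it, and every further term
# attached to 1-2 uniformly chosen existing parents within one branch.
# Construction guarantees acyclicity, a single root, and disjoint branch
# subgraphs.
random_rooted_dag <- function(n_nodes, block, namespace, n_branches = 2L) {
  if (n_nodes < n_branches + 1L) stop2("dag_size too small for the branch count")
  ids <- sprintf("GO:%d%06d", block, seq_len(n_nodes))
  branch_of <- c(NA_integer_, seq_len(n_branches),
                 sample.int(n_branches, n_nodes - n_branches - 1L, replace = TRUE))
  child <- character(0); parent <- character(0); rel <- character(0)
  for (i in seq(2L, n_nodes)) {
    cand <- if (i <= n_branches + 1L) 1L else which(branch_of[seq_len(i - 1L)] == branch_of[i])
    par <- if (length(cand) == 1L) cand else sample(cand, min(sample(1:2, 1L), length(cand)))
    child <- c(child, rep(ids[i], length(par)))
    parent <- c(parent, ids[par])
    rel <- c(rel, sample(c("is_a", "part_of"), length(par),
                         replace = TRUE, prob = c(0.8, 0.2)))
  }
  list(nodes = data.frame(id = ids, name = paste0("term ", ids),
                          namespace = namespace, stringsAsFactors = FALSE),
       edges = data.frame(child = child, parent = parent, rel = rel,
                          stringsAsFactors = FALSE),
       branch_roots = ids[1L + seq_len(n_branches)])
}

#' Generate a synthetic protein universe
#'
#' Produces proteins, a three-namespace GO DAG and group-biased annotations.
#' Sequences are drawn i.i.d. from each latent group's residue composition
#' (a Dirichlet draw per group), lengths uniform in `[lmin, lmax]`. Each
#' namespace DAG attaches every new term to 1-2 uniformly chosen existing
#' parents, guaranteeing acyclicity and a single root. Each protein draws
#' its per-namespace term set with weight `group_bias` on its group's term
#' subset. Fully deterministic given the config seed.
#'
#' @param config A [synth_config].
#' @return List with `proteins` (data.frame `id`, `sequence`, `group`),
#'   `dag` (a [go_dag] holding all three namespaces), `annotations`
#'   (an `annotation_table`), `group_terms` (per-namespace term subsets) and
#'   the `config`.
#' @export
generate_universe <- function(config = synth_config()) {
  set.seed(config$seed)
  C <- config$n_groups
  comp <- t(replicate(C, {
    g <- stats::rgamma(20L, shape = config$comp_conc)
    g / sum(g)
  }))
  colnames(comp) <- AA_ALPHABET
  groups <- sample.int(C, config$n_proteins, replace = TRUE)
  lens <- sample(config$lmin:config$lmax, config$n_proteins, replace = TRUE)
  sequences <- vapply(seq_len(config$n_proteins), function(i) {
    paste(sample(AA_ALPHABET, lens[i], replace = TRUE, prob = comp[groups[i], ]),
          collapse = "")
  }, "")
  proteins <- data.frame(id = sprintf("P%04d", seq_len(config$n_proteins)),
                         sequence = sequences, group = groups,
                         stringsAsFactors = FALSE)

  namespaces <- c(biological_process = 1L, molecular_function = 2L,
                  cellular_component = 3L)
  parts <- lapply(names(namespaces), function(ns) {
    random_rooted_dag(config$dag_size, namespaces[[ns]], ns, n_branches = C)
  })
  dag <- go_dag(do.call(rbind, lapply(parts, `[[`, "nodes")),
                do.call(rbind, lapply(parts, `[[`, "edges")))

  # each functional group is a coherent subgraph: one major branch per
  # namespace, mirroring how real annotation sets concentrate in related
  # ontology branches
  group_terms <- lapply(seq_along(namespaces), function(i) {
    lapply(parts[[i]]$branch_roots, function(a) sort(go_descendants(dag, a)))
  })
  names(group_terms) <- names(namespaces)

  rows_p <- character(0); rows_t <- character(0)
  for (i in seq_len(config$n_proteins)) {
    for (ns in names(namespaces)) {
      ids <- dag$nodes$id[dag$nodes$namespace == ns]
      w <- rep(1, length(ids))
      w[ids %in% group_terms[[ns]][[groups[i]]]] <- config$group_bias
      k <- sample(config$terms_min:config$terms_max, 1L)
      terms <- sample(ids, min(k, length(ids)), prob = w)
      rows_p <- c(rows_p, rep(proteins$id[i], length(terms)))
      rows_t <- c(rows_t, terms)
    }
  }
  annotations <- annotation_table(
    data.frame(protein_id = rows_p, go_id = rows_t, stringsAsFactors = FALSE), dag)

  list(proteins = proteins, dag = dag, annotations = annotations,
       group_terms = group_terms, config = config)
}

#' Generate labeled pairs with a planted interaction signal
#'
#' Samples `n_pairs` distinct unordered pairs uniformly, computes the planted
#' signal `z` = standardized shared-annotation count plus standardized
#' correlation of the two proteins' mean physicochemical profiles, sets the
#' logistic intercept by bisection so the expected positive fraction matches
#' the config, and draws labels Bernoulli from
#' `plogis(beta0 + beta_sig * z)`. With `beta_sig = 0` labels are
#' independent of the features.
#'
#' @param universe Output of [generate_universe].
#' @param config A [synth_config] (defaults to the universe's config).
#' @return A canonical pair data.frame (`id_u`, `id_v`, `label`) with the
#'   per-pair signal attached as attribute `"signal"`.
#' @export
generate_pairs <- function(universe, config = universe$config) {
  set.seed(config$seed + 500000L)
  n <- nrow(universe$proteins)
  n_avail <- n * (n - 1) / 2
  if (config$n_pairs > n_avail) {
    stop2("requested ", config$n_pairs, " pairs but only ", n_avail, " are available")
  }
  all_pairs <- utils::combn(n, 2L)
  pick <- sort(sample.int(ncol(all_pairs), config$n_pairs))
  iu <- all_pairs[1L, pick]
  iv <- all_pairs[2L, pick]

  sets <- universe$annotations$sets
  shared <- vapply(seq_along(iu), function(j) {
    length(intersect(sets[[universe$proteins$id[iu[j]]]] %||% character(0),
                     sets[[universe$proteins$id[iv[j]]]] %||% character(0)))
  }, 0L)

  scales <- load_scale_table()
  profiles <- t(vapply(universe$proteins$sequence, function(s) {
    colMeans(residue_encode(s, scales))
  }, numeric(ncol(scales))))
  prof_cor <- vapply(seq_along(iu), function(j) {
    stats::cor(profiles[iu[j], ], profiles[iv[j], ])
  }, 0)

  std <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  z <- std(shared) + std(prof_cor)

  target <- config$pos_frac
  f <- function(b0) mean(stats::plogis(b0 + config$beta_sig * z)) - target
  lo <- -50; hi <- 50
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  beta0 <- (lo + hi) / 2
  p <- stats::plogis(beta0 + config$beta_sig * z)
  labels <- stats::rbinom(length(p), 1L, p)

  pairs <- pair_list(data.frame(id_u = universe$proteins$id[iu],
                                id_v = universe$proteins$id[iv],
                                label = labels, stringsAsFactors = FALSE),
                     universe$proteins)
  attr(pairs, "signal") <- z
  pairs
}

#' Write a synthetic universe as standard files
#'
#' Writes FASTA sequences, the OBO ontology, the annotation TSV and the pair
#' TSV into a directory, in the exact formats the package readers accept.
#'
#' @param universe Output of [generate_universe].
#' @param pairs Output of [generate_pairs].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_universe <- function(universe, pairs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "proteins.fasta"),
             obo = file.path(dir, "ontology.obo"),
             annotations = file.path(dir, "annotations.tsv"),
             pairs = file.path(dir, "pairs.tsv"))
  write_fasta(universe$proteins, paths["fasta"])
  write_go_obo(universe$dag, paths["obo"])
  write_annotations(universe$annotations, paths["annotations"])
  write_pairs(pairs, paths["pairs"])
  invisible(paths)
}
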