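# LCA queries, cluster index construction, and pair feature vectors.

test_that("lowest common ancestor handles self, siblings and diamonds", {
  expect_equal(lowest_common_ancestor(star_dag(), "B"), "B")
  expect_equal(lowest_common_ancestor(star_dag(), c("B", "C")), "R")
  dag <- diamond_dag()
  # oracle: ancestor sets {B,R} and {D,B,C,R} intersect in {B,R}; B is deeper
  expect_equal(lowest_common_ancestor(dag, c("B", "D")), "B")
  expect_error(lowest_common_ancestor(dag, character(0)), "non-empty")
})

test_that("mixed-namespace LCA queries are rejected", {
  dag <- go_dag(data.frame(id = c("R1", "A", "R2", "B"),
                           namespace = c("bp", "bp", "mf", "mf")),
                data.frame(child = c("A", "B"), parent = c("R1", "R2")))
  expect_error(lowest_common_ancestor(dag, c("A", "B")), "namespaces")
})

test_that("LCA matches the brute-force oracle on random DAGs", {
  set.seed(202)
  for (i in 1:20) {
    dag <- random_test_dag(sample(5:30, 1))
    ids <- dag$nodes$id
    for (j in 1:5) {
      terms <- sample(ids, sample(1:3, 1))
      expect_equal(lowest_common_ancestor(dag, terms), brute_lca(dag, terms))
    }
  }
})

test_that("path node count is inclusive and uses the shortest ascent", {
  dag <- diamond_dag()
  expect_equal(path_node_count(dag, "B", "B"), 1L)
  expect_equal(path_node_count(dag, "D", "B"), 2L)
  expect_equal(path_node_count(dag, "D", "R"), 3L)  # shortest of the two routes
  expect_true(is.na(path_node_count(dag, "B", "C")))
})

test_that("cluster index partitions claimed terms disjointly", {
  # two nested anchors: deep anchor keeps its subtree, shallow one the rest
  dag <- go_dag(data.frame(id = c("R", "A", "B", "C", "D"), namespace = "bp"),
                data.frame(child = c("A", "B", "C", "D"),
                           parent = c("R", "A", "B", "A")))
  ann <- annotation_table(data.frame(
    protein_id = c("p1", "p2", "p3", "p4"),
    go_id = c("C", "B", "A", "D")), dag)
  pairs <- data.frame(id_u = c("p1", "p3"), id_v = c("p2", "p4"),
                      label = c(1L, 1L))
  idx <- build_lca_index(dag, pairs, ann)
  # pair1 LCA = B (depth 2), pair2 LCA = A (depth 1); B claims {B, C},
  # A claims {A, D} only
  expect_equal(idx$anchors, c("B", "A"))
  expect_equal(sort(names(idx$term2cluster)[idx$term2cluster == 1]), c("B", "C"))
  expect_equal(sort(names(idx$term2cluster)[idx$term2cluster == 2]), c("A", "D"))
  expect_false(anyDuplicated(names(idx$term2cluster)) > 0)
})

test_that("single root-anchored pair claims the whole namespace", {
  dag <- star_dag(3)
  ann <- annotation_table(data.frame(protein_id = c("p1", "p2"),
                                     go_id = c("B", "C")), dag)
  pairs <- data.frame(id_u = "p1", id_v = "p2", label = 1L)
  idx <- build_lca_index(dag, pairs, ann)
  expect_equal(idx$anchors, "R")
  expect_equal(idx$m, 1L)
  expect_length(idx$term2cluster, 4L)
})

test_that("index construction is order-independent and warns on bare pairs", {
  set.seed(33)
  dag <- random_test_dag(25)
  prot <- sprintf("p%02d", 1:10)
  ann <- annotation_table(data.frame(
    protein_id = rep(prot, each = 3),
    go_id = sample(dag$nodes$id, 30, replace = TRUE)), dag)
  pairs <- data.frame(id_u = prot[1:5], id_v = prot[6:10], label = 1L)
  idx1 <- build_lca_index(dag, pairs, ann)
  idx2 <- build_lca_index(dag, pairs[sample.int(5), ], ann)
  expect_identical(idx1, idx2)

  ann_sparse <- annotation_table(data.frame(protein_id = "p01", go_id = "T001"), dag)
  w <- capture_warnings(build_lca_index(dag, pairs, ann_sparse))
  expect_true(any(grepl("no annotations", w)))
})

test_that("clusters from random universes are always disjoint", {
  set.seed(44)
  for (i in 1:5) {
    dag <- random_test_dag(30)
    prot <- sprintf("p%02d", 1:12)
    ann <- annotation_table(data.frame(
      protein_id = rep(prot, each = 4),
      go_id = sample(dag$nodes$id, 48, replace = TRUE)), dag)
    pairs <- data.frame(id_u = prot[1:6], id_v = prot[7:12], label = 1L)
    idx <- build_lca_index(dag, pairs, ann)
    # disjointness: every term maps to exactly one cluster
    expect_false(anyDuplicated(names(idx$term2cluster)) > 0)
    # every anchor belongs to its own cluster
    expect_equal(unname(idx$term2cluster[idx$anchors]), seq_len(idx$m))
  }
})

test_that("pair feature vector counts inclusive ascending paths", {
  dag <- go_dag(data.frame(id = c("R", "A", "B"), namespace = "bp"),
                data.frame(child = c("A", "B"), parent = c("R", "A")))
  ann <- annotation_table(data.frame(protein_id = c("p1", "p2"),
                                     go_id = c("A", "B")), dag)
  idx <- build_lca_index(dag, data.frame(id_u = "p1", id_v = "p2", label = 1L), ann)
  expect_equal(idx$anchors, "A")
  # a term at its own anchor contributes 1
  expect_equal(unname(go_feature_vector(idx, dag, "A", character(0))), 1)
  # both proteins one edge below the anchor: 2 + 2 (oracle: path enumeration)
  expect_equal(unname(go_feature_vector(idx, dag, "B", "B")), 4)
  # terms outside every cluster yield the zero vector
  expect_equal(unname(go_feature_vector(idx, dag, "R", "R")), 0)
  expect_equal(unname(go_feature_vector(idx, dag, character(0), character(0))), 0)
})

test_that("pair feature vector is symmetric and monotone under added terms", {
  set.seed(55)
  dag <- random_test_dag(20)
  prot <- sprintf("p%02d", 1:6)
  ann <- annotation_table(data.frame(
    protein_id = rep(prot, each = 4),
    go_id = sample(dag$nodes$id, 24, replace = TRUE)), dag)
  pairs <- data.frame(id_u = prot[1:3], id_v = prot[4:6], label = 1L)
  idx <- build_lca_index(dag, pairs, ann)
  for (i in 1:10) {
    Gu <- sample(dag$nodes$id, 3)
    Gv <- sample(dag$nodes$id, 2)
    expect_equal(go_feature_vector(idx, dag, Gu, Gv),
                 go_feature_vector(idx, dag, Gv, Gu))
    extra <- sample(names(idx$term2cluster), 1)
    v0 <- go_feature_vector(idx, dag, Gu, Gv)
    v1 <- go_feature_vector(idx, dag, c(Gu, extra), Gv)
    expect_true(all(v1 >= v0))
  }
})

test_that("LCA index serializes to JSON and back", {
  dag <- diamond_dag()
  ann <- annotation_table(data.frame(protein_id = c("p1", "p2"),
                                     go_id = c("B", "D")), dag)
  idx <- build_lca_index(dag, data.frame(id_u = "p1", id_v = "p2", label = 1L), ann)
  f <- withr::local_tempfile(fileext = ".json")
  write_lca_index(idx, f)
  expect_identical(read_lca_index(f), idx)
})
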