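# Synthetic universe and planted-signal pair generation.

test_that("universes are valid, unique-id, FASTA-round-trippable", {
  cfg <- synth_config(n_proteins = 50L, n_pairs = 60L, dag_size = 20L, seed = 5)
  u <- generate_universe(cfg)
  expect_equal(nrow(u$proteins), 50L)
  expect_false(anyDuplicated(u$proteins$id) > 0)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(u$proteins, fa)
  back <- read_fasta(fa)
  expect_equal(back$sequence, u$proteins$sequence)
  expect_equal(sort(names(u$dag$roots)),
               c("biological_process", "cellular_component", "molecular_function"))
})

test_that("generated DAGs are acyclic across random configs", {
  set.seed(61)
  for (i in 1:8) {
    cfg <- synth_config(n_proteins = 10L, n_pairs = 5L,
                        dag_size = sample(10:40, 1),
                        n_groups = sample(2:4, 1), seed = sample(1e6, 1))
    u <- generate_universe(cfg)       # go_dag() errors on any cycle
    expect_s3_class(u$dag, "go_dag")
    expect_equal(unname(u$dag$depth[u$dag$roots]), rep(0L, 3))
  }
})

test_that("annotations are group-coherent: within-group Jaccard exceeds between", {
  cfg <- synth_config(seed = 62)
  u <- generate_universe(cfg)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  ids <- u$proteins$id
  set.seed(62)
  within <- c(); between <- c()
  for (i in 1:300) {
    p <- sample(ids, 2)
    j <- jac(u$annotations$sets[[p[1]]], u$annotations$sets[[p[2]]])
    same <- u$proteins$group[match(p[1], ids)] == u$proteins$group[match(p[2], ids)]
    if (same) within <- c(within, j) else between <- c(between, j)
  }
  expect_gt(mean(within), mean(between))  # oracle: direct Jaccard computation
})

test_that("universe generation is byte-deterministic given the seed", {
  cfg <- synth_config(n_proteins = 30L, n_pairs = 40L, dag_size = 15L, seed = 63)
  u1 <- generate_universe(cfg)
  u2 <- generate_universe(cfg)
  expect_identical(serialize(u1, NULL), serialize(u2, NULL))
  p1 <- generate_pairs(u1, cfg)
  p2 <- generate_pairs(u2, cfg)
  expect_identical(serialize(p1, NULL), serialize(p2, NULL))
})

test_that("written universes are byte-identical across writes and re-readable", {
  cfg <- synth_config(n_proteins = 25L, n_pairs = 30L, dag_size = 12L, seed = 64)
  u <- generate_universe(cfg)
  p <- generate_pairs(u, cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_universe(u, p, d1)
  f2 <- write_universe(u, p, d2)
  for (k in names(f1)) {
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
  }
  # generated artifacts pass the package validators unmodified
  prot <- read_fasta(f1["fasta"])
  dag <- read_go_obo(f1["obo"])
  ann <- read_annotations(f1["annotations"], dag)
  pp <- read_pairs(f1["pairs"], prot)
  expect_equal(nrow(pp), 30L)
  expect_equal(length(ann$sets), length(u$annotations$sets))
  expect_equal(sort(dag$nodes$id), sort(u$dag$nodes$id))
})

test_that("requesting more pairs than exist is an error", {
  cfg <- synth_config(n_proteins = 6L, n_pairs = 100L, dag_size = 10L, seed = 65)
  u <- generate_universe(cfg)
  expect_error(generate_pairs(u, cfg), "available")
})

test_that("positive fraction tracks the target at n = 2000", {
  cfg <- synth_config(n_proteins = 120L, n_pairs = 2000L, seed = 66)
  u <- generate_universe(cfg)
  p <- generate_pairs(u, cfg)
  expect_equal(mean(p$label), 0.5, tolerance = 0.06)  # 0.5 +/- 0.03
})

test_that("the planted signal is null at beta_sig 0 and strong at beta_sig 3", {
  cfg0 <- synth_config(n_proteins = 160L, n_pairs = 10000L, beta_sig = 0, seed = 67)
  u0 <- generate_universe(cfg0)
  p0 <- generate_pairs(u0, cfg0)
  expect_equal(rank_auc(attr(p0, "signal"), p0$label), 0.5, tolerance = 0.04)
  cfg3 <- synth_config(n_proteins = 120L, n_pairs = 2000L, beta_sig = 3, seed = 68)
  u3 <- generate_universe(cfg3)
  p3 <- generate_pairs(u3, cfg3)
  expect_gte(rank_auc(attr(p3, "signal"), p3$label), 0.85)
})
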