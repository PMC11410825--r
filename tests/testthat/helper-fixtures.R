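# Shared fixtures and independent oracles, built in code at test time.

# small diamond DAG: R -> {B, C} -> D (edges child -> parent)
diamond_dag <- function() {
  go_dag(nodes = data.frame(id = c("R", "B", "C", "D"), namespace = "bp",
                            stringsAsFactors = FALSE),
         edges = data.frame(child = c("B", "C", "D", "D"),
                            parent = c("R", "R", "B", "C"),
                            stringsAsFactors = FALSE))
}

# star DAG: root R with leaf children
star_dag <- function(n_leaves = 3) {
  leaves <- LETTERS[seq_len(n_leaves) + 1]
  go_dag(nodes = data.frame(id = c("R", leaves), namespace = "bp",
                            stringsAsFactors = FALSE),
         edges = data.frame(child = leaves, parent = "R",
                            stringsAsFactors = FALSE))
}

# random rooted DAG in the attach-to-1-2-existing-parents style, built
# independently of the package generator
random_test_dag <- function(n_nodes, namespace = "bp") {
  ids <- sprintf("T%03d", seq_len(n_nodes))
  child <- character(0); parent <- character(0)
  for (i in seq_len(n_nodes)[-1]) {
    par <- sample(seq_len(i - 1), min(sample(1:2, 1), i - 1))
    child <- c(child, rep(ids[i], length(par)))
    parent <- c(parent, ids[par])
  }
  go_dag(data.frame(id = ids, namespace = namespace, stringsAsFactors = FALSE),
         data.frame(child = child, parent = parent, stringsAsFactors = FALSE))
}

# brute-force LCA oracle: intersect full ancestor sets, take maximum depth,
# break ties by lexicographic id
brute_lca <- function(dag, terms) {
  anc <- lapply(terms, function(t) go_ancestors(dag, t))
  common <- Reduce(intersect, anc)
  d <- dag$depth[common]
  sort(common[d == max(d)])[1]
}

# naive O(L * k * G) double-loop auto-covariance oracle
naive_ac <- function(encoded, G) {
  L <- nrow(encoded); k <- ncol(encoded)
  out <- numeric(0)
  for (l in seq_len(k)) {
    mu <- mean(encoded[, l])
    for (g in seq_len(G)) {
      acc <- 0
      for (m in seq_len(L - g)) {
        acc <- acc + (encoded[m, l] - mu) * (encoded[m + g, l] - mu)
      }
      out <- c(out, acc / (L - g))
    }
  }
  unname(out)
}

# synthetic scale table with k columns, values distinct per residue
toy_scale_table <- function(k = 14, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(20 * k), 20, k,
              dimnames = list(ppifuse:::AA_ALPHABET, paste0("s", seq_len(k))))
  m
}

random_protein <- function(len) {
  paste(sample(ppifuse:::AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# all-zero LSTM parameters of a given size (forces gates to 0.5, head to 0.5)
zero_lstm_params <- function(h = 4, head = c(3, 2)) {
  structure(list(
    h = h,
    Wf = matrix(0, h, h + 1), df = rep(0, h),
    Wi = matrix(0, h, h + 1), di = rep(0, h),
    We = matrix(0, h, h + 1), de = rep(0, h),
    Wq = matrix(0, h, h + 1), bq = rep(0, h),
    W1 = matrix(0, head[1], h), b1 = rep(0, head[1]),
    W2 = matrix(0, head[2], head[1]), b2 = rep(0, head[2]),
    W3 = matrix(0, 1, head[2]), b3 = 0), class = "lstm_params")
}

# rank-based AUC
rank_auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
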