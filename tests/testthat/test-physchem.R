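# Physicochemical encoding and auto-covariance compression.

test_that("bundled scale table has 20 amino acids on 14 scales", {
  scales <- load_scale_table()
  expect_equal(dim(scales), c(20L, 14L))
  expect_setequal(rownames(scales), ppifuse:::AA_ALPHABET)
  expect_false(anyNA(scales))
  expect_false(anyDuplicated(colnames(scales)) > 0)
})

test_that("residue encoding maps each residue to its scale row", {
  scales <- load_scale_table()
  m <- residue_encode("ACD", scales)
  expect_equal(dim(m), c(3L, 14L))
  expect_equal(residue_encode("A", scales)[1, ], scales["A", ])
  # every protein encodes to 14 columns with the bundled table
  expect_equal(ncol(residue_encode(random_protein(30), scales)), 14L)
  expect_error(residue_encode("ACB", scales), "position 3")
})

test_that("auto-covariance matches the hand-expanded toy case", {
  m <- matrix(c(1, 2, 3, 4), ncol = 1)
  # ((1-2.5)(2-2.5) + (2-2.5)(3-2.5) + (3-2.5)(4-2.5)) / 3 = 1.25/3
  expect_equal(unname(auto_covariance(m, G = 1)), 1.25 / 3)
  expect_equal(unname(auto_covariance(matrix(rep(7, 9), ncol = 1), G = 3)),
               rep(0, 3))
  expect_error(auto_covariance(m, G = 4), "G = 4")
  expect_error(auto_covariance(m, G = 5, protein_id = "px"), "px")
})

test_that("auto-covariance equals the naive double-loop oracle", {
  set.seed(101)
  for (i in 1:25) {
    L <- sample(5:30, 1)
    k <- sample(c(1, 3, 14), 1)
    G <- sample(1:3, 1)
    enc <- matrix(rnorm(L * k), L, k)
    expect_equal(unname(auto_covariance(enc, G)), naive_ac(enc, G),
                 tolerance = 1e-12)
  }
})

test_that("AC is translation-invariant and scales quadratically", {
  set.seed(7)
  enc <- matrix(rnorm(60), 20, 3)
  base <- auto_covariance(enc, 2)
  expect_equal(auto_covariance(enc + 5, 2), base, tolerance = 1e-12)
  expect_equal(auto_covariance(enc * 3, 2), base * 9, tolerance = 1e-10)
})

test_that("two-step scaling standardizes then min-max rescales to [0,1]", {
  X <- cbind(a = c(2, 4, 6), b = c(1, 1, 1))
  expect_warning(sc <- fit_ac_scaler(X), "zero-variance")
  scaled <- apply_ac_scaler(X, sc)
  expect_equal(scaled[, "a"], c(0, 0.5, 1))   # oracle: z then min-max by hand
  expect_equal(scaled[, "b"], rep(0, 3))      # degenerate column rule
  # held-out values outside the training range clip to [0, 1]; degenerate
  # columns stay 0
  expect_equal(unname(apply_ac_scaler(cbind(a = -100, b = 5), sc)[1, ]), c(0, 0))
  expect_equal(unname(apply_ac_scaler(cbind(a = 100, b = 5), sc)[1, ]), c(1, 0))
  expect_error(fit_ac_scaler(X[1, , drop = FALSE]), "2 training proteins")
})

test_that("scaled training features span [0,1] per non-degenerate column", {
  set.seed(11)
  X <- matrix(rnorm(80), 10, 8)
  sc <- fit_ac_scaler(X)
  S <- apply_ac_scaler(X, sc)
  expect_true(all(S >= 0 & S <= 1))
  expect_equal(unname(apply(S, 2, min)), rep(0, 8))
  expect_equal(unname(apply(S, 2, max)), rep(1, 8))
})

test_that("pair features concatenate to the documented lengths", {
  scales <- load_scale_table()
  prot <- data.frame(id = c("u", "v"),
                     sequence = c(random_protein(40), random_protein(25)))
  ac <- ac_features(prot, scales, G = 2)
  expect_equal(ncol(ac), 28L)  # 14 scales x gap 2 per protein
  pf <- pair_feature(ac["u", ], ac["v", ])
  expect_length(pf, 56L)       # 2 x 14 x 2
  expect_length(pair_feature(1, 2), 2L)  # k = 1, G = 1 degenerate case
  expect_error(pair_feature(1:3, 1:2), "mismatch")
})
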