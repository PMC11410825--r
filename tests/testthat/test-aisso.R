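# The hybrid shark-smell / Aquila optimizer.

sphere <- function(x) sum(x^2)

test_that("ICMIC stream follows the map and stays in [-1, 1]", {
  expect_equal(icmic_stream(1, 2 / pi, 1), 1)  # sin(pi/2)
  s <- icmic_stream(2, 0.7, 300)
  expect_true(all(s >= -1 & s <= 1))
  expect_identical(s, icmic_stream(2, 0.7, 300))
  expect_error(icmic_stream(0, 0.5, 5), "a must")
  expect_error(icmic_stream(1, 0, 5), "x0")
})

test_that("Levy sigma matches the direct gamma-function evaluation", {
  # frozen from an independent evaluation of the printed formula at beta = 1.5
  expect_equal(levy_sigma(1.5), 0.581368317019, tolerance = 1e-10)
  expect_equal(levy_sigma(1.5, mantegna_exponent = TRUE),
               0.581368317019^(1 / 1.5), tolerance = 1e-10)
})

test_that("Levy steps vanish at zero scale and are seed-reproducible", {
  cfg0 <- aisso_config(levy_s = 0)
  set.seed(1)
  expect_equal(levy_step(5, cfg0), rep(0, 5))
  cfg <- aisso_config()
  set.seed(2); a <- levy_step(4, cfg)
  set.seed(2); b <- levy_step(4, cfg)
  expect_identical(a, b)
})

test_that("population initialization honors bounds and the seed solution", {
  cfg <- aisso_config(np = 10L, nd = 2L)
  set.seed(3)
  pop <- init_population(cfg)
  expect_equal(dim(pop$positions), c(10L, 2L))
  expect_true(all(pop$positions >= 0 & pop$positions <= 1))
  expect_equal(pop$velocities, matrix(0, 10, 2))
  set.seed(3)
  pop2 <- init_population(cfg, seed_solution = c(0.25, 0.75))
  expect_equal(pop2$positions[1, ], c(0.25, 0.75))
  set.seed(3); p1 <- init_population(cfg)
  set.seed(3); p2 <- init_population(cfg)
  expect_identical(p1, p2)
  expect_error(aisso_config(lb = 1, ub = 0), "bound")
  expect_error(init_population(aisso_config(), seed_solution = 1:3), "length")
})

test_that("shark move descends the gradient within the step bound", {
  cfg <- aisso_config(netak = 1, alphak = 0, delT = 0.1, fd_step = 1e-3)
  # flat objective, resting shark: no movement
  set.seed(4)
  still <- sso_move(c(0.5, 0.5), c(0, 0), function(x) 1, cfg)
  expect_equal(still$position, c(0.5, 0.5))
  # 1-D sphere at 0.5: gradient 2x = 1, move is toward 0, at most delT * |grad|
  cfg1 <- aisso_config(nd = 1L, netak = 1, alphak = 0, delT = 0.1)
  set.seed(5)
  for (i in 1:10) {
    mv <- sso_move(0.5, 0, sphere, cfg1)
    expect_lte(mv$position, 0.5)
    expect_gte(mv$position, 0.5 - 0.1 * 1.0 - 1e-9)
  }
})

test_that("velocity limiter caps the magnitude at |betak * v_prev|", {
  cfg <- aisso_config(nd = 1L, netak = 1, alphak = 1, betak = 0.5)
  set.seed(6)
  for (i in 1:20) {
    vprev <- runif(1, -1, 1)
    mv <- sso_move(0.5, vprev, sphere, cfg)
    expect_lte(abs(mv$velocity), max(abs(0.5 * vprev),
               abs(1 * 1 * 1 + 1 * 1 * vprev)) + 1e-9)
    # when the limiter binds, the capped term's sign is kept
    if (abs(mv$velocity) == abs(0.5 * vprev)) {
      expect_equal(sign(mv$velocity), sign(vprev))
    }
  }
})

test_that("Aquila proposal reduces to the random member at zero mixing", {
  cfg <- aisso_config(levy_s = 0)
  set.seed(7)
  prop <- aquila_update(c(0.2, 0.8), c(0.4, 0.6), cfg, ra = 0)
  expect_equal(prop, c(0.4, 0.6))
  # spiral at theta = 3*pi/2 with upsilon = omega = 0: (Pi - K) = r1 per dim
  cfg2 <- aisso_config(upsilon = 0, omega = 0, levy_s = 0)
  set.seed(8)
  prop2 <- aquila_update(c(0, 0), c(0, 0), cfg2, ra = 1)
  set.seed(8)
  rnorm(2); rnorm(2)      # the Levy draws the proposal consumed first
  r1 <- runif(1, 0, 10)   # then the spiral radius draw
  expect_equal(prop2, pmin(pmax(c(r1, r1), 0), 1))
  # always within bounds
  set.seed(9)
  for (i in 1:20) {
    p <- aquila_update(runif(2), runif(2), aisso_config())
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("Gaussian mutation respects bounds and the zero-delta identity", {
  cfg <- aisso_config(delta = 0)
  expect_equal(gauss_mutate(c(0.3, 0.7), cfg), c(0.3, 0.7))
  cfg2 <- aisso_config(delta = 0.5)
  set.seed(10)
  for (i in 1:20) {
    m <- gauss_mutate(runif(2), cfg2)
    expect_true(all(m >= 0 & m <= 1))
  }
  set.seed(11); a <- gauss_mutate(c(0.5, 0.5), cfg2)
  set.seed(11); b <- gauss_mutate(c(0.5, 0.5), cfg2)
  expect_identical(a, b)
})

test_that("optimizer is elitist, bounded, deterministic, and uses its budget", {
  cfg <- aisso_config(seed = 12L)
  out <- aisso_optimize(sphere, cfg)
  expect_equal(out$trace, cummin(out$trace))  # non-increasing
  expect_true(all(out$population >= 0 & out$population <= 1))
  out2 <- aisso_optimize(sphere, cfg)
  expect_identical(out$trace, out2$trace)
  expect_identical(out$best_par, out2$best_par)
  # zero iterations: best of the initial population
  cfg0 <- aisso_config(itermax = 0L, seed = 13L)
  out0 <- aisso_optimize(sphere, cfg0)
  set.seed(13L)
  pop <- init_population(cfg0)
  expect_equal(out0$best_value, min(apply(pop$positions, 1, sphere)))
  expect_length(out0$trace, 0L)
})

test_that("a seeded solution enters the population verbatim", {
  cfg <- aisso_config(itermax = 0L, seed = 14L)
  out <- aisso_optimize(sphere, cfg, seed_solution = c(0, 0))
  expect_equal(out$best_value, 0)
  expect_equal(out$best_par, c(0, 0))
})

test_that("the optimizer solves the sphere and beats random search", {
  cfg <- aisso_config(seed = 15L)
  out <- aisso_optimize(sphere, cfg)
  expect_lte(out$best_value, 1e-2)
  rs <- random_search(sphere, cfg, n_evals = out$n_evals)
  expect_lte(out$best_value, rs$best_value)
})
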