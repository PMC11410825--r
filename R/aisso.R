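# AISSO: Aquila-Influenced Shark Smell Optimization.
#
# Each candidate ("shark") moves along the descent direction of the objective
# with momentum and a velocity limiter (the shark-smell move), then receives
# an Aquila "contour flight" proposal -- a Levy-flight step around the global
# best plus a spiral offset relative to a random population member -- which
# is accepted greedily only if it improves the candidate. A small fraction of
# non-best candidates receives Gaussian mutation per iteration. The global
# best is elitist: its trace never worsens.

#' AISSO configuration
#'
#' Defaults mirror the optimizer's published parameterization: population
#' `np = 10`, dimension `nd = 2`, `itermax = 25`, gradient rate
#' `netak = 0.5`, inertia `alphak = 0.5`, velocity-limit ratio `betak = 4`
#' (the shark-smell method's published growth cap; a ratio below 1 would
#' contract every velocity geometrically and freeze the swarm),
#' time step `delT = 0.1`, Levy scale `levy_s = 0.01` with exponent
#' `levy_beta = 1.5`, spiral constants `upsilon = 0.00565`, `omega = 0.005`,
#' `theta1 = 3*pi/2`, mutation fraction `delta = 0.1`, box bounds
#' `[0, 1]^nd`, finite-difference step `fd_step = 1e-3`.
#'
#' @param ... Named overrides of any default.
#' @return An `aisso_config` list.
#' @export
aisso_config <- function(...) {
  cfg <- utils::modifyList(list(
    np = 10L, nd = 2L, itermax = 25L,
    netak = 0.5, alphak = 0.5, betak = 4, delT = 0.1,
    levy_s = 0.01, levy_beta = 1.5, mantegna_exponent = FALSE,
    upsilon = 0.00565, omega = 0.005, theta1 = 3 * pi / 2,
    r1_max = 10, delta = 0.1,
    lb = 0, ub = 1, fd_step = 1e-3,
    icmic_a = 2, icmic_x0 = 0.7,
    seed = 1L), list(...))
  if (cfg$np < 2L) stop2("population size np must be >= 2")
  if (cfg$itermax < 0L) stop2("itermax must be >= 0")
  if (any(rep(cfg$lb, length.out = cfg$nd) >= rep(cfg$ub, length.out = cfg$nd))) {
    stop2("lower bound must be below upper bound in every dimension")
  }
  structure(cfg, class = "aisso_config")
}

#' Iterative chaotic map with infinite collapses (ICMIC)
#'
#' Iterates `x <- sin(a / x)`; all iterates lie in \[-1, 1\]. An iterate
#' hitting exactly 0 is nudged by 1e-12 so the stream never stalls.
#'
#' @param a Control parameter (> 0).
#' @param x0 Non-zero seed.
#' @param n Stream length.
#' @return Numeric vector of `n` iterates.
#' @examples
#' icmic_stream(1, 2 / pi, 1)  # sin(pi/2) = 1
#' @export
icmic_stream <- function(a, x0, n) {
  if (a <= 0) stop2("a must be > 0")
  if (x0 == 0) stop2("x0 must be non-zero")
  out <- numeric(n)
  x <- x0
  for (i in seq_len(n)) {
    x <- sin(a / x)
    if (x == 0) x <- 1e-12
    out[i] <- x
  }
  out
}

#' Levy-flight scale constant
#'
#' `sigma = Gamma(1 + beta) * sin(pi * beta / 2) /
#'  (Gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2))`, used as printed;
#' `mantegna_exponent = TRUE` raises it to `1 / beta` (the standard Mantegna
#' form).
#'
#' @param beta Stability exponent (default 1.5).
#' @param mantegna_exponent Apply the outer `1 / beta` exponent.
#' @return Positive scalar.
#' @export
levy_sigma <- function(beta = 1.5, mantegna_exponent = FALSE) {
  s <- (gamma(1 + beta) * sin(pi * beta / 2)) /
    (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2))
  if (mantegna_exponent) s^(1 / beta) else s
}

#' Draw one Levy-flight step
#'
#' Per element: `s * (N1 * sigma) / |N2|^(1/beta)` with `N1`, `N2` standard
#' normal and `|N2|` floored at 1e-12.
#'
#' @param dim Number of elements.
#' @param config An [aisso_config].
#' @return Numeric vector of length `dim`.
#' @export
levy_step <- function(dim, config = aisso_config()) {
  sig <- levy_sigma(config$levy_beta, config$mantegna_exponent)
  n1 <- stats::rnorm(dim)
  n2 <- stats::rnorm(dim)
  config$levy_s * (n1 * sig) / pmax(abs(n2), 1e-12)^(1 / config$levy_beta)
}

#' Initialize the AISSO population
#'
#' Uniform positions within the box bounds, zero velocities. An optional seed
#' solution (for instance the MAPE-derived fusion weights) replaces the first
#' member verbatim.
#'
#' @param config An [aisso_config].
#' @param seed_solution Optional numeric vector of length `nd`.
#' @return List with `positions` (np x nd matrix) and `velocities`
#'   (np x nd zero matrix).
#' @export
init_population <- function(config, seed_solution = NULL) {
  lb <- rep(config$lb, length.out = config$nd)
  ub <- rep(config$ub, length.out = config$nd)
  pos <- matrix(stats::runif(config$np * config$nd), config$np, config$nd)
  pos <- sweep(sweep(pos, 2L, ub - lb, "*"), 2L, lb, "+")
  if (!is.null(seed_solution)) {
    if (length(seed_solution) != config$nd) stop2("seed solution has wrong length")
    pos[1L, ] <- seed_solution
  }
  list(positions = pos, velocities = matrix(0, config$np, config$nd))
}

fd_gradient <- function(objective, x, h) {
  g <- numeric(length(x))
  for (j in seq_along(x)) {
    step <- h
    for (attempt in 1:2) {
      e <- numeric(length(x)); e[j] <- step
      fp <- objective(x + e)
      fm <- objective(x - e)
      if (is.finite(fp) && is.finite(fm)) {
        g[j] <- (fp - fm) / (2 * step)
        break
      }
      if (attempt == 2L) stop2("objective non-finite at finite-difference probe")
      step <- step / 10
    }
  }
  g
}

#' One shark-smell move
#'
#' Velocity per dimension: descent term `netak * U1 * (-grad)` (central
#' finite differences; the objective is minimized so the negative gradient is
#' the odour-ascent direction) plus momentum `alphak * U2 * v_prev`, with the
#' magnitude capped at `|betak * v_prev|` keeping the sign of the capped
#' term. The cap is vacuous while the prior velocity is zero (a resting shark
#' has no speed ratio to respect). Position advances by `v * delT`, clamped
#' to the bounds.
#'
#' @param position,velocity Current state vectors.
#' @param objective Function of a position vector returning a scalar.
#' @param config An [aisso_config].
#' @return List with updated `position` and `velocity`.
#' @export
sso_move <- function(position, velocity, objective, config = aisso_config()) {
  nd <- length(position)
  grad <- fd_gradient(objective, position, config$fd_step)
  vcand <- config$netak * stats::runif(nd) * (-grad) +
    config$alphak * stats::runif(nd) * velocity
  bv <- config$betak * velocity
  capped <- abs(bv) > 0 & abs(vcand) > abs(bv)
  v <- ifelse(capped, bv, vcand)
  lb <- rep(config$lb, length.out = nd)
  ub <- rep(config$ub, length.out = nd)
  list(position = clamp(position + v * config$delT, lb, ub), velocity = v)
}

#' One Aquila contour-flight proposal
#'
#' `X_best * Levy(nd) + X_R + (Pi - K) * ra` with spiral coordinates
#' `Pi = r * cos(theta)`, `K = r * sin(theta)`, `r = r1 + upsilon * D1`,
#' `theta = -omega * D1 + theta1`, `D1 = 1..nd`, `r1` uniform on
#' `[0, r1_max]`; the result is clamped to the bounds.
#'
#' @param best Global best position.
#' @param x_random A randomly chosen population member.
#' @param config An [aisso_config].
#' @param ra Mixing variate in (0, 1); drawn uniform if missing.
#' @return Proposed position vector.
#' @export
aquila_update <- function(best, x_random, config = aisso_config(), ra = NULL) {
  nd <- length(best)
  if (is.null(ra)) ra <- stats::runif(1)
  lev <- levy_step(nd, config)
  d1 <- seq_len(nd)
  r1 <- stats::runif(1, 0, config$r1_max)
  r <- r1 + config$upsilon * d1
  theta <- -config$omega * d1 + config$theta1
  spiral <- r * cos(theta) - r * sin(theta)
  lb <- rep(config$lb, length.out = nd)
  ub <- rep(config$ub, length.out = nd)
  clamp(best * lev + x_random + spiral * ra, lb, ub)
}

#' Gaussian mutation of a position
#'
#' Adds `N(0, (delta * (ub - lb))^2)` noise per element and clamps to the
#' bounds.
#'
#' @param position Position vector.
#' @param config An [aisso_config].
#' @return Mutated position vector.
#' @export
gauss_mutate <- function(position, config = aisso_config()) {
  nd <- length(position)
  lb <- rep(config$lb, length.out = nd)
  ub <- rep(config$ub, length.out = nd)
  if (config$delta == 0) return(position)
  clamp(position + stats::rnorm(nd, sd = config$delta * (ub - lb)), lb, ub)
}

#' Run the AISSO optimizer
#'
#' Minimizes `objective` over the box `[lb, ub]^nd`. Per iteration every
#' candidate takes a shark-smell move, then an Aquila contour proposal is
#' accepted greedily if it improves the candidate; a `delta` fraction of
#' non-best candidates receives greedy Gaussian mutation. The Aquila mixing
#' variate comes from an ICMIC chaotic stream. The returned best-value trace
#' is non-increasing (elitism).
#'
#' @param objective Function of a numeric vector of length `nd` returning a
#'   finite scalar to minimize.
#' @param config An [aisso_config].
#' @param seed_solution Optional vector placed verbatim in the initial
#'   population.
#' @return List with `best_par`, `best_value`, per-iteration `trace`,
#'   final `population` matrix, and the evaluation count `n_evals`.
#' @export
aisso_optimize <- function(objective, config = aisso_config(),
                           seed_solution = NULL) {
  set.seed(config$seed)
  np <- config$np
  n_evals <- 0L
  obj <- function(x) { n_evals <<- n_evals + 1L; objective(x) }

  pop <- init_population(config, seed_solution)
  vals <- apply(pop$positions, 1L, obj)
  if (all(!is.finite(vals))) stop2("objective non-finite over the whole initial population")
  best_i <- which.min(vals)
  best_par <- pop$positions[best_i, ]
  best_value <- vals[best_i]

  r3 <- if (config$itermax > 0) {
    abs(icmic_stream(config$icmic_a, config$icmic_x0, config$itermax * np))
  } else numeric(0)
  r3[r3 == 0] <- 1e-12
  trace <- numeric(config$itermax)
  k <- 0L
  for (it in seq_len(config$itermax)) {
    for (y in seq_len(np)) {
      k <- k + 1L
      mv <- sso_move(pop$positions[y, ], pop$velocities[y, ], obj, config)
      pop$positions[y, ] <- mv$position
      pop$velocities[y, ] <- mv$velocity
      vals[y] <- obj(mv$position)
      if (vals[y] < best_value) { best_value <- vals[y]; best_par <- mv$position }
      xr <- pop$positions[sample.int(np, 1L), ]
      prop <- aquila_update(best_par, xr, config, ra = r3[k])
      pv <- obj(prop)
      if (pv < vals[y]) {
        pop$positions[y, ] <- prop
        vals[y] <- pv
        if (pv < best_value) { best_value <- pv; best_par <- prop }
      }
    }
    # Gaussian mutation of a delta-fraction of non-best candidates
    non_best <- setdiff(seq_len(np), which.min(vals))
    n_mut <- max(1L, round(config$delta * np))
    for (y in sample(non_best, min(n_mut, length(non_best)))) {
      cand <- gauss_mutate(pop$positions[y, ], config)
      cv <- obj(cand)
      if (cv < vals[y]) {
        pop$positions[y, ] <- cand
        vals[y] <- cv
        if (cv < best_value) { best_value <- cv; best_par <- cand }
      }
    }
    trace[it] <- best_value
  }
  list(best_par = best_par, best_value = best_value, trace = trace,
       population = pop$positions, values = vals, n_evals = n_evals)
}

#' Equal-budget uniform random search (control)
#'
#' Draws `n_evals` uniform points in the box and returns the best; used as
#' the baseline the population optimizer must beat.
#'
#' @param objective Function to minimize.
#' @param config An [aisso_config] (bounds, dimension, seed).
#' @param n_evals Evaluation budget.
#' @return List with `best_par` and `best_value`.
#' @export
random_search <- function(objective, config = aisso_config(), n_evals) {
  set.seed(config$seed)
  lb <- rep(config$lb, length.out = config$nd)
  ub <- rep(config$ub, length.out = config$nd)
  best_value <- Inf
  best_par <- NULL
  for (i in seq_len(n_evals)) {
    x <- lb + stats::runif(config$nd) * (ub - lb)
    v <- objective(x)
    if (v < best_value) { best_value <- v; best_par <- x }
  }
  list(best_par = best_par, best_value = best_value)
}
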