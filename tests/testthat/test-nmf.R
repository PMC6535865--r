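cfg_tight <- solver_config(max_outer_iter = 500L, rel_tol = 0)

test_that("objective values match scalar hand computations", {
  expect_equal(nmf_objective(matrix(2), matrix(1), matrix(1), "euclidean_sq"), 1)
  expect_equal(nmf_objective(matrix(2), matrix(1), matrix(1), "kl"),
               2 * log(2) - 2 + 1)
  W <- matrix(runif(6), 3, 2); H <- matrix(runif(4), 2, 2)
  V <- W %*% H
  expect_equal(nmf_objective(V, W, H, "euclidean_sq"), 0)
  expect_equal(nmf_objective(V, W, H, "kl"), 0, tolerance = 1e-12)
  expect_equal(nmf_objective(V, W, H, "pnmf_regularized", alpha = 1, beta = 1),
               sum(W^2) + sum(H^2))
  # KL conventions: 0 log 0 = 0; support mismatch diverges
  expect_equal(nmf_objective(matrix(0), matrix(1), matrix(0), "kl"), 0)
  expect_equal(nmf_objective(matrix(1), matrix(0), matrix(0), "kl"), Inf)
  expect_error(nmf_objective(matrix(1), matrix(1, 2, 1), matrix(1), "euclidean_sq"),
               "shape")
})

test_that("an exact factorization is a fixed point of the multiplicative update", {
  set.seed(4)
  W <- matrix(runif(6) + 0.5, 3, 2)
  H <- matrix(runif(8) + 0.5, 2, 4)
  V <- W %*% H
  fit <- solve_mu(V, 2, init = structure(list(W0 = W, H0 = H), class = "amnd_init"),
                  cfg = solver_config(max_outer_iter = 1L, rel_tol = 0,
                                      epsilon_guard = 1e-300))
  expect_equal(fit$W, W, tolerance = 1e-10)
  expect_equal(fit$H, H, tolerance = 1e-10)
})

test_that("all five solvers reach the rank-1 SVD residual on a positive matrix", {
  V <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  target <- svd_rank1_residual(V)
  tols <- c(mu = 1e-3, als = 1e-6, alsobs = 1e-6, pg = 1e-4, pnmf = 1e-3)
  solvers <- list(
    mu = function() solve_mu(V, 1, cfg = cfg_tight),
    als = function() solve_als(V, 1, cfg = cfg_tight),
    alsobs = function() solve_alsobs(V, 1, cfg = cfg_tight),
    pg = function() solve_pg(V, 1, cfg = cfg_tight),
    pnmf = function() {
      c0 <- cfg_tight; c0$pnmf_alpha <- 0; c0$pnmf_beta <- 0
      solve_pnmf(V, 1, cfg = c0)
    })
  for (nm in names(solvers)) {
    fit <- solvers[[nm]]()
    achieved <- sqrt(nmf_objective(V, fit$W, fit$H, "euclidean_sq"))
    expect_lt(abs(achieved - target), tols[[nm]])
  }
})

test_that("monotone solvers have nonincreasing objective traces on random instances", {
  for (k in 1:15) {
    V <- rand_nonneg(10, 8, 300 + k)
    cfg <- solver_config(max_outer_iter = 40L, rel_tol = 0)
    for (fit in list(solve_mu(V, 3, cfg = cfg),
                     solve_als(V, 3, cfg = cfg),
                     solve_alsobs(V, 3, cfg = cfg))) {
      expect_true(all(diff(fit$objective_trace) <= 1e-9))
      expect_no_neg(fit$W); expect_no_neg(fit$H)
    }
    fit_pg <- solve_pg(V, 3, cfg = cfg)
    fit_pn <- solve_pnmf(V, 3, cfg = cfg)
    for (fit in list(fit_pg, fit_pn)) {
      expect_lte(utils::tail(fit$objective_trace, 1), fit$objective_trace[1])
      expect_no_neg(fit$W); expect_no_neg(fit$H)
    }
  }
})

test_that("alternating NNLS recovers planted factorizations", {
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    W0 <- matrix(runif(12), 6, 2)
    H0 <- matrix(runif(10), 2, 5)
    V <- W0 %*% H0
    fit <- solve_als(V, 2, init = "random",
                     cfg = solver_config(max_outer_iter = 100L, rel_tol = 0,
                                         seed = seed))
    if (utils::tail(fit$objective_trace, 1) < 1e-8) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("the OBS column solver matches exhaustive active-set NNLS", {
  # 6x4 least-squares subproblems whose unconstrained solution has exactly
  # one negative coefficient: the cleanest exercise of one saliency-guided
  # deletion plus correction. (Cascading multi-negative instances are where
  # the greedy no-re-entry pruning legitimately diverges from exact NNLS.)
  hits <- 0L; tried <- 0L; seed <- 0L
  while (tried < 100L) {
    seed <- seed + 1L
    set.seed(1000 + seed)
    A <- matrix(rnorm(24), 6, 4)
    b <- rnorm(6)
    unc <- qr.solve(A, b)
    if (sum(unc < 0) != 1L) next
    tried <- tried + 1L
    oracle <- brute_force_nnls(A, b)
    got <- amnd:::obs_solve(crossprod(A) + diag(1e-12, 4), crossprod(A, b))
    if (max(abs(got - oracle)) < 1e-6) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("the exact NNLS column solver agrees with the enumeration oracle", {
  for (seed in 1:40) {
    set.seed(2000 + seed)
    d <- sample(2:6, 1)
    A <- matrix(rnorm(9 * d), 9, d)
    b <- rnorm(9)
    oracle <- brute_force_nnls(A, b)
    got <- amnd:::nnls_solve(crossprod(A) + diag(1e-12, d), crossprod(A, b))
    expect_lt(max(abs(got - oracle)), 1e-6)
  }
})

test_that("the NNLS solver agrees with an established implementation", {
  skip_if_not_installed("pracma")
  for (seed in 1:10) {
    set.seed(3000 + seed)
    A <- matrix(rnorm(30), 10, 3)
    b <- rnorm(10)
    got <- amnd:::nnls_solve(crossprod(A) + diag(1e-12, 3), crossprod(A, b))
    ref <- pracma::lsqnonneg(A, b)$x
    expect_equal(as.numeric(got), as.numeric(ref), tolerance = 1e-8)
  }
})

test_that("regularized multiplicative updates reduce to the plain ones at zero penalty", {
  V <- rand_nonneg(6, 5, 77)
  init <- nndsvd(V, 2)
  init <- perturb_zeros(init, 1e-6)
  cfg0 <- solver_config(max_outer_iter = 7L, rel_tol = 0,
                        pnmf_alpha = 0, pnmf_beta = 0)
  f_mu <- solve_mu(V, 2, init = init, cfg = cfg0)
  f_pn <- solve_pnmf(V, 2, init = init, cfg = cfg0)
  expect_identical(f_pn$W, f_mu$W)
  expect_identical(f_pn$H, f_mu$H)
})

test_that("large penalties shrink the factor norms", {
  V <- rand_nonneg(5, 4, 31)
  init <- perturb_zeros(nndsvd(V, 2), 1e-6)
  cfg0 <- solver_config(max_outer_iter = 50L, rel_tol = 0,
                        pnmf_alpha = 0, pnmf_beta = 0)
  cfg1 <- solver_config(max_outer_iter = 50L, rel_tol = 0,
                        pnmf_alpha = 1000, pnmf_beta = 1000)
  f0 <- solve_pnmf(V, 2, init = init, cfg = cfg0)
  f1 <- solve_pnmf(V, 2, init = init, cfg = cfg1)
  expect_lt(norm(f1$W, "F"), norm(f0$W, "F"))
  expect_lt(norm(f1$H, "F"), norm(f0$H, "F"))
})

test_that("regularized updates match an independent re-implementation", {
  # straight-line duplicate of the update maps, written without reusing the
  # package internals
  V <- rand_nonneg(5, 4, 55)
  init <- perturb_zeros(nndsvd(V, 2), 1e-6)
  a <- 0.1; b <- 0.1; eps <- 1e-12
  W <- init$W0; H <- init$H0
  for (it in 1:100) {
    W <- W * (V %*% t(H)) / (W %*% H %*% t(H) + a * W + eps)
    H <- H * (t(W) %*% V) / (t(W) %*% W %*% H + b * H + eps)
  }
  obj_oracle <- sum((V - W %*% H)^2) + a * sum(W^2) + b * sum(H^2)
  fit <- solve_pnmf(V, 2, init = init,
                    cfg = solver_config(max_outer_iter = 100L, rel_tol = 0,
                                        pnmf_alpha = a, pnmf_beta = b))
  expect_equal(utils::tail(fit$objective_trace, 1), obj_oracle, tolerance = 1e-10)
})

test_that("projected-gradient subproblems respect their termination contract", {
  # started at the unconstrained optimum with nonnegative entries, the
  # projected gradient is zero and the state is untouched
  set.seed(8)
  A <- matrix(runif(12) + 0.5, 4, 3)
  Xstar <- matrix(runif(6) + 0.2, 3, 2)
  B <- A %*% Xstar
  out <- amnd:::pg_subproblem(crossprod(A), crossprod(A, B), Xstar,
                              solver_config())
  expect_equal(out, Xstar, tolerance = 1e-12)

  # generic start: stop rule is pg-norm <= pg_eps * initial gradient norm,
  # or the inner iteration cap
  cfgp <- solver_config(pg_eps = 1e-3, pg_max_inner = 200L)
  X0 <- matrix(runif(6), 3, 2)
  AtA <- crossprod(A); AtB <- crossprod(A, B)
  g0 <- sqrt(sum((AtA %*% X0 - AtB)^2))
  out2 <- amnd:::pg_subproblem(AtA, AtB, X0, cfgp)
  g <- AtA %*% out2 - AtB
  pg <- ifelse(out2 > 0, g, pmin(g, 0))
  expect_lte(sqrt(sum(pg^2)), 1e-3 * g0 + 1e-12)
})

test_that("factorize_all returns the five solvers in fixed order, deterministically", {
  V <- rand_nonneg(12, 9, 17)
  cfg <- solver_config(max_outer_iter = 30L)
  fits <- factorize_all(V, 3, cfg = cfg)
  expect_identical(names(fits), c("mu", "als", "alsobs", "pg", "pnmf"))
  for (f in fits) {
    expect_identical(dim(f$W), c(12L, 3L))
    expect_identical(dim(f$H), c(3L, 9L))
  }
  fits2 <- factorize_all(V, 3, cfg = cfg)
  expect_identical(lapply(fits, `[[`, "objective_trace"),
                   lapply(fits2, `[[`, "objective_trace"))
  # every solver beats the all-ones baseline factorization
  base <- nmf_objective(V, matrix(1, 12, 3), matrix(1, 3, 9), "euclidean_sq")
  for (f in fits) {
    expect_lt(nmf_objective(V, f$W, f$H, "euclidean_sq"), base)
  }
})

test_that("scaling V rescales the fit without changing the relative error", {
  V <- rand_nonneg(10, 7, 23)
  cfg <- solver_config(max_outer_iter = 50L, rel_tol = 0)
  for (solver in list(solve_mu, solve_als)) {
    f1 <- solver(V, 2, cfg = cfg)
    f2 <- solver(5 * V, 2, cfg = cfg)
    rel1 <- norm(V - f1$W %*% f1$H, "F") / norm(V, "F")
    rel2 <- norm(5 * V - f2$W %*% f2$H, "F") / norm(5 * V, "F")
    # the absolute epsilon guard in multiplicative denominators is the only
    # scale-dependent term, so equivariance is near-exact, not bitwise
    expect_equal(rel1, rel2, tolerance = 1e-3)
  }
})

test_that("held-out samples project onto the coefficient matrix consistently", {
  set.seed(14)
  W0 <- matrix(runif(20), 10, 2)
  H0 <- matrix(runif(12), 2, 6)
  V <- W0 %*% H0
  fit <- solve_als(V, 2, cfg = solver_config(max_outer_iter = 200L, rel_tol = 0))
  stopifnot(utils::tail(fit$objective_trace, 1) < 1e-8)
  # training rows reproduce their own feature rows at ~zero residual
  Wnew <- project_new_samples(fit, V[3:5, , drop = FALSE])
  expect_equal(Wnew, fit$W[3:5, , drop = FALSE], tolerance = 1e-4)
  # a zero row maps to zero features
  expect_equal(project_new_samples(fit, matrix(0, 1, 6)),
               matrix(0, 1, 2), tolerance = 1e-12)
  # random rows match the enumeration oracle
  for (k in 1:20) {
    set.seed(400 + k)
    v <- runif(6)
    got <- project_new_samples(fit$H, matrix(v, 1))
    oracle <- brute_force_nnls(t(fit$H), v)
    expect_lt(max(abs(as.numeric(got) - oracle)), 1e-6)
  }
  expect_error(project_new_samples(fit, matrix(1, 1, 5)), "columns")
})

test_that("solver preconditions are enforced", {
  V <- rand_nonneg(5, 4, 2)
  expect_error(solve_mu(V, 4), "rank")
  expect_error(solve_mu(matrix(0, 3, 3), 1), "zero")
  expect_error(solve_als(V - 1, 2), "nonnegative")
})
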