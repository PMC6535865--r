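#' Solver configuration for the NMF variants
#'
#' @param max_outer_iter Maximum number of outer (alternating) iterations.
#' @param rel_tol Stop when the relative change of the objective between
#'   outer iterations falls below this value.
#' @param epsilon_guard Small constant added to multiplicative-update
#'   denominators to avoid division by zero (the zero-deadlock guard).
#' @param cost Cost function for the multiplicative-update solver:
#'   `"euclidean"` (squared Frobenius) or `"kl"` (generalized
#'   Kullback-Leibler divergence).
#' @param pg_beta,pg_sigma Armijo backtracking constants for the projected
#'   gradient solver, both in (0, 1).
#' @param pg_eps Relative projected-gradient tolerance of the inner solves.
#' @param pg_max_inner Inner iteration cap per projected-gradient subproblem.
#' @param pnmf_alpha,pnmf_beta Frobenius penalty weights of the regularized
#'   solver's objective.
#' @param ridge Relative ridge added to the normal-equation matrices of the
#'   ALS-family subproblems before inversion.
#' @param seed Integer seed, used only when an explicit random
#'   initialization is requested.
#' @return A list of class `amnd_solver_config`.
#' @export
solver_config <- function(max_outer_iter = 200L, rel_tol = 1e-4,
                          epsilon_guard = 1e-12,
                          cost = c("euclidean", "kl"),
                          pg_beta = 0.1, pg_sigma = 0.01, pg_eps = 1e-4,
                          pg_max_inner = 50L,
                          pnmf_alpha = 0.1, pnmf_beta = 0.1,
                          ridge = 1e-10, seed = 1L) {
  cost <- match.arg(cost)
  stopifnot(max_outer_iter >= 1L, rel_tol >= 0, epsilon_guard > 0,
            pg_beta > 0, pg_beta < 1, pg_sigma > 0, pg_sigma < 1,
            pg_eps > 0, pg_max_inner >= 1L,
            pnmf_alpha >= 0, pnmf_beta >= 0, ridge >= 0)
  structure(
    list(max_outer_iter = as.integer(max_outer_iter), rel_tol = rel_tol,
         epsilon_guard = epsilon_guard, cost = cost,
         pg_beta = pg_beta, pg_sigma = pg_sigma, pg_eps = pg_eps,
         pg_max_inner = as.integer(pg_max_inner),
         pnmf_alpha = pnmf_alpha, pnmf_beta = pnmf_beta,
         ridge = ridge, seed = as.integer(seed)),
    class = "amnd_solver_config"
  )
}

#' NMF objective value
#'
#' Squared-Frobenius cost `sum((V - WH)^2)`, generalized Kullback-Leibler
#' divergence `sum(V log(V / WH) - V + WH)` (with `0 log 0 = 0`, and `+Inf`
#' where `WH = 0` but `V > 0`), or the Frobenius-regularized cost
#' `||V - WH||_F^2 + alpha ||W||_F^2 + beta ||H||_F^2`.
#'
#' @param V,W,H Conforming nonnegative matrices.
#' @param kind `"euclidean_sq"`, `"kl"`, or `"pnmf_regularized"`.
#' @param alpha,beta Penalty weights (regularized kind only).
#' @return A single nonnegative number.
#' @export
nmf_objective <- function(V, W, H, kind = c("euclidean_sq", "kl", "pnmf_regularized"),
                          alpha = 0, beta = 0) {
  kind <- match.arg(kind)
  if (nrow(W) != nrow(V) || ncol(H) != ncol(V) || ncol(W) != nrow(H)) {
    stop("shape mismatch between V, W and H")
  }
  WH <- W %*% H
  if (kind == "euclidean_sq") {
    sum((V - WH)^2)
  } else if (kind == "kl") {
    pos <- V > 0
    if (any(pos & WH == 0)) return(Inf)
    term <- numeric(length(V))
    term[pos] <- V[pos] * log(V[pos] / WH[pos])
    sum(term) - sum(V) + sum(WH)
  } else {
    sum((V - WH)^2) + alpha * sum(W^2) + beta * sum(H^2)
  }
}

new_factorization <- function(W, H, solver, trace, converged, cfg) {
  structure(
    list(W = W, H = H, r = ncol(W), objective_trace = trace,
         solver_name = solver, converged = converged,
         iterations = length(trace) - 1L, config = cfg),
    class = "amnd_factorization"
  )
}

#' @export
print.amnd_factorization <- function(x, ...) {
  cat("NMF fit [", x$solver_name, "]: ", nrow(x$W), " x ", ncol(x$H),
      " at rank ", x$r, "; ", x$iterations, " iterations, final objective ",
      format(utils::tail(x$objective_trace, 1L), digits = 6),
      if (x$converged) " (converged)\n" else " (iteration cap)\n", sep = "")
  invisible(x)
}

check_V <- function(V, r) {
  if (!is.matrix(V)) V <- as.matrix(V)
  if (anyNA(V)) stop("V contains missing values")
  if (any(V < 0)) stop("V must be nonnegative")
  if (all(V == 0)) stop("V is identically zero; nothing to factorize")
  if (r >= min(dim(V)) ) stop("rank r must be < min(m, n)")
  if (r < 1L) stop("rank r must be >= 1")
  V
}

resolve_init <- function(V, r, init, cfg, lift_zeros = FALSE) {
  if (is.null(init)) {
    init <- nndsvd(V, r)
  } else if (identical(init, "random")) {
    init <- with_local_seed(cfg$seed, {
      list(W0 = matrix(runif(nrow(V) * r, 0.1, 1) * sqrt(mean(V) / r), nrow(V), r),
           H0 = matrix(runif(r * ncol(V), 0.1, 1) * sqrt(mean(V) / r), r, ncol(V)))
    })
    class(init) <- "amnd_init"
  }
  stopifnot(inherits(init, "amnd_init") || (is.list(init) && !is.null(init$W0)))
  if (lift_zeros) {
    eps <- max(1e-6 * mean(V), .Machine$double.eps)
    init$W0[init$W0 == 0] <- eps
    init$H0[init$H0 == 0] <- eps
  }
  init
}

# shared outer-loop stopping rule on the objective trace
rel_change <- function(prev, cur) {
  abs(prev - cur) / max(abs(prev), .Machine$double.eps)
}

#' NMF by multiplicative updates
#'
#' Lee-Seung multiplicative update iteration for the squared-Frobenius cost
#' (default) or the generalized KL divergence, with an epsilon guard on
#' every denominator so that iterates can never divide by zero.
#'
#' @param V Nonnegative matrix (`m x n`).
#' @param r Factorization rank, `< min(m, n)`.
#' @param init `NULL` for the deterministic NNDSVD start (zeros lifted),
#'   `"random"` for a seeded random start, or an `amnd_init` pair.
#' @param cfg A [solver_config()].
#' @return An `amnd_factorization`.
#' @export
solve_mu <- function(V, r, init = NULL, cfg = solver_config()) {
  V <- check_V(V, r)
  init <- resolve_init(V, r, init, cfg, lift_zeros = TRUE)
  W <- init$W0; H <- init$H0
  eps <- cfg$epsilon_guard
  kind <- if (cfg$cost == "kl") "kl" else "euclidean_sq"
  trace <- nmf_objective(V, W, H, kind)
  converged <- FALSE
  for (it in seq_len(cfg$max_outer_iter)) {
    if (cfg$cost == "euclidean") {
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
      H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
    } else {
      WH <- W %*% H + eps
      W <- W * ((V / WH) %*% t(H)) / (matrix(rowSums(H), nrow(W), r, byrow = TRUE) + eps)
      WH <- W %*% H + eps
      H <- H * crossprod(W, V / WH) / (matrix(colSums(W), r, ncol(H)) + eps)
    }
    trace <- c(trace, nmf_objective(V, W, H, kind))
    if (rel_change(trace[it], trace[it + 1L]) < cfg$rel_tol) { converged <- TRUE; break }
  }
  new_factorization(W, H, "mu", trace, converged, cfg)
}

#' NMF by alternating nonnegative least squares
#'
#' Alternates the two constrained subproblems `min_{H >= 0} ||V - WH||_F^2`
#' and `min_{W >= 0} ||V - WH||_F^2`, each solved exactly per column by an
#' active-set method, so the objective trace is nonincreasing.
#'
#' @inheritParams solve_mu
#' @return An `amnd_factorization`.
#' @export
solve_als <- function(V, r, init = NULL, cfg = solver_config()) {
  als_like(V, r, init, cfg, method = "nnls", name = "als")
}

#' NMF by alternating least squares with optimal-brain-surgery pruning
#'
#' The same alternating scheme as [solve_als()], but each column subproblem
#' handles negativity by Hessian-based pruning: from the unconstrained
#' least-squares solution, the negative coefficient of minimal saliency
#' `x_i^2 / (2 [Q^{-1}]_{ii})` is deleted, the survivors are corrected by
#' `-(x_i / [Q^{-1}]_{ii}) Q^{-1} e_i`, and the deleted coefficient stays
#' at zero; this repeats until no negative coefficients remain.
#'
#' @inheritParams solve_mu
#' @return An `amnd_factorization`.
#' @export
solve_alsobs <- function(V, r, init = NULL, cfg = solver_config()) {
  als_like(V, r, init, cfg, method = "obs", name = "alsobs")
}

als_like <- function(V, r, init, cfg, method, name) {
  V <- check_V(V, r)
  init <- resolve_init(V, r, init, cfg)
  W <- init$W0; H <- init$H0
  if (any(colSums(W) == 0)) {
    # a zero column in W makes the first H-subproblem degenerate
    W[, colSums(W) == 0] <- mean(V) * 1e-6
  }
  trace <- nmf_objective(V, W, H, "euclidean_sq")
  converged <- FALSE
  for (it in seq_len(cfg$max_outer_iter)) {
    H <- nnls_columns(W, V, method = method, ridge = cfg$ridge)
    W <- t(nnls_columns(t(H), t(V), method = method, ridge = cfg$ridge))
    trace <- c(trace, nmf_objective(V, W, H, "euclidean_sq"))
    if (rel_change(trace[it], trace[it + 1L]) < cfg$rel_tol) { converged <- TRUE; break }
  }
  new_factorization(W, H, name, trace, converged, cfg)
}

# Projected-gradient subproblem: minimize f(X) = 0.5 ||B - A X||_F^2 over
# X >= 0, by x_{k+1} = P[x_k - alpha_k grad], alpha_k = beta^t with t = 1, 2,
# ... the first power satisfying the Armijo condition
# f(x_{k+1}) - f(x_k) <= sigma * <grad, x_{k+1} - x_k>. Stops when the
# projected-gradient norm falls below pg_eps times the initial gradient
# norm, or after pg_max_inner steps.
pg_subproblem <- function(AtA, AtB, X, cfg) {
  f_of <- function(X) 0.5 * (sum(X * (AtA %*% X)) - 2 * sum(X * AtB))
  grad_of <- function(X) AtA %*% X - AtB
  g <- grad_of(X)
  g0_norm <- sqrt(sum(g^2))
  if (g0_norm == 0) return(X)
  fX <- f_of(X)
  for (k in seq_len(cfg$pg_max_inner)) {
    pg <- ifelse(X > 0, g, pmin(g, 0))
    if (sqrt(sum(pg^2)) <= cfg$pg_eps * g0_norm) break
    accepted <- FALSE
    alpha <- 1
    for (t in seq_len(60L)) {
      alpha <- cfg$pg_beta^t
      Xn <- pmax(X - alpha * g, 0)
      d <- Xn - X
      fXn <- f_of(Xn)
      if (fXn - fX <= cfg$pg_sigma * sum(g * d)) { accepted <- TRUE; break }
    }
    if (!accepted) break  # no descent step at machine precision
    X <- Xn
    fX <- fXn
    g <- grad_of(X)
    if (!all(is.finite(g))) stop("non-finite gradient in projected-gradient subproblem")
  }
  X
}

#' NMF by alternating projected gradient
#'
#' Alternates projected-gradient solves of the two nonnegativity-constrained
#' subproblems; each inner step projects a gradient step onto the
#' nonnegative orthant with an Armijo backtracking step size
#' `alpha = beta^t`, and each inner solve stops when the projected-gradient
#' norm has dropped by the factor `pg_eps` relative to its start.
#'
#' @inheritParams solve_mu
#' @return An `amnd_factorization`.
#' @export
solve_pg <- function(V, r, init = NULL, cfg = solver_config()) {
  V <- check_V(V, r)
  init <- resolve_init(V, r, init, cfg)
  W <- init$W0; H <- init$H0
  trace <- nmf_objective(V, W, H, "euclidean_sq")
  converged <- FALSE
  for (it in seq_len(cfg$max_outer_iter)) {
    H <- pg_subproblem(crossprod(W), crossprod(W, V), H, cfg)
    Wt <- pg_subproblem(tcrossprod(H), H %*% t(V), t(W), cfg)
    W <- t(Wt)
    trace <- c(trace, nmf_objective(V, W, H, "euclidean_sq"))
    if (rel_change(trace[it], trace[it + 1L]) < cfg$rel_tol) { converged <- TRUE; break }
  }
  new_factorization(W, H, "pg", trace, converged, cfg)
}

#' Frobenius-regularized NMF by multiplicative updates
#'
#' Minimizes `||V - WH||_F^2 + alpha ||W||_F^2 + beta ||H||_F^2` with
#' multiplicative updates whose denominators carry the ridge terms
#' `alpha W` / `beta H`; at `alpha = beta = 0` the update maps coincide
#' exactly with the plain Euclidean multiplicative updates.
#'
#' @inheritParams solve_mu
#' @return An `amnd_factorization`.
#' @export
solve_pnmf <- function(V, r, init = NULL, cfg = solver_config()) {
  V <- check_V(V, r)
  init <- resolve_init(V, r, init, cfg, lift_zeros = TRUE)
  W <- init$W0; H <- init$H0
  eps <- cfg$epsilon_guard
  a <- cfg$pnmf_alpha; b <- cfg$pnmf_beta
  trace <- nmf_objective(V, W, H, "pnmf_regularized", alpha = a, beta = b)
  converged <- FALSE
  for (it in seq_len(cfg$max_outer_iter)) {
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + a * W + eps)
    H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + b * H + eps)
    trace <- c(trace, nmf_objective(V, W, H, "pnmf_regularized", alpha = a, beta = b))
    if (rel_change(trace[it], trace[it + 1L]) < cfg$rel_tol) { converged <- TRUE; break }
  }
  new_factorization(W, H, "pnmf", trace, converged, cfg)
}

#' Run all five NMF solvers from a shared NNDSVD start
#'
#' @param V Nonnegative matrix.
#' @param r Common factorization rank.
#' @param cfg A [solver_config()] shared by all solvers.
#' @return A named list of five `amnd_factorization` objects in the fixed
#'   order `mu`, `als`, `alsobs`, `pg`, `pnmf`.
#' @export
factorize_all <- function(V, r, cfg = solver_config()) {
  V <- check_V(V, r)
  init <- nndsvd(V, r)
  fits <- list(
    mu     = solve_mu(V, r, init = init_lifted(init, V), cfg = cfg),
    als    = solve_als(V, r, init = init, cfg = cfg),
    alsobs = solve_alsobs(V, r, init = init, cfg = cfg),
    pg     = solve_pg(V, r, init = init, cfg = cfg),
    pnmf   = solve_pnmf(V, r, init = init_lifted(init, V), cfg = cfg)
  )
  fits[SOLVER_ORDER]
}

init_lifted <- function(init, V) {
  perturb_zeros(init, eps = max(1e-6 * mean(V), .Machine$double.eps))
}

#' Project new samples onto a fitted coefficient matrix
#'
#' For each new expression row `v`, solves `min_{w >= 0} ||v - w H||^2`
#' with the same exact NNLS subproblem solver used by the ALS variant;
#' this supplies leakage-free features for held-out samples.
#'
#' @param H Coefficient matrix (`r x n`) from a fitted factorization, or an
#'   `amnd_factorization`.
#' @param V_new Nonnegative matrix of new samples (`m_new x n`).
#' @return Nonnegative `m_new x r` matrix of projected features.
#' @export
project_new_samples <- function(H, V_new) {
  if (inherits(H, "amnd_factorization")) H <- H$H
  if (!is.matrix(V_new)) V_new <- matrix(V_new, nrow = 1L)
  if (ncol(V_new) != ncol(H)) {
    stop("V_new has ", ncol(V_new), " columns but H expects ", ncol(H))
  }
  if (any(V_new < 0)) stop("V_new must be nonnegative")
  # rows of W solve NNLS with design t(H)
  t(nnls_columns(t(H), t(V_new), method = "nnls"))
}
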