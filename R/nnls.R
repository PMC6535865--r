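# Internal least-squares machinery for the ALS-family solvers. All routines
# work on the normal equations (Q = A'A [+ ridge], Atb = A'b): the factor
# rank r is small, so dense r x r solves per step are cheap and shared
# across the n (or m) columns of the full subproblem.

# Exact nonnegative least squares, min_{x >= 0} ||b - A x||^2, by the
# Lawson-Hanson active-set method on the normal equations. Q must be
# positive definite (callers add a small ridge).
nnls_solve <- function(Q, Atb, tol = NULL) {
  r <- length(Atb)
  if (is.null(tol)) tol <- 1e-10 * max(abs(Atb), 1)
  x <- numeric(r)
  passive <- logical(r)
  w <- Atb  # negative gradient at x = 0
  outer <- 0L
  while (any(!passive & w > tol)) {
    outer <- outer + 1L
    if (outer > 10L * r + 50L) break  # safety; LH terminates in theory
    cand <- w
    cand[passive] <- -Inf
    passive[which.max(cand)] <- TRUE
    repeat {
      P <- which(passive)
      s <- numeric(r)
      s[P] <- solve(Q[P, P, drop = FALSE], Atb[P])
      if (all(s[P] > -tol)) {
        x <- pmax(s, 0)
        break
      }
      neg <- P[s[P] <= 0]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      drop_ <- passive & (x <= tol)
      passive[drop_] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) break
    }
    w <- Atb - as.numeric(Q %*% x)
  }
  x
}

# One column subproblem solved by optimal-brain-surgery elimination: start
# from the unconstrained solution; while negative coefficients remain,
# delete the one of minimal saliency L_i = x_i^2 / (2 [Q^-1]_ii), correct
# the survivors by dx = -(x_i / [Q^-1]_ii) Q^-1 e_i (which pins coordinate
# i at exactly 0), and never let a deleted coefficient re-enter.
obs_solve <- function(Q, Atb) {
  r <- length(Atb)
  alive <- rep(TRUE, r)
  Qinv <- solve(Q)
  xs <- as.numeric(Qinv %*% Atb)
  while (length(xs) > 0L) {
    neg <- which(xs < -1e-12)
    if (length(neg) == 0L) break
    dinv <- diag(Qinv)
    if (is.null(dim(Qinv))) dinv <- Qinv  # 1x1 case
    sal <- xs[neg]^2 / (2 * dinv[neg])
    i <- neg[which.min(sal)]
    orig <- which(alive)
    alive[orig[i]] <- FALSE
    if (sum(alive) == 0L) { xs <- numeric(0); break }
    # the OBS correction equals the re-optimized quadratic on the surviving
    # set; recompute directly to avoid accumulation of roundoff
    Qs <- Q[alive, alive, drop = FALSE]
    Qinv <- solve(Qs)
    xs <- as.numeric(Qinv %*% Atb[alive])
  }
  x <- numeric(r)
  if (any(alive)) x[alive] <- pmax(xs, 0)
  x
}

# Solve min_{H >= 0} ||V - W H||_F^2 column-by-column. method "nnls" uses
# Lawson-Hanson (exact NNLS); "obs" uses the elimination scheme above.
# Columns whose unconstrained solution is already nonnegative are
# batch-solved in one call.
nnls_columns <- function(W, V, method = c("nnls", "obs"), ridge = 1e-10) {
  method <- match.arg(method)
  r <- ncol(W)
  AtA <- crossprod(W)
  scale <- mean(diag(AtA))
  if (!is.finite(scale) || scale <= 0) stop("factor has zero columns; subproblem degenerate")
  Q <- AtA + diag(ridge * scale, r)
  AtB <- crossprod(W, V)
  H <- tryCatch(solve(Q, AtB), error = function(e) {
    stop("least-squares subproblem is rank deficient even after ridge")
  })
  bad <- which(colSums(H < 0) > 0L)
  for (u in bad) {
    H[, u] <- if (method == "nnls") nnls_solve(Q, AtB[, u]) else obs_solve(Q, AtB[, u])
  }
  H[H < 0] <- 0
  H
}
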