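# Independent oracles and fixture builders shared across tests. The oracles
# are deliberately naive (enumeration, pairwise counting) and never call the
# code paths they check.

# Exhaustive active-set NNLS: enumerate every zero-set, solve the
# unconstrained LS on the complement, keep the best feasible solution.
# Only usable for small d.
brute_force_nnls <- function(A, b) {
  d <- ncol(A)
  best <- NULL
  best_obj <- Inf
  for (mask in 0:(2^d - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(d) - 1L)) > 0L)
    x <- numeric(d)
    if (length(free) > 0L) {
      Af <- A[, free, drop = FALSE]
      sol <- tryCatch(qr.solve(Af, b), error = function(e) NULL)
      if (is.null(sol)) next
      x[free] <- sol
    }
    if (any(x < -1e-9)) next
    obj <- sum((b - A %*% x)^2)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best <- x
    }
  }
  best
}

# Pairwise Mann-Whitney AUC with ties counted 0.5.
brute_force_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Random nonnegative matrix.
rand_nonneg <- function(m, n, seed) {
  set.seed(seed)
  matrix(runif(m * n, 0, 1), m, n)
}

# A small synthetic feature stack (five m x r matrices) without running NMF.
make_stack <- function(m, r, seed = 1, normalize = FALSE) {
  set.seed(seed)
  mats <- stats::setNames(
    lapply(1:5, function(j) matrix(runif(m * r), m, r)),
    c("mu", "als", "alsobs", "pg", "pnmf"))
  feature_stack(mats, normalize = normalize)
}

# Rank-1 residual of the best rank-1 approximation (Eckart-Young): for a
# positive matrix the nonnegative rank-1 NMF optimum coincides with the
# leading SVD pair (Perron-Frobenius), so sqrt(min objective) equals the
# second singular value for a 2-column matrix, and more generally
# sqrt(sum_{i>=2} sigma_i^2).
svd_rank1_residual <- function(V) {
  s <- svd(V)$d
  sqrt(sum(s[-1L]^2))
}

# Tiny cohort written to a temporary directory; returns the dir.
write_tiny_cohort <- function(dir, m = 60, n = 30, seed = 5) {
  cfg <- cohort_config(m = m, n = n, d_c = 6L, r0 = 3L, noise_sd = 0.05,
                       clinical_signal = 0.5, seed = seed)
  co <- generate_synthetic_cohort(cfg)
  write_cohort(co, dir)
  co
}

expect_no_neg <- function(M, tol = 0) {
  expect_gte(min(M), -tol)
}
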