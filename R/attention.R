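#' Stack the five solvers' per-sample feature vectors
#'
#' Row `i` of each solver's `W` is sample `i`'s feature vector. The stack
#' keeps the five `m x r` matrices in the fixed solver order `mu`, `als`,
#' `alsobs`, `pg`, `pnmf`. By default each solver's features are min-max
#' normalized per column so the five branches live on a common `[0, 1]`
#' scale before fusion (raw `W` magnitudes differ across solvers).
#'
#' @param fits A named list of five `amnd_factorization`s, as returned by
#'   [factorize_all()], or a named list of five `m x r` matrices.
#' @param normalize Min-max normalize each solver's columns to `[0, 1]`
#'   (default `TRUE`).
#' @param ref Optional row indices (e.g. the training split) whose min/max
#'   define the normalization.
#' @return A list of class `amnd_stack`: `mats` (named list of five `m x r`
#'   matrices), `m`, `r`.
#' @export
feature_stack <- function(fits, normalize = TRUE, ref = NULL) {
  if (!all(SOLVER_ORDER %in% names(fits))) {
    stop("fits must be named by the five solvers: ", paste(SOLVER_ORDER, collapse = ", "))
  }
  mats <- lapply(fits[SOLVER_ORDER], function(f) {
    M <- if (inherits(f, "amnd_factorization")) f$W else f
    if (!is.matrix(M)) stop("each stack entry must be a matrix or factorization")
    M
  })
  dims <- vapply(mats, dim, integer(2L))
  if (length(unique(dims[1L, ])) != 1L || length(unique(dims[2L, ])) != 1L) {
    stop("all five feature matrices must share the same shape")
  }
  if (normalize) mats <- lapply(mats, minmax_normalize, ref = ref)
  structure(list(mats = mats, m = dims[1L, 1L], r = dims[2L, 1L]),
            class = "amnd_stack")
}

#' Bilinear attention scores
#'
#' For sample `i` and solver `j`, the raw score is the bilinear form
#' `w[i, j] = f_j(i)' X c(i)` between the solver's feature vector and the
#' sample's clinical vector, through the trainable `r x d_c` matrix `X`.
#'
#' @param stack An [feature_stack()].
#' @param clinical `m x d_c` clinical matrix, samples aligned with the
#'   stack.
#' @param X Numeric `r x d_c` weight matrix.
#' @return An `m x 5` matrix of raw scores, columns in solver order.
#' @export
attention_raw_weights <- function(stack, clinical, X) {
  stopifnot(inherits(stack, "amnd_stack"))
  clinical <- as.matrix(clinical)
  if (nrow(clinical) != stack$m) stop("clinical rows must match the stack's samples")
  if (!all(dim(X) == c(stack$r, ncol(clinical)))) {
    stop("X must be r x d_c = ", stack$r, " x ", ncol(clinical))
  }
  Z <- clinical %*% t(X)  # m x r; row i = X c(i)
  raw <- vapply(stack$mats, function(Wj) rowSums(Wj * Z), numeric(stack$m))
  if (stack$m == 1L) raw <- matrix(raw, 1L)
  colnames(raw) <- SOLVER_ORDER
  raw
}

#' Row-wise softmax normalization of attention scores
#'
#' Computed with row-max subtraction for overflow safety; each row of the
#' result is strictly positive and sums to 1.
#'
#' @param raw Matrix of finite raw scores (samples x branches).
#' @return Matrix of the same shape with rows on the probability simplex.
#' @export
attention_normalize <- function(raw) {
  raw <- as.matrix(raw)
  if (!all(is.finite(raw))) stop("raw attention scores must be finite")
  shifted <- raw - apply(raw, 1L, max)
  e <- exp(shifted)
  e / rowSums(e)
}

#' Fuse the stacked features with attention weights
#'
#' Per sample, the fused vector is the convex combination
#' `F(i) = sum_j what[i, j] f_j(i)` of the five solver feature vectors.
#'
#' @param stack An [feature_stack()].
#' @param what `m x 5` matrix of normalized weights (rows sum to 1).
#' @return An `m x r` fused feature matrix.
#' @export
attention_fuse <- function(stack, what) {
  stopifnot(inherits(stack, "amnd_stack"))
  what <- as.matrix(what)
  if (!all(dim(what) == c(stack$m, 5L))) stop("weights must be m x 5")
  if (max(abs(rowSums(what) - 1)) > 1e-9) stop("weight rows must sum to 1")
  F <- matrix(0, stack$m, stack$r)
  for (j in seq_along(stack$mats)) {
    F <- F + what[, j] * stack$mats[[j]]
  }
  dimnames(F) <- dimnames(stack$mats[[1L]])
  F
}

#' Concatenate fused features with clinical covariates
#'
#' @param F `m x r` fused feature matrix.
#' @param clinical `m x d_c` clinical matrix; when both carry rownames they
#'   must agree.
#' @return An `m x (r + d_c)` matrix, fused features first.
#' @export
concat_clinical <- function(F, clinical) {
  F <- as.matrix(F); clinical <- as.matrix(clinical)
  if (nrow(F) != nrow(clinical)) stop("sample counts differ")
  if (!is.null(rownames(F)) && !is.null(rownames(clinical)) &&
      !identical(rownames(F), rownames(clinical))) {
    stop("sample IDs of fused features and clinical matrix are misaligned")
  }
  cbind(F, clinical)
}
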