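#' Nonnegative double singular value decomposition (NNDSVD) initialization
#'
#' Deterministic SVD-based starting point shared by all five NMF solvers.
#' The leading singular triplet is nonnegative after sign canonicalization
#' (Perron-Frobenius); each later rank-1 term `sigma_j m_j n_j'` is split
#' into its positive and negative sections and the section with the larger
#' mass supplies that component's factors.
#'
#' @param V Nonnegative numeric matrix (`m x n`).
#' @param r Target rank, `1 <= r <= min(m, n)`.
#' @param scaling `"sqrt"` (default) distributes `sqrt(sigma_j)` to both
#'   factors so that `W0 %*% H0` approximates `V`; `"sigma"` places
#'   `sigma_j` on both sides.
#' @return A list of class `amnd_init` with nonnegative `W0` (`m x r`),
#'   `H0` (`r x n`) and `singular_values` (length `r`), columns of `W0`
#'   ordered by descending singular value.
#' @export
nndsvd <- function(V, r, scaling = c("sqrt", "sigma")) {
  scaling <- match.arg(scaling)
  if (!is.matrix(V)) V <- as.matrix(V)
  if (any(V < 0)) stop("V must be nonnegative")
  m <- nrow(V); n <- ncol(V)
  if (r < 1L || r > min(m, n)) stop("r must satisfy 1 <= r <= min(m, n)")
  sv <- svd(V, nu = r, nv = r)
  W0 <- matrix(0, m, r)
  H0 <- matrix(0, r, n)
  sig <- sv$d[seq_len(r)]
  fac <- function(s) if (scaling == "sqrt") sqrt(s) else s

  for (j in seq_len(r)) {
    u <- sv$u[, j]; v <- sv$v[, j]
    if (j == 1L) {
      # canonicalize the SVD sign ambiguity: leading pair is nonnegative up
      # to a global sign
      if (sum(u) < 0) { u <- -u; v <- -v }
      W0[, 1L] <- fac(sig[1L]) * pmax(u, 0)
      H0[1L, ] <- fac(sig[1L]) * pmax(v, 0)
    } else {
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
      nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
      mp <- nup * nvp  # mass of the positive section of sigma*u*v'
      mn <- nun * nvn
      if (mp >= mn && mp > 0) {
        W0[, j] <- fac(sig[j] * mp) * up / nup
        H0[j, ] <- fac(sig[j] * mp) * vp / nvp
      } else if (mn > 0) {
        W0[, j] <- fac(sig[j] * mn) * un / nun
        H0[j, ] <- fac(sig[j] * mn) * vn / nvn
      }
      # both sections empty only for a zero singular value: leave zeros
    }
  }
  structure(list(W0 = W0, H0 = H0, singular_values = sig),
            class = "amnd_init")
}

#' Replace exact zeros in an initialization pair
#'
#' Multiplicative solvers cannot move an entry off an exact zero, so the
#' zeros of an NNDSVD pair are lifted to a small positive value before those
#' solvers run.
#'
#' @param init An `amnd_init` pair.
#' @param eps Positive replacement value; default `1e-6 * mean` of the
#'   nonzero entries of `W0`/`H0` scale proxy `mean(c(W0, H0))`, bounded
#'   below by `.Machine$double.eps`.
#' @return The modified `amnd_init`.
#' @export
perturb_zeros <- function(init, eps = NULL) {
  stopifnot(inherits(init, "amnd_init"))
  if (is.null(eps)) {
    eps <- max(1e-6 * mean(c(init$W0, init$H0)), .Machine$double.eps)
  }
  if (eps <= 0) stop("eps must be positive")
  init$W0[init$W0 == 0] <- eps
  init$H0[init$H0 == 0] <- eps
  init
}
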