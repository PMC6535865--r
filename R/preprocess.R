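#' Dichotomize survival times at a year threshold
#'
#' Patients surviving at least `threshold` years are long-term survivors
#' (label 1); the rest are short-term (label 0). The boundary case
#' `time == threshold` counts as long-term.
#'
#' @param times Nonnegative numeric vector of survival times in years.
#' @param threshold Positive threshold in years (default 5).
#' @return Integer 0/1 vector, names preserved.
#' @export
label_by_threshold <- function(times, threshold = 5) {
  if (anyNA(times)) stop("survival times contain missing values")
  if (!is.numeric(times) || any(times < 0)) stop("survival times must be nonnegative numbers")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a single positive number of years")
  }
  out <- as.integer(times >= threshold)
  names(out) <- names(times)
  out
}

#' Min-max normalize columns to [0, 1]
#'
#' Each column is mapped by `(x - min) / (max - min)`. Constant columns map
#' to 0. With `ref` supplied, the minima/maxima are taken from the reference
#' rows only (e.g. the training split) and the transform is applied to all
#' rows, clipped back into `[0, 1]`; this is the leakage-free mode. Without
#' `ref` the statistics come from the whole matrix ("global" mode).
#'
#' @param M Numeric matrix without missing values.
#' @param ref Optional integer vector of row indices whose min/max define the
#'   transform.
#' @return A matrix of the same shape with all entries in `[0, 1]`.
#' @export
minmax_normalize <- function(M, ref = NULL) {
  if (!is.matrix(M)) M <- as.matrix(M)
  if (anyNA(M)) stop("matrix contains missing values")
  sub <- if (is.null(ref)) M else M[ref, , drop = FALSE]
  lo <- apply(sub, 2L, min)
  hi <- apply(sub, 2L, max)
  rng <- hi - lo
  out <- sweep(M, 2L, lo, "-")
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, rng[nz], "/")
  out[, !nz] <- 0
  # reference-based stats can push held-out rows outside [0, 1]
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Stratified 80/10/10 train/validation/test split
#'
#' Within each class, `round(0.1 * class size)` samples go to validation and
#' the same number to test; the remainder trains. Membership is a uniformly
#' random within-class permutation driven by `seed`.
#'
#' @param labels 0/1 vector (one per sample).
#' @param seed Integer seed; the split is a pure function of `labels` and
#'   `seed`.
#' @param fractions Split fractions, kept at `c(0.8, 0.1, 0.1)`; validation
#'   and test sizes are `round(fractions[2] * class size)` per class.
#' @return An object of class `amnd_split`: list with integer index vectors
#'   `train_idx`, `val_idx`, `test_idx`, plus `fractions` and `seed`.
#' @export
stratified_split <- function(labels, seed = 1L, fractions = c(0.8, 0.1, 0.1)) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be three numbers summing to 1")
  }
  n <- length(labels)
  train <- integer(0); val <- integer(0); test <- integer(0)
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    m_c <- length(idx)
    k <- round(fractions[2L] * m_c)
    if (k < 1L) stop("class ", cls, " has too few samples (", m_c,
                     ") for a nonempty validation/test part")
    # independent shuffle per class; caller's RNG stream untouched
    perm <- with_local_seed(seed + cls, sample(idx, m_c))
    val <- c(val, perm[seq_len(k)])
    test <- c(test, perm[k + seq_len(k)])
    train <- c(train, perm[-seq_len(2L * k)])
  }
  structure(
    list(train_idx = sort(train), val_idx = sort(val), test_idx = sort(test),
         fractions = fractions, seed = as.integer(seed)),
    class = "amnd_split"
  )
}

#' @export
print.amnd_split <- function(x, ...) {
  cat("amnd stratified split (seed ", x$seed, "): train ",
      length(x$train_idx), " / val ", length(x$val_idx), " / test ",
      length(x$test_idx), "\n", sep = "")
  invisible(x)
}

# Save/restore .Random.seed so seeded helpers do not disturb the caller's RNG
# stream.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Run expr with a local, restored-after RNG state.
with_local_seed <- function(seed, expr) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  expr
}
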