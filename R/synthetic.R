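#' Configuration for a synthetic multimodal cohort
#'
#' Defaults mirror a large breast-cancer prognosis cohort: 1980 patients,
#' a post-selection expression panel of 1000 genes with planted low-rank
#' structure, 25 clinical covariates scaled to `[0, 1]`, and an imbalanced
#' outcome with about 24.8% short-term survivors.
#'
#' @param m Number of samples.
#' @param n Number of genes.
#' @param d_c Number of clinical features.
#' @param r0 Planted latent rank of the expression matrix.
#' @param noise_sd Standard deviation of the additive Gaussian noise on the
#'   expression matrix (clipped at 0).
#' @param class_balance Expected fraction of short-term survivors (label 0),
#'   in (0, 1).
#' @param clinical_signal In `[0, 1]`; 0 makes every clinical column pure
#'   noise and removes the clinical term from the outcome model, 1 makes all
#'   columns informative.
#' @param seed Integer seed; the cohort is a pure function of the config.
#' @return A list of class `amnd_cohort_config`.
#' @export
cohort_config <- function(m = 1980L, n = 1000L, d_c = 25L, r0 = 10L,
                          noise_sd = 0.1, class_balance = 491 / 1980,
                          clinical_signal = 0.5, seed = 1L) {
  cfg <- list(m = as.integer(m), n = as.integer(n), d_c = as.integer(d_c),
              r0 = as.integer(r0), noise_sd = noise_sd,
              class_balance = class_balance,
              clinical_signal = clinical_signal, seed = as.integer(seed))
  if (cfg$m <= 0L || cfg$n <= 0L || cfg$d_c <= 0L) stop("m, n, d_c must be positive")
  if (cfg$r0 <= 0L || cfg$r0 >= cfg$n) stop("latent rank r0 must satisfy 0 < r0 < n")
  if (cfg$noise_sd < 0) stop("noise_sd must be nonnegative")
  if (cfg$class_balance <= 0 || cfg$class_balance >= 1) stop("class_balance must lie in (0, 1)")
  if (cfg$clinical_signal < 0 || cfg$clinical_signal > 1) stop("clinical_signal must lie in [0, 1]")
  class(cfg) <- "amnd_cohort_config"
  cfg
}

#' Generate a synthetic expression + clinical + survival cohort
#'
#' The expression matrix is `clip(W0 H0 + noise, 0)` with nonnegative planted
#' factors of rank `r0`. A per-sample molecular score (a fixed combination of
#' the planted factors) and an independent clinical factor drive both the
#' informative clinical columns and the outcome: the label is Bernoulli in a
#' logistic model whose intercept is calibrated so the expected long-term
#' fraction equals `1 - class_balance`. Survival times consistent with the
#' labels at the 5-year threshold are emitted as well.
#'
#' @param cfg An [cohort_config()] object (or arguments forwarded to it).
#' @param ... Used to build a config when `cfg` is missing.
#' @return A list of class `amnd_cohort` with elements `expression`
#'   (nonnegative `m x n` matrix), `clinical` (`m x d_c` matrix in `[0, 1]`),
#'   `labels` (named 0/1 vector), `times` (named numeric, years), and
#'   `config`.
#' @export
generate_synthetic_cohort <- function(cfg = cohort_config(...), ...) {
  stopifnot(inherits(cfg, "amnd_cohort_config"))
  with_local_seed(cfg$seed, {
    m <- cfg$m; n <- cfg$n; d_c <- cfg$d_c; r0 <- cfg$r0
    sample_ids <- sprintf("S%04d", seq_len(m))

    # planted nonnegative factors; gamma(2, 2) gives right-skewed positive
    # loadings typical of expression components
    W0 <- matrix(rgamma(m * r0, shape = 2, rate = 2), m, r0)
    H0 <- matrix(rgamma(r0 * n, shape = 2, rate = 2), r0, n)
    V <- W0 %*% H0
    if (cfg$noise_sd > 0) V <- V + matrix(rnorm(m * n, sd = cfg$noise_sd), m, n)
    V <- pmax(V, 0)
    dimnames(V) <- list(sample_ids, sprintf("G%05d", seq_len(n)))

    # molecular score: fixed combination of planted factors, standardized
    beta <- rnorm(r0)
    z_raw <- as.numeric(W0 %*% beta)
    if (sd(z_raw) == 0) stop("degenerate molecular signal; cannot calibrate outcome model")
    z <- (z_raw - mean(z_raw)) / sd(z_raw)
    # clinical factor independent of the expression data
    u <- rnorm(m)

    # informative clinical columns reflect mostly the clinical factor u with
    # a weak echo of the molecular score, behind substantial measurement
    # noise: clinically recorded covariates are coarser than the molecular
    # profile, so the expression route carries more outcome information
    # than the clinical route, with the clinical factor complementary
    n_info <- round(cfg$clinical_signal * d_c)
    C <- matrix(0, m, d_c,
                dimnames = list(sample_ids, sprintf("clin_%02d", seq_len(d_c))))
    for (j in seq_len(d_c)) {
      if (j <= n_info) {
        a <- runif(1, 0, 0.3); b <- runif(1, 0.3, 0.8)
        C[, j] <- a * z + b * u + rnorm(m, sd = 0.8)
      } else {
        C[, j] <- rnorm(m)
      }
    }
    C <- minmax_normalize(C)

    # outcome: logistic in the molecular score plus (scaled) clinical factor
    gamma_u <- 1.2 * cfg$clinical_signal
    eta0 <- 1.6 * z + gamma_u * u
    target <- 1 - cfg$class_balance  # expected long-term fraction
    f <- function(b0) mean(stats::plogis(b0 + eta0)) - target
    lo <- -20; hi <- 20
    if (f(lo) > 0 || f(hi) < 0) stop("cannot calibrate intercept for requested class balance")
    b0 <- uniroot(f, c(lo, hi), tol = 1e-10)$root
    p <- stats::plogis(b0 + eta0)
    labels <- rbinom(m, 1L, p)
    names(labels) <- sample_ids

    # survival times consistent with the 5-year dichotomy
    times <- ifelse(labels == 1L, 5 + rexp(m, rate = 1 / 3), runif(m, 0, 5))
    # runif(0,5) can in principle hit 5 exactly only with probability 0
    names(times) <- sample_ids

    structure(
      list(expression = V, clinical = C, labels = labels, times = times,
           config = cfg),
      class = "amnd_cohort"
    )
  })
}

#' @export
print.amnd_cohort <- function(x, ...) {
  cat("amnd synthetic cohort: ", nrow(x$expression), " samples x ",
      ncol(x$expression), " genes, ", ncol(x$clinical),
      " clinical features; ", sum(x$labels == 1L), " long-term / ",
      sum(x$labels == 0L), " short-term (seed ", x$config$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Write a cohort to disk as delimited text plus a JSON config sidecar
#'
#' Emits `expression.tsv`, `clinical.tsv`, `labels.tsv` and `config.json`
#' in `dir`.
#'
#' @param cohort An `amnd_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "amnd_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(cohort$expression, file.path(dir, "expression.tsv"))
  write_matrix(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_labels(cohort$labels, file.path(dir, "labels.tsv"), times = cohort$times)
  jsonlite::write_json(unclass(cohort$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `expression.tsv`, `clinical.tsv`,
#'   `labels.tsv` (and optionally `config.json`).
#' @return An `amnd_cohort` (with `config = NULL` if no sidecar is present).
#' @export
read_cohort <- function(dir) {
  V <- read_matrix(file.path(dir, "expression.tsv"), "expression")
  C <- read_matrix(file.path(dir, "clinical.tsv"), "clinical")
  lab <- read_labels(file.path(dir, "labels.tsv"))
  if (!identical(rownames(V), rownames(C)) ||
      !identical(rownames(V), lab$sample_ids)) {
    stop("sample IDs disagree across expression, clinical and labels files")
  }
  cfg_path <- file.path(dir, "config.json")
  cfg <- NULL
  if (file.exists(cfg_path)) {
    cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    cfg <- do.call(cohort_config, cfg)
  }
  structure(
    list(expression = V, clinical = C, labels = lab$labels, times = lab$times,
         config = cfg),
    class = "amnd_cohort"
  )
}
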