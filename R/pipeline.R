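#' Run the full fusion pipeline on one split
#'
#' Normalizes both modalities to `[0, 1]`, factorizes the expression matrix
#' with all five solvers from a shared NNDSVD start, stacks and fuses the
#' features, trains the requested variant on the training part of a
#' stratified split, and evaluates on the test part.
#'
#' Normalization and feature-stack scaling use either the whole cohort
#' (`normalization = "global"`, mirroring a single up-front preprocessing
#' pass) or training-split statistics only (`"train"`, the leakage-hygienic
#' default).
#'
#' @param expression Nonnegative `m x n` expression matrix.
#' @param clinical `m x d_c` clinical matrix.
#' @param labels 0/1 vector of length `m`.
#' @param r Factorization rank.
#' @param split_seed Seed of the stratified split.
#' @param solver_cfg A [solver_config()].
#' @param model_cfg An [model_config()].
#' @param normalization `"train"` or `"global"`.
#' @param stack Optional precomputed [feature_stack()]; skips
#'   factorization (useful when several variants share one stack).
#' @return A list of class `amnd_run`: `stack`, `split`, `model`,
#'   `predictions` (test part), `metrics` (one-row tibble), `roc`.
#' @export
amnd_run <- function(expression, clinical, labels, r = 200L, split_seed = 1L,
                     solver_cfg = solver_config(), model_cfg = model_config(),
                     normalization = c("train", "global"), stack = NULL) {
  normalization <- match.arg(normalization)
  labels <- as.integer(labels)
  split <- stratified_split(labels, seed = split_seed)
  ref <- if (normalization == "train") split$train_idx else NULL
  if (is.null(stack)) {
    V <- minmax_normalize(expression, ref = ref)
    fits <- factorize_all(V, r, cfg = solver_cfg)
    stack <- feature_stack(fits, normalize = TRUE, ref = ref)
  }
  C <- minmax_normalize(clinical, ref = ref)
  model <- amnd_train(stack, C, labels, split, model_cfg)
  pred <- amnd_predict(model, stack, C, idx = split$test_idx)
  metrics <- evaluate_predictions(labels[split$test_idx], pred$probability)
  roc <- roc_auc(labels[split$test_idx], pred$probability)
  structure(list(stack = stack, split = split, model = model,
                 predictions = pred, metrics = metrics, roc = roc,
                 clinical = C, labels = labels),
            class = "amnd_run")
}

#' @export
print.amnd_run <- function(x, ...) {
  cat("amnd run [", x$model$config$variant, "]\n", sep = "")
  print(x$metrics)
  invisible(x)
}
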