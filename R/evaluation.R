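#' Confusion-matrix metrics at a fixed threshold
#'
#' Accuracy, precision, recall and F1 with positive class = label 1
#' (long-term survival). With no predicted positives, precision (and hence
#' F1) is reported as 0 and the result is flagged.
#'
#' @param labels 0/1 truth vector.
#' @param predictions 0/1 predicted-label vector of the same length.
#' @return A list of class `amnd_metrics`: `acc`, `pre`, `recall`, `f1`,
#'   `n_pos`, `n_neg`, `undefined_precision` flag.
#' @export
confusion_metrics <- function(labels, predictions) {
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  if (length(labels) != length(predictions)) stop("length mismatch")
  if (!all(labels %in% c(0L, 1L)) || !all(predictions %in% c(0L, 1L))) {
    stop("labels and predictions must be 0/1")
  }
  if (sum(labels == 1L) == 0L) stop("no positive samples in labels")
  tp <- sum(labels == 1L & predictions == 1L)
  fp <- sum(labels == 0L & predictions == 1L)
  fn <- sum(labels == 1L & predictions == 0L)
  tn <- sum(labels == 0L & predictions == 0L)
  acc <- (tp + tn) / length(labels)
  undef <- (tp + fp) == 0L
  if (undef) warning("no predicted positives; precision reported as 0")
  pre <- if (undef) 0 else tp / (tp + fp)
  rec <- tp / (tp + fn)
  f1 <- if (pre + rec == 0) 0 else 2 * pre * rec / (pre + rec)
  structure(list(acc = acc, pre = pre, recall = rec, f1 = f1,
                 n_pos = sum(labels == 1L), n_neg = sum(labels == 0L),
                 undefined_precision = undef),
            class = "amnd_metrics")
}

#' ROC curve and AUC
#'
#' The ROC is swept over all distinct score thresholds; the AUC is the
#' Mann-Whitney concordance probability (midranks, so ties count 0.5),
#' which equals the trapezoidal area under the swept curve.
#'
#' @param labels 0/1 truth vector with both classes present.
#' @param scores Real-valued scores, larger = more positive.
#' @return A list of class `amnd_roc`: `auc` plus `roc_points`, a tibble
#'   with columns `fpr`, `tpr` running from (0, 0) to (1, 1).
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stop("length mismatch")
  if (anyNA(scores) || !is.numeric(scores)) stop("scores must be numeric and non-missing")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  # midrank Mann-Whitney
  rk <- rank(scores, ties.method = "average")
  auc <- (sum(rk[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # threshold sweep over distinct scores, descending
  ord <- order(scores, decreasing = TRUE)
  ys <- labels[ord]; ss <- scores[ord]
  keep <- c(diff(ss) != 0, TRUE)  # last index of each tie group
  tp <- cumsum(ys)[keep]
  fp <- cumsum(1L - ys)[keep]
  roc <- tibble::tibble(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  structure(list(auc = auc, roc_points = roc, n_pos = n_pos, n_neg = n_neg),
            class = "amnd_roc")
}

#' @export
print.amnd_roc <- function(x, ...) {
  cat("ROC over ", x$n_pos, " positives / ", x$n_neg, " negatives: AUC = ",
      format(x$auc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Evaluate a prediction set on one split
#'
#' @param labels 0/1 truth vector for the scored samples.
#' @param probs Predicted probabilities.
#' @param threshold Decision threshold for the confusion metrics.
#' @return A one-row tibble: `auc`, `acc`, `pre`, `recall`, `f1`, `n_pos`,
#'   `n_neg`.
#' @export
evaluate_predictions <- function(labels, probs, threshold = 0.5) {
  roc <- roc_auc(labels, probs)
  cm <- confusion_metrics(labels, as.integer(probs >= threshold))
  tibble::tibble(auc = roc$auc, acc = cm$acc, pre = cm$pre,
                 recall = cm$recall, f1 = cm$f1,
                 n_pos = cm$n_pos, n_neg = cm$n_neg)
}

#' Repeated-repartition experiment
#'
#' Re-splits the cohort `n_repeats` times (seeds `base_seed + 1 ..
#' base_seed + n_repeats`), trains the configured variant on each training
#' part and evaluates on the matching test part, mirroring the repeated
#' repartitioning protocol; factorizations are computed once and reused
#' across repeats. Failed repeats are recorded and excluded from the
#' aggregate.
#'
#' @param stack An [feature_stack()] (or `NULL` for `only_clinical`).
#' @param clinical Clinical matrix (or `NULL` for `only_exp`).
#' @param labels 0/1 vector.
#' @param cfg An [model_config()]; its `seed` is re-derived per repeat.
#' @param n_repeats Number of repartitions (the full protocol uses 100).
#' @param base_seed Base seed for the split/training sequence.
#' @return A list of class `amnd_repeat_report`: `per_repeat` tibble (one
#'   row per successful repeat), `summary` tibble of means and SDs,
#'   `failures` (character), `n_repeats`, `base_seed`, `variant`.
#' @export
repeat_experiment <- function(stack, clinical, labels, cfg = model_config(),
                              n_repeats = 100L, base_seed = 0L) {
  stopifnot(n_repeats >= 1L)
  labels <- as.integer(labels)
  rows <- vector("list", n_repeats)
  failures <- character(0)
  for (k in seq_len(n_repeats)) {
    seed_k <- base_seed + k
    res <- tryCatch({
      split <- stratified_split(labels, seed = seed_k)
      cfg_k <- cfg
      cfg_k$seed <- as.integer(seed_k)
      model <- amnd_train(stack, clinical, labels, split, cfg_k)
      te <- split$test_idx
      pred <- amnd_predict(model, stack, clinical, idx = te)
      cbind(tibble::tibble(repeat_id = k, seed = seed_k,
                           best_epoch = model$best_epoch),
            evaluate_predictions(labels[te], pred$probability))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("repeat %d: %s", k, conditionMessage(res)))
    } else {
      rows[[k]] <- res
    }
  }
  per_repeat <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(per_repeat) || nrow(per_repeat) == 0L) {
    stop("every repeat failed; first failure: ", failures[1L])
  }
  per_repeat <- tibble::as_tibble(per_repeat)
  metrics <- c("auc", "acc", "pre", "recall", "f1")
  summary <- tibble::tibble(
    metric = metrics,
    mean = unname(vapply(metrics, function(mn) mean(per_repeat[[mn]]), numeric(1L))),
    sd = unname(vapply(metrics, function(mn) sd(per_repeat[[mn]]), numeric(1L)))
  )
  structure(
    list(per_repeat = per_repeat, summary = summary, failures = failures,
         n_repeats = n_repeats, base_seed = base_seed, variant = cfg$variant),
    class = "amnd_repeat_report"
  )
}

#' @export
print.amnd_repeat_report <- function(x, ...) {
  cat("repeated-split report [", x$variant, "]: ", nrow(x$per_repeat), "/",
      x$n_repeats, " repeats\n", sep = "")
  print(x$summary)
  if (length(x$failures)) cat(length(x$failures), "failures recorded\n")
  invisible(x)
}
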