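#' Tidy the objective trace of a factorization
#'
#' @param x An `amnd_factorization`.
#' @param ... Unused.
#' @return A tibble with columns `iteration` (0 = initialization) and
#'   `objective`.
#' @method tidy amnd_factorization
#' @export
tidy.amnd_factorization <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$objective_trace) - 1L,
                 objective = x$objective_trace)
}

#' One-row summary of a factorization
#'
#' @param x An `amnd_factorization`.
#' @param ... Unused.
#' @return A one-row tibble: `solver`, `rank`, `iterations`, `converged`,
#'   `objective`.
#' @method glance amnd_factorization
#' @export
glance.amnd_factorization <- function(x, ...) {
  tibble::tibble(solver = x$solver_name, rank = x$r,
                 iterations = x$iterations, converged = x$converged,
                 objective = utils::tail(x$objective_trace, 1L))
}

#' Tidy ROC points
#'
#' @param x An `amnd_roc`.
#' @param ... Unused.
#' @return The `(fpr, tpr)` tibble.
#' @method tidy amnd_roc
#' @export
tidy.amnd_roc <- function(x, ...) x$roc_points

#' One-row AUC summary
#'
#' @param x An `amnd_roc`.
#' @param ... Unused.
#' @return A one-row tibble: `auc`, `n_pos`, `n_neg`.
#' @method glance amnd_roc
#' @export
glance.amnd_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy confusion metrics into metric/value rows
#'
#' @param x An `amnd_metrics`.
#' @param ... Unused.
#' @return A tibble with columns `metric` and `value`.
#' @method tidy amnd_metrics
#' @export
tidy.amnd_metrics <- function(x, ...) {
  tibble::tibble(metric = c("acc", "pre", "recall", "f1"),
                 value = c(x$acc, x$pre, x$recall, x$f1))
}

#' Tidy the training history of a fitted model
#'
#' @param x An `amnd_model`.
#' @param ... Unused.
#' @return The per-epoch history tibble (`epoch`, `train_loss`, `val_auc`).
#' @method tidy amnd_model
#' @export
tidy.amnd_model <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @param x An `amnd_model`.
#' @param ... Unused.
#' @return A one-row tibble: `variant`, `epochs`, `best_epoch`,
#'   `best_val_auc`.
#' @method glance amnd_model
#' @export
glance.amnd_model <- function(x, ...) {
  tibble::tibble(variant = x$config$variant, epochs = nrow(x$history),
                 best_epoch = x$best_epoch, best_val_auc = x$best_val_auc)
}

#' Per-repeat rows of a repeated-split report
#'
#' @param x An `amnd_repeat_report`.
#' @param ... Unused.
#' @return The per-repeat tibble.
#' @method tidy amnd_repeat_report
#' @export
tidy.amnd_repeat_report <- function(x, ...) x$per_repeat

#' One-row mean/SD summary of a repeated-split report
#'
#' @param x An `amnd_repeat_report`.
#' @param ... Unused.
#' @return A one-row tibble with `<metric>_mean` and `<metric>_sd` columns
#'   plus `variant` and `n_repeats`.
#' @method glance amnd_repeat_report
#' @export
glance.amnd_repeat_report <- function(x, ...) {
  wide <- as.list(c(stats::setNames(x$summary$mean, paste0(x$summary$metric, "_mean")),
                    stats::setNames(x$summary$sd, paste0(x$summary$metric, "_sd"))))
  tibble::as_tibble(c(list(variant = x$variant,
                           n_repeats = nrow(x$per_repeat)), wide))
}
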