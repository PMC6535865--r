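#' Plot the objective trace of a factorization
#'
#' @param object An `amnd_factorization`.
#' @param ... Unused.
#' @return A ggplot: objective versus outer iteration on a log y scale.
#' @method autoplot amnd_factorization
#' @export
autoplot.amnd_factorization <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(title = paste0("NMF objective trace (", object$solver_name, ")"),
                  x = "outer iteration", y = "objective") +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object An `amnd_roc`.
#' @param ... Unused.
#' @return A ggplot of the ROC curve with the chance diagonal.
#' @method autoplot amnd_roc
#' @export
autoplot.amnd_roc <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("ROC (AUC = %.3f)", object$auc),
                  x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Plot training history of a fitted model
#'
#' @param object An `amnd_model`.
#' @param ... Unused.
#' @return A ggplot of training loss and validation AUC per epoch.
#' @method autoplot amnd_model
#' @export
autoplot.amnd_model <- function(object, ...) {
  df <- tidy(object)
  long <- rbind(
    data.frame(epoch = df$epoch, value = df$train_loss, what = "train loss"),
    data.frame(epoch = df$epoch, value = df$val_auc, what = "validation AUC")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dotted") +
    ggplot2::facet_wrap(~what, scales = "free_y", ncol = 1L) +
    ggplot2::labs(title = paste0("training history (", object$config$variant, ")"),
                  x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-repeat metric distributions
#'
#' @param object An `amnd_repeat_report`.
#' @param ... Unused.
#' @return A ggplot: boxplots of AUC/Acc/Pre/recall/F1 over repeats.
#' @method autoplot amnd_repeat_report
#' @export
autoplot.amnd_repeat_report <- function(object, ...) {
  df <- object$per_repeat
  long <- do.call(rbind, lapply(c("auc", "acc", "pre", "recall", "f1"),
                                function(mn) data.frame(metric = mn, value = df[[mn]])))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(title = paste0("test metrics over ", nrow(df),
                                 " repartitions (", object$variant, ")"),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of per-sample attention weights
#'
#' @param weights Tibble from [attention_weights()].
#' @param max_samples Cap on plotted samples (random thinning beyond it is
#'   not applied; the first `max_samples` rows are shown).
#' @return A ggplot tile map, samples by solvers.
#' @export
plot_attention_weights <- function(weights, max_samples = 100L) {
  w <- utils::head(weights, max_samples)
  long <- do.call(rbind, lapply(SOLVER_ORDER, function(s) {
    data.frame(sample_id = w$sample_id, solver = s, weight = w[[s]])
  }))
  long$sample_id <- factor(long$sample_id, levels = w$sample_id)
  long$solver <- factor(long$solver, levels = SOLVER_ORDER)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$solver, y = .data$sample_id,
                                     fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "NMF solver", y = "sample", fill = "weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
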