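# Adam state and update over the nested parameter list.

adam_init <- function(params) {
  zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      if (!is.null(names(p))) g <- g[names(p)]  # grads may list components in another order
      res <- Map(walk, p, g, m, v)
      list(p = lapply(res, `[[`, "p"), m = lapply(res, `[[`, "m"),
           v = lapply(res, `[[`, "v"))
    } else {
      upd(p, g, m, v)
    }
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}

#' Train the fusion classifier end-to-end
#'
#' Minimizes binary cross-entropy with Adam over minibatches. For the
#' attention variants the gradient flows through the softmax and the
#' bilinear score into the attention matrix `X`, so fusion weights and
#' network train jointly. Early stopping monitors validation AUC and the
#' returned model is the best-validation-epoch snapshot.
#'
#' @param stack An [feature_stack()] (or `NULL` for `only_clinical`).
#' @param clinical `m x d_c` clinical matrix (or `NULL` for `only_exp`).
#' @param labels 0/1 vector of length `m`.
#' @param split An [stratified_split()] of the `m` samples.
#' @param cfg An [model_config()].
#' @return An object of class `amnd_model`: `params`, `config`, `history`
#'   (tibble: epoch, train_loss, val_auc), `best_epoch`, `r`, `d_c`.
#' @export
amnd_train <- function(stack, clinical, labels, split, cfg = model_config()) {
  stopifnot(inherits(split, "amnd_split"), inherits(cfg, "amnd_model_config"))
  labels <- as.integer(labels)
  if (variant_uses_stack(cfg) && !inherits(stack, "amnd_stack")) {
    stop("variant '", cfg$variant, "' needs a feature stack")
  }
  if (variant_uses_clinical(cfg) && is.null(clinical)) {
    stop("variant '", cfg$variant, "' needs clinical data")
  }
  if (!is.null(clinical)) clinical <- as.matrix(clinical)
  data <- list(stack = if (variant_uses_stack(cfg)) stack,
               clinical = clinical, labels = labels)
  tr <- split$train_idx; va <- split$val_idx
  if (length(unique(labels[tr])) < 2L) stop("training set contains a single class")
  if (length(unique(labels[va])) < 2L) stop("validation set contains a single class")

  r <- if (!is.null(data$stack)) data$stack$r else 0L
  d_c <- if (!is.null(clinical)) ncol(clinical) else 0L
  sample_weights <- NULL
  if (cfg$class_weights) {
    freq <- table(factor(labels[tr], levels = c(0L, 1L)))
    wcls <- as.numeric(sum(freq) / (2 * freq))
    sample_weights <- wcls[labels + 1L]
  }

  params <- init_params(cfg, r, d_c)
  state <- adam_init(params)
  history <- vector("list", cfg$max_epochs)
  best <- list(auc = -Inf, epoch = 0L, params = params)
  stall <- 0L
  burn_in <- min(cfg$min_epochs, cfg$max_epochs)

  with_local_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample(tr)
      nb <- ceiling(length(perm) / cfg$batch_size)
      ep_loss <- 0
      for (bi in seq_len(nb)) {
        lo <- (bi - 1L) * cfg$batch_size + 1L
        hi <- min(bi * cfg$batch_size, length(perm))
        idx <- perm[lo:hi]
        step <- nn_loss_grads(params, data, idx, cfg, train_mode = TRUE,
                              sample_weights = sample_weights)
        res <- adam_step(params, step$grads, state, cfg$learning_rate)
        params <- res$params
        state <- res$state
        ep_loss <- ep_loss + step$loss * length(idx)
      }
      ep_loss <- ep_loss / length(perm)
      val <- nn_loss_grads(params, data, va, cfg, train_mode = FALSE,
                           want_grads = FALSE)
      val_auc <- roc_auc(labels[va], val$probs)$auc
      history[[epoch]] <- c(epoch = epoch, train_loss = ep_loss, val_auc = val_auc)
      if (epoch < burn_in) next  # burn-in: a barely-trained net can score a
                                 # lucky AUC on a small validation set
      if (val_auc > best$auc + 1e-12) {
        best <- list(auc = val_auc, epoch = epoch, params = params)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
  })
  history <- tibble::as_tibble(do.call(rbind, history[!vapply(history, is.null, logical(1L))]))
  structure(
    list(params = best$params, config = cfg, history = history,
         best_epoch = best$epoch, best_val_auc = best$auc, r = r, d_c = d_c),
    class = "amnd_model"
  )
}

#' @export
print.amnd_model <- function(x, ...) {
  cat("amnd model [", x$config$variant, "]: trained ", nrow(x$history),
      " epochs, best epoch ", x$best_epoch, " (validation AUC ",
      format(x$best_val_auc, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Predict survival probabilities
#'
#' Deterministic forward pass (no dropout); probabilities are sigmoid
#' outputs in `[0, 1]`, labels are thresholded at 0.5.
#'
#' @param model An [amnd_train()] fit.
#' @param stack,clinical Data aligned on samples (as in training).
#' @param idx Optional row indices to score (default: all samples).
#' @return A tibble of class `amnd_predictions` with columns `sample_id`,
#'   `probability`, `label`.
#' @export
amnd_predict <- function(model, stack = NULL, clinical = NULL, idx = NULL) {
  stopifnot(inherits(model, "amnd_model"))
  cfg <- model$config
  m <- if (!is.null(stack)) stack$m else nrow(clinical)
  if (is.null(idx)) idx <- seq_len(m)
  data <- list(stack = if (variant_uses_stack(cfg)) stack,
               clinical = if (!is.null(clinical)) as.matrix(clinical),
               labels = integer(m))
  if (variant_uses_stack(cfg) && is.null(data$stack)) {
    stop("variant '", cfg$variant, "' needs a feature stack")
  }
  if (variant_uses_clinical(cfg) && is.null(data$clinical)) {
    stop("variant '", cfg$variant, "' needs clinical data")
  }
  exp_width <- variant_input_width(cfg, model$r, model$d_c)
  got_r <- if (!is.null(data$stack)) data$stack$r else 0L
  got_d <- if (!is.null(data$clinical)) ncol(data$clinical) else 0L
  if (variant_input_width(cfg, got_r, got_d) != exp_width) {
    stop("input width mismatch: model expects ", exp_width)
  }
  fw <- nn_loss_grads(model$params, data, idx, cfg, train_mode = FALSE,
                      want_grads = FALSE)
  ids <- if (!is.null(data$stack) && !is.null(rownames(data$stack$mats[[1L]]))) {
    rownames(data$stack$mats[[1L]])[idx]
  } else if (!is.null(data$clinical) && !is.null(rownames(data$clinical))) {
    rownames(data$clinical)[idx]
  } else as.character(idx)
  out <- tibble::tibble(sample_id = ids, probability = fw$probs,
                        label = as.integer(fw$probs >= 0.5))
  class(out) <- c("amnd_predictions", class(out))
  out
}

#' Per-sample attention weights of a trained model
#'
#' @param model A trained attention-variant model.
#' @param stack,clinical Data aligned on samples.
#' @return A tibble: `sample_id` plus one normalized-weight column per
#'   solver; each row sums to 1.
#' @export
attention_weights <- function(model, stack, clinical) {
  stopifnot(inherits(model, "amnd_model"))
  if (!variant_uses_attention(model$config)) {
    stop("variant '", model$config$variant, "' has no attention weights")
  }
  what <- attention_normalize(
    attention_raw_weights(stack, clinical, model$params$X))
  ids <- rownames(stack$mats[[1L]])
  if (is.null(ids)) ids <- as.character(seq_len(stack$m))
  out <- tibble::as_tibble(as.data.frame(what))
  names(out) <- SOLVER_ORDER
  tibble::add_column(out, sample_id = ids, .before = 1L)
}
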