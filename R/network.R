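#' Configuration of the fusion classifier
#'
#' @param hidden_layers Integer vector of hidden-layer widths.
#' @param activation `"relu"` or `"tanh"`.
#' @param dropout Dropout probability on hidden activations during training,
#'   in `[0, 1)`.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience, in epochs without a new best
#'   validation AUC; the returned model is rolled back to the best epoch.
#' @param min_epochs Burn-in before early-stopping tracking starts: epochs
#'   before this are never selected as best (an untrained network can score
#'   a spuriously high AUC on a small validation set).
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout; training is a pure function of data + config.
#' @param variant One of `"amnd"` (attention fusion + clinical
#'   concatenation), `"clinical_first"` (attention fusion only; clinical
#'   data drive the weights but are not concatenated), `"clinical_second"`
#'   (uniform 0.2 fusion + clinical), `"only_clinical"`, `"only_exp"`
#'   (uniform 0.2 fusion only), or `"single:<solver>"` (one solver's
#'   features + clinical).
#' @param attention_decay L2 penalty weight on the bilinear attention
#'   matrix `X`; shrinks the raw scores toward 0, i.e. toward uniform
#'   attention, unless the data support a deviation.
#' @param class_weights Weight the loss by inverse class frequency
#'   (default `FALSE`).
#' @return A list of class `amnd_model_config`.
#' @export
model_config <- function(hidden_layers = c(128L, 32L),
                         activation = c("relu", "tanh"), dropout = 0.2,
                         learning_rate = 1e-3, batch_size = 32L,
                         max_epochs = 200L, patience = 20L, min_epochs = 10L,
                         seed = 1L, variant = "amnd", attention_decay = 1e-3,
                         class_weights = FALSE) {
  activation <- match.arg(activation)
  stopifnot(length(hidden_layers) >= 1L, all(hidden_layers >= 1L),
            dropout >= 0, dropout < 1, learning_rate > 0,
            batch_size >= 1L, max_epochs >= 1L, patience >= 1L,
            min_epochs >= 1L, attention_decay >= 0)
  vp <- parse_variant(variant)
  structure(
    list(hidden_layers = as.integer(hidden_layers), activation = activation,
         dropout = dropout, learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         min_epochs = as.integer(min_epochs),
         attention_decay = attention_decay,
         seed = as.integer(seed), variant = variant,
         variant_kind = vp$kind, solver = vp$solver,
         class_weights = isTRUE(class_weights)),
    class = "amnd_model_config"
  )
}

parse_variant <- function(variant) {
  known <- c("amnd", "clinical_first", "clinical_second", "only_clinical", "only_exp")
  if (variant %in% known) return(list(kind = variant, solver = NULL))
  if (startsWith(variant, "single:")) {
    solver <- sub("^single:", "", variant)
    if (!solver %in% SOLVER_ORDER) {
      stop("unknown solver in variant '", variant, "'; use one of ",
           paste(SOLVER_ORDER, collapse = ", "))
    }
    return(list(kind = "single", solver = solver))
  }
  stop("unknown variant '", variant, "'")
}

variant_uses_attention <- function(cfg) cfg$variant_kind %in% c("amnd", "clinical_first")
variant_uses_stack <- function(cfg) cfg$variant_kind != "only_clinical"
variant_uses_clinical <- function(cfg) cfg$variant_kind != "only_exp"
variant_concats_clinical <- function(cfg) {
  cfg$variant_kind %in% c("amnd", "clinical_second", "only_clinical", "single")
}

variant_input_width <- function(cfg, r, d_c) {
  switch(cfg$variant_kind,
         amnd = r + d_c,
         clinical_first = r,
         clinical_second = r + d_c,
         only_clinical = d_c,
         only_exp = r,
         single = r + d_c)
}

#' Assemble classifier inputs for a variant at fixed attention parameters
#'
#' Builds the per-sample input matrix each ablation variant feeds the
#' network: attention-fused features (with the supplied `X`), uniform
#' 0.2-weight fusion, a single solver's features, and/or the clinical
#' block, as the variant dictates.
#'
#' @param variant Variant string (see [model_config()]).
#' @param stack An [feature_stack()] (ignored by `only_clinical`).
#' @param clinical `m x d_c` clinical matrix.
#' @param X `r x d_c` attention matrix, required by the attention variants.
#' @return An `m x width` numeric input matrix.
#' @export
build_inputs <- function(variant, stack = NULL, clinical = NULL, X = NULL) {
  vp <- parse_variant(variant)
  kind <- vp$kind
  if (kind != "only_clinical" && is.null(stack)) {
    stop("variant '", variant, "' needs a feature stack")
  }
  if (kind %in% c("amnd", "clinical_first", "clinical_second", "only_clinical", "single") &&
      is.null(clinical)) {
    stop("variant '", variant, "' needs clinical data")
  }
  if (kind %in% c("amnd", "clinical_first")) {
    if (is.null(X)) stop("attention variants need the bilinear matrix X")
    what <- attention_normalize(attention_raw_weights(stack, clinical, X))
    F <- attention_fuse(stack, what)
    if (kind == "amnd") concat_clinical(F, clinical) else F
  } else if (kind == "clinical_second") {
    concat_clinical(uniform_fusion(stack), clinical)
  } else if (kind == "only_clinical") {
    as.matrix(clinical)
  } else if (kind == "only_exp") {
    uniform_fusion(stack)
  } else {
    concat_clinical(stack$mats[[vp$solver]], clinical)
  }
}

uniform_fusion <- function(stack) {
  attention_fuse(stack, matrix(0.2, stack$m, 5L))
}

# ---- network internals ------------------------------------------------------

init_params <- function(cfg, r, d_c) {
  with_local_seed(cfg$seed, {
    params <- list()
    if (variant_uses_attention(cfg)) {
      s <- 1 / sqrt(r * d_c)  # raw scores start near 0 => near-uniform attention
      params$X <- matrix(runif(r * d_c, -s, s), r, d_c)
    }
    widths <- c(variant_input_width(cfg, r, d_c), cfg$hidden_layers, 1L)
    params$layers <- vector("list", length(widths) - 1L)
    for (l in seq_along(params$layers)) {
      sdv <- sqrt(2 / widths[l])  # He init; sensible for relu, fine for tanh
      params$layers[[l]] <- list(
        W = matrix(rnorm(widths[l] * widths[l + 1L], sd = sdv),
                   widths[l], widths[l + 1L]),
        b = numeric(widths[l + 1L])
      )
    }
    params
  })
}

# Forward and (optionally) backward pass for one batch of row indices.
# data: list(stack = amnd_stack or NULL, clinical = matrix or NULL,
# labels = 0/1 vector). Dropout masks are drawn from the current RNG stream
# when train_mode is TRUE. Returns list(loss, probs, what, grads?).
nn_loss_grads <- function(params, data, idx, cfg, train_mode = FALSE,
                          sample_weights = NULL, want_grads = TRUE) {
  kind <- cfg$variant_kind
  B <- length(idx)
  clin <- if (!is.null(data$clinical)) data$clinical[idx, , drop = FALSE]
  sub_mats <- NULL
  if (variant_uses_stack(cfg)) {
    sub_mats <- lapply(data$stack$mats, function(M) M[idx, , drop = FALSE])
  }
  r <- if (!is.null(sub_mats)) ncol(sub_mats[[1L]]) else 0L

  # fusion stage
  what <- NULL
  F <- NULL
  if (variant_uses_attention(cfg)) {
    Z <- clin %*% t(params$X)  # B x r; row i = X c(i)
    raw <- vapply(sub_mats, function(Wj) rowSums(Wj * Z), numeric(B))
    if (B == 1L) raw <- matrix(raw, 1L)
    e <- exp(raw - apply(raw, 1L, max))
    what <- e / rowSums(e)
    F <- matrix(0, B, r)
    for (j in seq_len(5L)) F <- F + what[, j] * sub_mats[[j]]
  } else if (kind == "single") {
    F <- sub_mats[[cfg$solver]]
  } else if (kind != "only_clinical") {
    F <- matrix(0, B, r)
    for (j in seq_len(5L)) F <- F + 0.2 * sub_mats[[j]]
  }
  input <- if (kind == "only_clinical") clin
           else if (kind %in% c("clinical_first", "only_exp")) F
           else cbind(F, clin)

  # MLP forward; apre = pre-dropout activation (for exact derivatives)
  L <- length(params$layers)
  zs <- vector("list", L)
  apre <- vector("list", L)
  apost <- vector("list", L)
  masks <- vector("list", L)
  a <- input
  for (l in seq_len(L)) {
    lay <- params$layers[[l]]
    z <- a %*% lay$W + matrix(lay$b, B, length(lay$b), byrow = TRUE)
    zs[[l]] <- z
    if (l < L) {
      av <- if (cfg$activation == "relu") pmax(z, 0) else tanh(z)
      apre[[l]] <- av
      if (train_mode && cfg$dropout > 0) {
        mask <- matrix(rbinom(length(av), 1L, 1 - cfg$dropout),
                       nrow(av), ncol(av)) / (1 - cfg$dropout)
        av <- av * mask
        masks[[l]] <- mask
      }
      apost[[l]] <- av
      a <- av
    }
  }
  logits <- as.numeric(zs[[L]])
  probs <- stats::plogis(logits)
  y <- data$labels[idx]
  wts <- if (is.null(sample_weights)) rep(1, B) else sample_weights[idx]
  wts <- wts / sum(wts)
  epsl <- 1e-12
  loss <- -sum(wts * (y * log(probs + epsl) + (1 - y) * log(1 - probs + epsl)))
  decay <- if (is.null(cfg$attention_decay)) 0 else cfg$attention_decay
  if (variant_uses_attention(cfg) && decay > 0) {
    loss <- loss + decay * sum(params$X^2)
  }

  out <- list(loss = loss, probs = probs, what = what)
  if (!want_grads) return(out)

  grads <- list(layers = vector("list", L))
  delta <- matrix(wts * (probs - y), B, 1L)  # dloss/dlogits (BCE + sigmoid)
  dinput <- NULL
  for (l in rev(seq_len(L))) {
    a_prev <- if (l == 1L) input else apost[[l - 1L]]
    grads$layers[[l]] <- list(W = crossprod(a_prev, delta),
                              b = colSums(delta))
    d_aprev <- delta %*% t(params$layers[[l]]$W)
    if (l > 1L) {
      if (!is.null(masks[[l - 1L]])) d_aprev <- d_aprev * masks[[l - 1L]]
      dact <- if (cfg$activation == "relu") (zs[[l - 1L]] > 0) * 1
              else 1 - apre[[l - 1L]]^2
      delta <- d_aprev * dact
    } else {
      dinput <- d_aprev
    }
  }

  if (variant_uses_attention(cfg)) {
    dF <- dinput[, seq_len(r), drop = FALSE]
    # through the convex combination: da[, j] = <W_j(i), dF(i)>
    da <- vapply(sub_mats, function(Wj) rowSums(Wj * dF), numeric(B))
    if (B == 1L) da <- matrix(da, 1L)
    # softmax backward
    draw <- what * (da - rowSums(what * da))
    # raw[i, j] = <W_j(i), Z(i)> with Z = clin %*% t(X)
    dZ <- matrix(0, B, r)
    for (j in seq_len(5L)) dZ <- dZ + draw[, j] * sub_mats[[j]]
    grads$X <- crossprod(dZ, clin)  # r x d_c
    if (decay > 0) grads$X <- grads$X + 2 * decay * params$X
  }
  out$grads <- grads
  out
}
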