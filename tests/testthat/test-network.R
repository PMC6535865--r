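# A small separable two-modality fixture used by several blocks: the first
# stack feature carries the label, the clinical block is mildly informative.
make_training_fixture <- function(m = 80, seed = 7) {
  set.seed(seed)
  x <- runif(m)
  labels <- as.integer(x > 0.5)
  mats <- stats::setNames(lapply(1:5, function(j) {
    cbind(x + rnorm(m, sd = 0.02), matrix(runif(m * 2), m, 2))
  }), c("mu", "als", "alsobs", "pg", "pnmf"))
  clinical <- cbind(x + rnorm(m, sd = 0.3), matrix(runif(m * 2), m, 2))
  clinical <- minmax_normalize(clinical)
  list(stack = feature_stack(mats, normalize = FALSE), clinical = clinical,
       labels = labels, split = stratified_split(labels, seed = seed))
}

test_that("variant inputs have the documented widths and contents", {
  fx <- make_training_fixture()
  r <- 3L; d_c <- 3L
  X <- matrix(rnorm(r * d_c, sd = 0.1), r, d_c)
  expect_identical(ncol(build_inputs("amnd", fx$stack, fx$clinical, X)), r + d_c)
  expect_identical(ncol(build_inputs("clinical_first", fx$stack, fx$clinical, X)), r)
  expect_identical(ncol(build_inputs("clinical_second", fx$stack, fx$clinical)), r + d_c)
  expect_identical(ncol(build_inputs("only_clinical", clinical = fx$clinical)), d_c)
  expect_identical(ncol(build_inputs("only_exp", fx$stack)), r)
  single <- build_inputs("single:pg", fx$stack, fx$clinical)
  expect_identical(ncol(single), r + d_c)
  expect_equal(single[, 1:r], fx$stack$mats$pg)
  expect_error(build_inputs("amnd", fx$stack, fx$clinical), "X")
  expect_error(build_inputs("nope", fx$stack, fx$clinical), "unknown variant")
})

test_that("zero attention parameters reproduce the uniform-fusion variant exactly", {
  fx <- make_training_fixture()
  amnd_in <- build_inputs("amnd", fx$stack, fx$clinical, matrix(0, 3, 3))
  unif_in <- build_inputs("clinical_second", fx$stack, fx$clinical)
  expect_equal(amnd_in, unif_in, tolerance = 1e-12)
  # identical branches make the uniform fusion equal any single branch
  same <- fx$stack
  same$mats <- lapply(same$mats, function(x) fx$stack$mats$mu)
  expect_equal(build_inputs("only_exp", same), fx$stack$mats$mu, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences end-to-end", {
  set.seed(9)
  m <- 10; r <- 3; d_c <- 2
  stack <- make_stack(m, r, seed = 31)
  clinical <- matrix(runif(m * d_c), m, d_c)
  labels <- c(rep(1L, 5), rep(0L, 5))
  cfg <- model_config(hidden_layers = 4L, dropout = 0, seed = 3,
                      variant = "amnd", attention_decay = 1e-3)
  params <- amnd:::init_params(cfg, r, d_c)
  data <- list(stack = stack, clinical = clinical, labels = labels)
  idx <- seq_len(m)
  res <- amnd:::nn_loss_grads(params, data, idx, cfg)
  h <- 1e-6
  loss_at <- function(p) amnd:::nn_loss_grads(p, data, idx, cfg,
                                              want_grads = FALSE)$loss
  flat_check <- function(getter, setter, analytic) {
    p0 <- getter(params)
    worst <- 0
    for (k in seq_along(p0)) {
      pp <- p0; pp[k] <- p0[k] + h
      lp <- loss_at(setter(params, pp))
      pp[k] <- p0[k] - h
      lm <- loss_at(setter(params, pp))
      fd <- (lp - lm) / (2 * h)
      worst <- max(worst, abs(fd - analytic[k]) /
                            max(abs(fd), abs(analytic[k]), 1e-8))
    }
    worst
  }
  worst <- flat_check(function(p) as.numeric(p$X),
                      function(p, v) { p$X[] <- v; p },
                      as.numeric(res$grads$X))
  for (l in seq_along(params$layers)) {
    worst <- max(worst,
      flat_check(function(p) as.numeric(p$layers[[l]]$W),
                 function(p, v) { p$layers[[l]]$W[] <- v; p },
                 as.numeric(res$grads$layers[[l]]$W)),
      flat_check(function(p) as.numeric(p$layers[[l]]$b),
                 function(p, v) { p$layers[[l]]$b[] <- v; p },
                 as.numeric(res$grads$layers[[l]]$b)))
  }
  expect_lt(worst, 1e-4)
})

test_that("training is deterministic and learns a separable cohort", {
  fx <- make_training_fixture()
  # min_epochs near the cap so the snapshot comes from a well-trained epoch
  # (the 8-sample validation set saturates almost immediately here)
  cfg <- model_config(hidden_layers = c(16L, 8L), dropout = 0,
                      max_epochs = 150L, patience = 60L, min_epochs = 120L,
                      seed = 5, learning_rate = 5e-3)
  mod <- amnd_train(fx$stack, fx$clinical, fx$labels, fx$split, cfg)
  mod2 <- amnd_train(fx$stack, fx$clinical, fx$labels, fx$split, cfg)
  expect_identical(mod$history, mod2$history)
  expect_identical(mod$params, mod2$params)
  # loss decreased and the training portion is essentially solved
  expect_lt(mod$history$train_loss[mod$best_epoch], mod$history$train_loss[1])
  pr <- amnd_predict(mod, fx$stack, fx$clinical, idx = fx$split$train_idx)
  expect_gte(roc_auc(fx$labels[fx$split$train_idx], pr$probability)$auc, 0.99)
})

test_that("early stopping reports the best post-burn-in validation AUC", {
  fx <- make_training_fixture(seed = 21)
  cfg <- model_config(hidden_layers = 8L, max_epochs = 60L, patience = 15L,
                      min_epochs = 10L, seed = 2)
  mod <- amnd_train(fx$stack, fx$clinical, fx$labels, fx$split, cfg)
  h <- mod$history
  eligible <- h$val_auc[h$epoch >= cfg$min_epochs]
  expect_equal(mod$best_val_auc, max(eligible))
  expect_identical(h$val_auc[h$epoch == mod$best_epoch][1], mod$best_val_auc)
})

test_that("prediction is a deterministic sigmoid map with sane edge cases", {
  fx <- make_training_fixture(seed = 33)
  cfg <- model_config(hidden_layers = 8L, max_epochs = 15L, patience = 10L,
                      min_epochs = 5L, seed = 4)
  mod <- amnd_train(fx$stack, fx$clinical, fx$labels, fx$split, cfg)
  p_all <- amnd_predict(mod, fx$stack, fx$clinical)
  expect_true(all(p_all$probability >= 0 & p_all$probability <= 1))
  # a zeroed network outputs probability 0.5 everywhere
  mod0 <- mod
  mod0$params$layers <- lapply(mod0$params$layers, function(l) {
    l$W[] <- 0; l$b[] <- 0; l
  })
  p0 <- amnd_predict(mod0, fx$stack, fx$clinical)
  expect_equal(p0$probability, rep(0.5, nrow(p0)))
  # subsetting rows (any "batching") leaves probabilities unchanged
  p_sub <- amnd_predict(mod, fx$stack, fx$clinical, idx = c(4L, 9L))
  expect_equal(p_sub$probability, p_all$probability[c(4, 9)], tolerance = 1e-12)
})

test_that("degenerate training inputs are rejected", {
  fx <- make_training_fixture(seed = 40)
  one_class <- fx
  one_class$labels <- rep(1L, length(fx$labels))
  split <- fx$split  # reuse a valid partition
  expect_error(amnd_train(one_class$stack, one_class$clinical,
                          one_class$labels, split, model_config()),
               "single class")
  expect_error(amnd_train(NULL, fx$clinical, fx$labels, fx$split,
                          model_config(variant = "amnd")), "stack")
  expect_error(amnd_train(fx$stack, NULL, fx$labels, fx$split,
                          model_config(variant = "only_clinical")), "clinical")
})
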