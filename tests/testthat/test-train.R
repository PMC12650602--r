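test_that("cosine annealing hits its endpoints and midpoint", {
  cfg <- train_config()
  expect_equal(cosine_lr(0, cfg), 1e-3)
  expect_equal(cosine_lr(100, cfg), 1e-6)
  expect_equal(cosine_lr(50, cfg), 5.005e-4, tolerance = 1e-7)
  expect_equal(cosine_lr(150, cfg), 1e-6)  # clamped beyond t_max
  expect_true(all(diff(cosine_lr(0:100, cfg)) < 0))  # monotone decay
})

test_that("gradient clipping rescales by the global norm", {
  g <- clip_gradients(list(a = c(2, 0)), 1)
  expect_equal(g$a, c(1, 0))
  expect_equal(attr(g, "global_norm"), 2)
  g2 <- clip_gradients(list(a = c(0.3, 0.4)), 1)
  expect_equal(g2$a, c(0.3, 0.4))  # norm 0.5, unchanged
  g3 <- clip_gradients(list(a = c(3, 0), b = matrix(c(0, 4), 1)), 1)
  expect_equal(g3$a, c(0.6, 0))
  expect_equal(as.numeric(g3$b), c(0, 0.8))
  expect_equal(attr(g3, "global_norm"), 5)
})

test_that("stratified splitting preserves proportions and partitions the data", {
  ds <- generate_dataset(200, rng_seed = 301)  # 1000 beats
  cfg <- train_config(seed = 17, test_frac = 0.2, val_frac = 0.2)
  sp <- split_dataset(ds, cfg)
  expect_equal(nrow(sp$train$beats), 640L)
  expect_equal(nrow(sp$val$beats), 160L)
  expect_equal(nrow(sp$test$beats), 200L)
  expect_true(all(sp$train$class_counts == 128L))
  expect_true(all(sp$val$class_counts == 32L))
  expect_true(all(sp$test$class_counts == 40L))
  # partition: union of label multisets equals the input multiset
  all_lab <- sort(c(as.character(sp$train$labels), as.character(sp$val$labels),
                    as.character(sp$test$labels)))
  expect_equal(all_lab, sort(as.character(ds$labels)))
  # and of the rows themselves
  all_rows <- rbind(sp$train$beats, sp$val$beats, sp$test$beats)
  expect_equal(sort(all_rows[, 1]), sort(ds$beats[, 1]))
  # determinism / seed sensitivity
  sp2 <- split_dataset(ds, cfg)
  expect_identical(sp$train$beats, sp2$train$beats)
  sp3 <- split_dataset(ds, train_config(seed = 18))
  expect_false(identical(sp$train$beats, sp3$train$beats))
  expect_equal(dim(sp3$train$beats), dim(sp$train$beats))
  # too-small classes are refused
  tiny <- beat_dataset(ds$beats[1:20, ], ds$labels[1:20])
  expect_error(split_dataset(tiny, cfg), "at least 5")
})

small_splits <- function() {
  ds <- generate_dataset(60, rng_seed = 401)
  cfg <- train_config(seed = 23, max_epochs = 4, batch_size = 128)
  c(split_dataset(ds, cfg), list(cfg = cfg))
}

test_that("training reduces the loss and logs the cosine schedule", {
  sp <- small_splits()
  fit <- train_model(sp$train, sp$val, model_config(), sp$cfg)
  h <- fit$history
  expect_lte(nrow(h), 4L)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_equal(h$lr, cosine_lr(h$epoch - 1, sp$cfg))
  # restored checkpoint is at least as good as the first epoch
  expect_lte(min(h$val_loss), h$val_loss[1])
  # SMOTE provenance lands on the training split only
  has_bal <- function(d) any(vapply(d$provenance,
    function(p) identical(p$step, "balance_smote"), logical(1)))
  expect_true(has_bal(smote_oversample(sp$train)))
  expect_false(has_bal(sp$val))
  expect_false(has_bal(sp$test))
  # training is reproducible from the master seed
  fit2 <- train_model(sp$train, sp$val, model_config(), sp$cfg)
  expect_equal(fit$history, fit2$history, tolerance = 1e-12)
  expect_equal(fit$model$params, fit2$model$params, tolerance = 1e-12)
})

test_that("a zero learning rate freezes the loss", {
  ds <- generate_dataset(20, rng_seed = 402)
  cfg <- train_config(seed = 5, max_epochs = 3, lr0 = 1e-12, eta_min = 0,
                      batch_size = 256, weight_decay = 0)
  sp <- split_dataset(ds, cfg)
  mcfg <- model_config(transformer_dropout = 0, classifier_dropout = 0)
  fit <- train_model(sp$train, sp$val, mcfg, cfg)
  # single full batch per epoch, no dropout, negligible updates:
  # the training loss is constant across epochs
  expect_lt(diff(range(fit$history$train_loss)), 1e-6)
})

test_that("balanced validation data and empty splits are rejected", {
  sp <- small_splits()
  bal_val <- smote_oversample(
    beat_dataset(sp$val$beats, sp$val$labels, role = "train"))
  expect_error(train_model(sp$train, bal_val, model_config(), sp$cfg),
               "never be balanced")
  empty <- beat_dataset(sp$val$beats[0, , drop = FALSE],
                        sp$val$labels[0])
  expect_error(train_model(empty, sp$val, model_config(), sp$cfg), "empty")
})
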