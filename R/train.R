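# Dataset splitting and the optimization loop: Adam with weight decay,
# cosine-annealed learning rate, global-norm gradient clipping, early
# stopping on validation loss with best-checkpoint restore. SMOTE is
# applied to the training split only.

#' Training configuration
#'
#' Defaults follow the study protocol: Adam with initial learning rate
#' 1e-3 and weight decay 1e-4, cosine annealing to 1e-6 over `t_max = 100`
#' epochs, batch size 256, gradient clipping at global norm 1.0. Early
#' stopping monitors validation loss with patience 10 and restores the
#' best checkpoint. One master `seed` drives the split, SMOTE, weight
#' initialization, batch shuffling and dropout.
#'
#' @param lr0 Initial learning rate.
#' @param weight_decay L2 weight-decay coefficient.
#' @param t_max Cosine-annealing period in epochs.
#' @param eta_min Minimum learning rate.
#' @param batch_size Mini-batch size.
#' @param clip_max_norm Global gradient-norm clip threshold.
#' @param max_epochs Maximum training epochs.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping.
#' @param early_stop_min_delta Smallest validation-loss decrease counted as
#'   an improvement (cross-entropy scale); smaller changes are treated as
#'   numerical noise.
#' @param seed Master seed.
#' @param test_frac Fraction of the whole dataset held out as the test set.
#' @param val_frac Fraction of the remainder used for validation (the
#'   80/20 development split).
#' @param balance `"smote"` (balance the training split) or `"none"`.
#' @param smote_k SMOTE neighbour count.
#' @param bn_momentum Batch-norm running-statistics momentum.
#' @return A `train_config` list.
#' @export
train_config <- function(lr0 = 1e-3, weight_decay = 1e-4, t_max = 100L,
                         eta_min = 1e-6, batch_size = 256L,
                         clip_max_norm = 1.0, max_epochs = 100L,
                         early_stop_patience = 10L,
                         early_stop_min_delta = 1e-4, seed = 1L,
                         test_frac = 0.2, val_frac = 0.2,
                         balance = c("smote", "none"), smote_k = 5L,
                         bn_momentum = 0.1) {
  balance <- match.arg(balance)
  stopifnot(lr0 >= 0, weight_decay >= 0, t_max > 0, eta_min >= 0,
            batch_size > 0, clip_max_norm > 0, max_epochs > 0,
            early_stop_patience > 0, early_stop_min_delta >= 0,
            test_frac > 0, test_frac < 1,
            val_frac > 0, val_frac < 1)
  structure(list(lr0 = lr0, weight_decay = weight_decay,
                 t_max = as.integer(t_max), eta_min = eta_min,
                 batch_size = as.integer(batch_size),
                 clip_max_norm = clip_max_norm,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 early_stop_min_delta = early_stop_min_delta,
                 seed = as.integer(seed), test_frac = test_frac,
                 val_frac = val_frac, balance = balance,
                 smote_k = as.integer(smote_k), bn_momentum = bn_momentum),
            class = "train_config")
}

#' Stratified train/validation/test split
#'
#' The test set is held out first (`test_frac` of each class), then the
#' remainder is split 80/20 (by default) into training and validation.
#' Per-class proportions are preserved within one sample; the three parts
#' are disjoint and exhaustive.
#'
#' @param dataset A [beat_dataset()].
#' @param config A [train_config()] (uses `test_frac`, `val_frac`, `seed`).
#' @return List with `train`, `val`, `test` datasets (roles set).
#' @export
split_dataset <- function(dataset, config = train_config()) {
  stopifnot(inherits(dataset, "beat_dataset"))
  counts <- table(dataset$labels)
  if (any(counts < 5L)) {
    stop("every class must appear at least 5 times; classes ",
         paste(names(counts)[counts < 5], collapse = ", "),
         " are too small - generate or load more data")
  }
  lab <- as.character(dataset$labels)
  parts <- list(train = integer(), val = integer(), test = integer())
  with_seed(config$seed, {
    for (k in levels(dataset$labels)) {
      idx <- sample(which(lab == k))
      n_k <- length(idx)
      n_test <- round(n_k * config$test_frac)
      test_idx <- idx[seq_len(n_test)]
      rest <- idx[-seq_len(n_test)]
      n_val <- round(length(rest) * config$val_frac)
      val_idx <- rest[seq_len(n_val)]
      train_idx <- rest[-seq_len(n_val)]
      parts$train <- c(parts$train, train_idx)
      parts$val <- c(parts$val, val_idx)
      parts$test <- c(parts$test, test_idx)
    }
  })
  make <- function(role) {
    idx <- sort(parts[[role]])
    beat_dataset(dataset$beats[idx, , drop = FALSE], lab[idx],
                 provenance = c(dataset$provenance,
                                list(prov_step("split", role = role,
                                               seed = config$seed,
                                               test_frac = config$test_frac,
                                               val_frac = config$val_frac))),
                 role = role)
  }
  list(train = make("train"), val = make("val"), test = make("test"))
}

#' Cosine-annealed learning rate
#'
#' `eta_min + 0.5 * (lr0 - eta_min) * (1 + cos(pi * epoch / t_max))` for
#' `epoch` in `0..t_max` (so epoch 0 gives `lr0` and epoch `t_max` gives
#' `eta_min`); epochs beyond `t_max` clamp to `eta_min`.
#'
#' @param epoch Zero-based epoch index (vectorized).
#' @param config A [train_config()].
#' @return Learning rate(s).
#' @export
cosine_lr <- function(epoch, config = train_config()) {
  lr <- config$eta_min + 0.5 * (config$lr0 - config$eta_min) *
    (1 + cos(pi * epoch / config$t_max))
  lr[epoch > config$t_max] <- config$eta_min
  lr
}

#' Clip gradients by global norm
#'
#' If the L2 norm over all gradient arrays exceeds `max_norm`, every
#' gradient is scaled by `max_norm / global_norm`; otherwise gradients are
#' returned unchanged. The observed global norm is attached as attribute
#' `"global_norm"`.
#'
#' @param grads Named list of numeric arrays (or a single array).
#' @param max_norm Positive clip threshold.
#' @return The (possibly scaled) gradients.
#' @export
clip_gradients <- function(grads, max_norm) {
  stopifnot(max_norm > 0)
  single <- !is.list(grads)
  gl <- if (single) list(grads) else grads
  gn <- sqrt(sum(vapply(gl, function(g) sum(g^2), numeric(1))))
  if (is.finite(gn) && gn > max_norm) {
    gl <- lapply(gl, function(g) g * (max_norm / gn))
  }
  out <- if (single) gl[[1]] else gl
  attr(out, "global_norm") <- gn
  out
}

# One Adam step over a named parameter list (weight decay added to the
# gradient, bias-corrected moments).
adam_step <- function(params, grads, opt, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

labels_to_int0 <- function(labels) as.integer(labels) - 1L

# Cross-entropy and macro F1 of a model on a dataset (evaluation mode).
eval_loss_f1 <- function(model, dataset, batch_size = 1024L) {
  probs <- predict(model, dataset, type = "prob", batch_size = batch_size)
  y <- as.integer(dataset$labels)
  p_true <- probs[cbind(seq_along(y), y)]
  loss <- mean(-log(pmax(p_true, 1e-12)))
  pred <- factor(colnames(probs)[max.col(probs, ties.method = "first")],
                 levels = model$classes)
  cm <- confusion_matrix(dataset$labels, pred)
  f1 <- mean(vapply(model$classes,
                    function(k) class_metrics(cm, k)[["f1"]], numeric(1)))
  list(loss = loss, macro_f1 = f1)
}

#' Train a beat-classification model
#'
#' Minimizes cross-entropy with Adam (weight decay 1e-4), stepping the
#' cosine-annealing schedule once per epoch and clipping gradients at
#' global norm `clip_max_norm` every batch. When `config$balance` is
#' `"smote"` the training split is balanced first (validation and test
#' data are never balanced). Early stopping monitors validation loss; the
#' best-validation checkpoint is restored before returning. Fully
#' reproducible from the single master seed.
#'
#' @param train Training [beat_dataset()].
#' @param val Validation [beat_dataset()]; must not be balanced.
#' @param model_cfg A [model_config()].
#' @param config A [train_config()].
#' @return List with `model` (the trained [hctg_model()]) and `history`
#'   (data frame: epoch, train_loss, val_loss, lr, val_macro_f1).
#' @export
train_model <- function(train, val, model_cfg = model_config(),
                        config = train_config()) {
  stopifnot(inherits(train, "beat_dataset"), inherits(val, "beat_dataset"))
  if (nrow(train$beats) == 0L || nrow(val$beats) == 0L) {
    stop("empty training or validation split")
  }
  if (prov_has_step(val$provenance, "balance_smote")) {
    stop("validation data must never be balanced")
  }
  if (config$balance == "smote" &&
      !prov_has_step(train$provenance, "balance_smote")) {
    train <- smote_oversample(train,
                              smote_config(k_neighbors = config$smote_k,
                                           seed = child_seed(config$seed, 1L)))
  }
  model <- hctg_model(model_cfg, seed = child_seed(config$seed, 2L))
  vcode <- variant_code(model_cfg$variant)
  X <- train$beats
  y0 <- labels_to_int0(train$labels)
  n <- nrow(X)
  opt <- list(t = 0L,
              m = lapply(model$params, function(p) p * 0),
              v = lapply(model$params, function(p) p * 0))
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), lr = numeric(),
                        val_macro_f1 = numeric())
  best <- list(loss = Inf, params = model$params, state = model$state,
               epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    lr <- cosine_lr(epoch - 1L, config)
    ord <- with_seed(child_seed(config$seed, 100L + epoch), sample.int(n))
    starts <- seq(1L, n, by = config$batch_size)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
      res <- cpp_hctg_train_batch(model$params, model$state, model$pe,
                                  X[idx, , drop = FALSE], y0[idx], vcode,
                                  model_cfg$n_transformer_layers,
                                  model_cfg$n_heads,
                                  model_cfg$transformer_dropout,
                                  model_cfg$classifier_dropout,
                                  as.integer(child_seed(config$seed,
                                                        epoch * 1000L + bi)),
                                  config$bn_momentum)
      if (!is.finite(res$loss)) {
        stop(sprintf("non-finite training loss at epoch %d, batch %d",
                     epoch, bi))
      }
      losses[bi] <- res$loss
      grads <- clip_gradients(res$grads, config$clip_max_norm)
      upd <- adam_step(model$params, grads, opt, lr, config$weight_decay)
      model$params <- upd$params
      opt <- upd$opt
      model$state <- res$state
    }
    vm <- eval_loss_f1(model, val)
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = mean(losses),
                                val_loss = vm$loss, lr = lr,
                                val_macro_f1 = vm$macro_f1))
    if (vm$loss < best$loss - config$early_stop_min_delta) {
      best <- list(loss = vm$loss, params = model$params,
                   state = model$state, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stop_patience) break
    }
  }
  model$params <- best$params
  model$state <- best$state
  attr(history, "best_epoch") <- best$epoch
  list(model = model, history = history)
}

#' Save / load a trained model
#'
#' The checkpoint is an RDS container of the weights plus a JSON sidecar
#' with the architecture configuration.
#'
#' @param model An [hctg_model()].
#' @param path Checkpoint path (`.rds`).
#' @return `path` (save) or the restored model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "hctg_model"))
  saveRDS(model, path)
  jsonlite::write_json(model$config[names(model$config) != "class"],
                       paste0(path, ".config.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "hctg_model"))
  model
}
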