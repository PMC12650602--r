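test_that("confusion matrix counts true-by-predicted pairs in fixed class order", {
  y <- c("N", "N", "S"); p <- c("N", "S", "S")
  cm <- confusion_matrix(y, p)
  expect_equal(rownames(cm), c("N", "S", "V", "F", "Q"))
  expect_equal(cm["N", "N"], 1L)
  expect_equal(cm["N", "S"], 1L)
  expect_equal(cm["S", "S"], 1L)
  expect_equal(sum(cm), 3L)
  # identical vectors give a diagonal matrix
  y2 <- sample(aami_classes(), 50, replace = TRUE)
  cm2 <- confusion_matrix(y2, y2)
  expect_equal(cm2, diag(as.integer(table(factor(y2, aami_classes())))),
               ignore_attr = TRUE)
  # row sums equal true-class counts
  set.seed(3)
  yt <- sample(aami_classes(), 200, TRUE); yp <- sample(aami_classes(), 200, TRUE)
  cm3 <- confusion_matrix(yt, yp)
  expect_equal(rowSums(cm3), as.numeric(table(factor(yt, aami_classes()))),
               ignore_attr = TRUE)
  expect_error(confusion_matrix(c("N", "Z"), c("N", "N")), "Z")
})

test_that("per-class metrics implement precision, recall and their harmonic mean", {
  cm <- matrix(0L, 5, 5, dimnames = list(aami_classes(), aami_classes()))
  cm["N", "N"] <- 9L; cm["S", "N"] <- 1L; cm["N", "S"] <- 1L
  m <- class_metrics(cm, "N")
  expect_equal(unname(m), c(0.9, 0.9, 0.9), ignore_attr = TRUE)
  # precision == recall == p implies F1 == p (harmonic mean of equals)
  cm2 <- matrix(0L, 5, 5, dimnames = list(aami_classes(), aami_classes()))
  cm2["V", "V"] <- 3L; cm2["V", "N"] <- 1L; cm2["N", "V"] <- 1L; cm2["N", "N"] <- 5L
  mv <- class_metrics(cm2, "V")
  expect_equal(mv[["precision"]], mv[["recall"]])
  expect_equal(mv[["f1"]], mv[["precision"]])
  # absent class: 0/0 convention with flag
  mq <- class_metrics(cm2, "Q")
  expect_equal(unname(mq), c(0, 0, 0), ignore_attr = TRUE)
  expect_true(attr(mq, "undefined"))
})

test_that("macro and weighted aggregation follow their definitions", {
  per <- matrix(1, 5, 3, dimnames = list(NULL, c("precision", "recall", "f1")))
  per[, ] <- 0.8
  agg <- aggregate_metrics(per, c(10, 10, 10, 10, 10))
  expect_equal(unname(agg$macro), rep(0.8, 3))
  expect_equal(unname(agg$weighted), rep(0.8, 3))
  per2 <- per; per2[1, "f1"] <- 1.0; per2[2, "f1"] <- 0.5
  agg2 <- aggregate_metrics(per2[1:2, , drop = FALSE][c(1, 2, 1, 1, 1), ],
                            c(10, 10, 0, 0, 0))
  # equal supports: macro == weighted on the two populated classes
  expect_equal(unname(agg2$weighted["f1"]), 0.75)
  per3 <- per; per3[, "f1"] <- c(1.0, 0.5, 0, 0, 0)
  agg3 <- aggregate_metrics(per3, c(90, 10, 0, 0, 0))
  expect_equal(unname(agg3$weighted["f1"]), 0.95)
  expect_equal(unname(colMeans(per3)["f1"]), unname(agg3$macro["f1"]))
})

test_that("report metrics agree with an independent implementation", {
  skip_if_not_installed("caret")
  set.seed(9)
  classes <- aami_classes()
  for (rep_i in 1:10) {
    y <- factor(sample(classes, 120, TRUE), levels = classes)
    p <- factor(sample(classes, 120, TRUE), levels = classes)
    ours <- eval_report(y, p)
    ref <- caret::confusionMatrix(p, y, mode = "prec_recall")
    by <- ref$byClass
    for (k in seq_along(classes)) {
      refp <- by[k, "Precision"]; refr <- by[k, "Recall"]; reff <- by[k, "F1"]
      if (!is.na(refp)) expect_equal(ours$per_class$precision[k], unname(refp),
                                     tolerance = 1e-9)
      if (!is.na(refr)) expect_equal(ours$per_class$recall[k], unname(refr),
                                     tolerance = 1e-9)
      if (!is.na(reff)) expect_equal(ours$per_class$f1[k], unname(reff),
                                     tolerance = 1e-9)
    }
    expect_equal(ours$accuracy, unname(ref$overall["Accuracy"]),
                 tolerance = 1e-9)
    # algebraic identity: weighted recall equals accuracy
    expect_equal(unname(ours$weighted["recall"]), ours$accuracy,
                 tolerance = 1e-12)
    # macro between per-class extremes
    expect_gte(ours$macro[["f1"]], min(ours$per_class$f1))
    expect_lte(ours$macro[["f1"]], max(ours$per_class$f1))
  }
})

test_that("a perfect classifier and a constant predictor bound the report", {
  ds <- fix_dataset()
  model <- fix_model()
  # labels fed back as predictions: everything is 1
  perfect <- evaluate_model(model, ds, predictions = ds$labels)
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$per_class$f1 == 1))
  expect_equal(sum(diag(perfect$confusion)), perfect$n_samples)
  # constant predictor on balanced classes: accuracy is the class share
  const <- evaluate_model(model, ds,
                          predictions = factor(rep("N", nrow(ds$beats)),
                                               levels = aami_classes()))
  expect_equal(const$accuracy, 0.2)
})

test_that("accuracy can mask minority-class failure that macro F1 exposes", {
  classes <- aami_classes()
  y <- factor(c(rep("N", 95), "S", "V", "F", "Q", "S"), levels = classes)
  p <- factor(rep("N", 100), levels = classes)  # degenerate majority predictor
  rep_ <- eval_report(y, p)
  expect_gte(rep_$accuracy, 0.9)
  expect_lte(rep_$macro[["f1"]], 0.25)
})

test_that("balanced data is refused at evaluation time", {
  ds <- generate_dataset(8, rng_seed = 55)
  keep <- c(which(ds$labels == "N"), which(ds$labels == "S")[1:4])
  d <- beat_dataset(ds$beats[keep, ], ds$labels[keep], role = "train")
  bal <- smote_oversample(d)
  expect_error(evaluate_model(fix_model(), bal), "only to the training set")
})

test_that("accuracy equals the trace share for any report", {
  set.seed(12)
  for (i in 1:5) {
    y <- sample(aami_classes(), 80, TRUE)
    p <- sample(aami_classes(), 80, TRUE)
    r <- eval_report(y, p)
    expect_equal(r$accuracy, sum(diag(r$confusion)) / r$n_samples)
  }
})
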