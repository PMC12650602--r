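# Confusion matrix and the precision/recall/F1 metric suite with
# per-class, macro and support-weighted aggregation.

#' Confusion matrix over the five AAMI classes
#'
#' Entry (i, j) counts samples with true class i predicted as class j;
#' class order is fixed as (N, S, V, F, Q).
#'
#' @param y_true,y_pred Equal-length vectors of class labels.
#' @return Integer matrix `[5 x 5]` with dimnames `true` x `predicted`.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  classes <- aami_classes()
  bad <- setdiff(unique(c(as.character(y_true), as.character(y_pred))),
                 classes)
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  tt <- table(factor(as.character(y_true), levels = classes),
              factor(as.character(y_pred), levels = classes))
  m <- matrix(as.integer(tt), 5L, 5L,
              dimnames = list(true = classes, predicted = classes))
  m
}

#' Per-class precision, recall and F1
#'
#' One-vs-rest counts are read from the confusion matrix: precision =
#' TP/(TP+FP), recall = TP/(TP+FN), F1 their harmonic mean. A 0/0 case
#' returns 0 and sets the `undefined` attribute.
#'
#' @param confusion A 5x5 confusion matrix from [confusion_matrix()].
#' @param class Class name (or index) to score.
#' @return Named vector `(precision, recall, f1)`, with attribute
#'   `undefined` (logical: any 0/0 encountered).
#' @export
class_metrics <- function(confusion, class) {
  k <- if (is.character(class)) match(class, rownames(confusion)) else class
  if (is.na(k)) stop("unknown class: ", class)
  tp <- confusion[k, k]
  fp <- sum(confusion[, k]) - tp
  fn <- sum(confusion[k, ]) - tp
  undef <- FALSE
  div <- function(num, den) {
    if (den == 0) { undef <<- TRUE; 0 } else num / den
  }
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  f1 <- div(2 * precision * recall, precision + recall)
  structure(c(precision = precision, recall = recall, f1 = f1),
            undefined = undef)
}

#' Macro and weighted metric aggregation
#'
#' Macro averages are unweighted means over the five classes; weighted
#' averages weight each class by its support. Accuracy (total correct over
#' total) equals the support-weighted recall for single-label multiclass
#' data.
#'
#' @param per_class Matrix `[5 x 3]` of per-class (precision, recall, f1).
#' @param supports Integer 5-vector of true-class counts; must sum > 0.
#' @return List with `macro`, `weighted` (each a named triple) and
#'   `accuracy`.
#' @export
aggregate_metrics <- function(per_class, supports) {
  stopifnot(nrow(per_class) == length(supports))
  if (sum(supports) <= 0) stop("supports must sum to a positive count")
  w <- supports / sum(supports)
  macro <- colMeans(per_class)
  weighted <- colSums(per_class * w)
  accuracy <- sum(per_class[, "recall"] * supports) / sum(supports)
  list(macro = macro, weighted = weighted, accuracy = accuracy)
}

#' Evaluate a model on a held-out test set
#'
#' Runs batched inference in evaluation mode, builds the confusion matrix
#' and the full per-class / macro / weighted report. Balanced (resampled)
#' datasets are refused: class balancing is a training-set-only operation
#' and evaluating on synthetic beats would bias every metric.
#'
#' @param model An [hctg_model()].
#' @param test A [beat_dataset()] that has not been balanced.
#' @param predictions Optional precomputed factor of predictions (test
#'   hook); when given, inference is skipped.
#' @return An `eval_report`: confusion matrix, per-class metric table,
#'   macro/weighted triples, accuracy, `n_samples`.
#' @export
evaluate_model <- function(model, test, predictions = NULL) {
  stopifnot(inherits(test, "beat_dataset"))
  if (prov_has_step(test$provenance, "balance_smote")) {
    stop("refusing to evaluate on balanced data: ",
         "resampling is applied only to the training set")
  }
  pred <- predictions %||% predict(model, test, type = "class")
  eval_report(test$labels, pred)
}

#' Build an evaluation report from labels and predictions
#'
#' @param y_true,y_pred Label vectors over the five classes.
#' @return An `eval_report` object.
#' @export
eval_report <- function(y_true, y_pred) {
  cm <- confusion_matrix(y_true, y_pred)
  classes <- aami_classes()
  per <- t(vapply(classes, function(k) class_metrics(cm, k), numeric(3)))
  colnames(per) <- c("precision", "recall", "f1")
  undef <- vapply(classes,
                  function(k) isTRUE(attr(class_metrics(cm, k), "undefined")),
                  logical(1))
  supports <- rowSums(cm)
  agg <- aggregate_metrics(per, supports)
  structure(list(confusion = cm,
                 per_class = data.frame(class = classes, per,
                                        support = as.integer(supports),
                                        undefined = undef,
                                        row.names = NULL),
                 macro = agg$macro, weighted = agg$weighted,
                 accuracy = agg$accuracy, n_samples = sum(cm)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat(sprintf("Evaluation on %d beats\n\n", x$n_samples))
  tab <- x$per_class
  tab$precision <- round(tab$precision, digits)
  tab$recall <- round(tab$recall, digits)
  tab$f1 <- round(tab$f1, digits)
  print(tab[, c("class", "precision", "recall", "f1", "support")],
        row.names = FALSE)
  fm <- function(v) paste(formatC(v, digits = digits, format = "f"),
                          collapse = " ")
  cat("\nMacro Average    ", fm(x$macro), "\n", sep = "")
  cat("Weighted Average ", fm(x$weighted), "\n", sep = "")
  cat("Accuracy         ", fm(x$accuracy), "\n", sep = "")
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits `<name>.json` (full report), `<name>_confusion.csv` and a
#' human-readable `<name>.txt` table.
#'
#' @param report An `eval_report`.
#' @param dir Output directory.
#' @param name Basename for the three files.
#' @return The JSON path, invisibly.
#' @export
write_eval_report <- function(report, dir, name = "eval") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jpath <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(list(per_class = report$per_class,
                            macro = as.list(report$macro),
                            weighted = as.list(report$weighted),
                            accuracy = report$accuracy,
                            n_samples = report$n_samples),
                       jpath, auto_unbox = TRUE, digits = NA)
  write.csv(as.data.frame(report$confusion), file.path(dir, paste0(name, "_confusion.csv")))
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, paste0(name, ".txt")))
  invisible(jpath)
}
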