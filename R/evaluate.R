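#' Classification metrics from a confusion matrix
#'
#' Computes overall accuracy, per-class precision and sensitivity, and
#' balanced accuracy (the mean of the per-class sensitivities, robust to
#' class imbalance) from a C x C confusion matrix with true classes in
#' rows and predictions in columns. A class that receives no predictions
#' has undefined precision; it is reported as 0 and flagged.
#'
#' @param confusion a square numeric matrix of counts; rows are truth,
#'   columns predictions.
#' @return a list with `accuracy`, `balanced_accuracy`, `precision`,
#'   `sensitivity`, `undefined_precision` (logical per class) and the
#'   `confusion` matrix itself.
#' @examples
#' confusion_metrics(matrix(c(8, 4, 2, 6), 2))  # balanced accuracy 0.7
#' @export
confusion_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion), all(confusion >= 0))
  tp <- unname(diag(confusion))
  support <- unname(rowSums(confusion))
  predicted <- unname(colSums(confusion))
  sens <- ifelse(support > 0, tp / support, NA_real_)
  undef <- predicted == 0
  prec <- ifelse(undef, 0, tp / pmax(predicted, 1))
  list(accuracy = sum(tp) / sum(confusion),
       balanced_accuracy = mean(sens, na.rm = TRUE),
       precision = prec,
       sensitivity = sens,
       undefined_precision = undef,
       confusion = confusion)
}

#' Build an evaluation report from truth and prediction vectors
#'
#' @param truth,predicted label vectors of equal length.
#' @param classes optional class vocabulary fixing the confusion-matrix
#'   order; defaults to the sorted union of observed labels.
#' @return an object of class `"ebdl_eval"` (see [confusion_metrics()]
#'   for the fields).
#' @export
eval_report <- function(truth, predicted, classes = NULL) {
  stopifnot(length(truth) == length(predicted))
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  ti <- factor(truth, levels = classes)
  pi <- factor(predicted, levels = classes)
  cm <- table(truth = ti, predicted = pi)
  cm <- matrix(as.numeric(cm), nrow = length(classes),
               dimnames = list(truth = as.character(classes),
                               predicted = as.character(classes)))
  out <- confusion_metrics(cm)
  out$classes <- classes
  structure(out, class = "ebdl_eval")
}

#' @export
print.ebdl_eval <- function(x, digits = 3, ...) {
  cat(sprintf("<ebdl_eval>  accuracy %.3f   balanced accuracy %.3f\n",
              x$accuracy, x$balanced_accuracy))
  df <- data.frame(class = as.character(x$classes),
                   precision = round(x$precision, digits),
                   sensitivity = round(x$sensitivity, digits))
  if (any(x$undefined_precision)) {
    df$note <- ifelse(x$undefined_precision, "no predictions", "")
  }
  print(df, row.names = FALSE)
  invisible(x)
}

#' Evaluate a fitted model on labelled samples
#'
#' Predicts every sample with the model's decision rule (nearest proxy
#' across sub-views, or argmax logits for the cross-entropy baseline) and
#' summarizes the result as accuracy, balanced accuracy, and per-class
#' precision/sensitivity.
#'
#' @param object a fitted [ebdl()] model.
#' @param samples labelled samples (list of [tfr_sample()] or array).
#' @param labels optional label vector overriding the samples' own.
#' @return an `"ebdl_eval"` report.
#' @export
evaluate <- function(object, samples, labels = NULL) {
  stopifnot(inherits(object, "ebdl"))
  dat <- .as_tfr_array(samples, labels)
  pred <- predict(object, samples)
  eval_report(dat$labels, pred, classes = object$classes)
}

#' Select the number of sub-band filters on validation data
#'
#' Trains one model per candidate filter count and returns the count with
#' the highest validation metric (ties towards fewer filters), together
#' with a per-candidate report: validation accuracy, test accuracy (when
#' a test set is given) and the learned (mu, sigma) pairs.
#'
#' @param train,validation,test sample lists; `test` may be `NULL`.
#' @param candidates integer vector of filter counts to try.
#' @param ... further arguments passed to [ebdl()] (epochs, learning
#'   rates, seed, ...).
#' @return an object of class `"ebdl_sweep"`: list with `best` (the
#'   selected count), `report` (one row per candidate) and `models`.
#' @export
select_filter_count <- function(train, validation, test = NULL,
                                candidates = 1:6, ...) {
  stopifnot(length(candidates) >= 1L, all(candidates >= 1L))
  rows <- list(); models <- list()
  for (m in candidates) {
    fit <- ebdl(train, val = validation, n_filters = m, ...)
    vdat <- .as_tfr_array(validation)
    val_acc <- mean(predict(fit, validation) == vdat$labels)
    test_acc <- NA_real_
    if (!is.null(test)) {
      tdat <- .as_tfr_array(test)
      test_acc <- mean(predict(fit, test) == tdat$labels)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      filter_count = m,
      val_accuracy = val_acc,
      test_accuracy = test_acc,
      learned = paste(sprintf("(%.2f, %.2f)", fit$filters$mu,
                              fit$filters$sigma), collapse = "; "),
      stringsAsFactors = FALSE)
    models[[as.character(m)]] <- fit
  }
  report <- do.call(rbind, rows)
  best <- report$filter_count[which.max(report$val_accuracy)]
  structure(list(best = best, report = report, models = models),
            class = "ebdl_sweep")
}

#' @export
print.ebdl_sweep <- function(x, ...) {
  cat(sprintf("<ebdl_sweep> selected filter count: %d\n", x$best))
  print(x$report[, c("filter_count", "val_accuracy", "test_accuracy")],
        row.names = FALSE)
  invisible(x)
}
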