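#' Confusion matrix
#'
#' Tallies counts `n_ij` indexed by (true class i, predicted class j).
#'
#' @param true_labels,pred_labels Integer labels in `1..n_classes`.
#' @param n_classes Number of classes.
#' @param class_names Optional class names for the dimnames.
#' @return Object of class `thz_confusion`: integer matrix with
#'   attributes.
#' @export
confusion_matrix <- function(true_labels, pred_labels, n_classes,
                             class_names = NULL) {
  if (length(true_labels) != length(pred_labels))
    stop("label vectors must have equal length")
  labs <- c(true_labels, pred_labels)
  if (length(labs) && (any(labs < 1) || any(labs > n_classes) ||
                       any(labs != round(labs))))
    stop("labels must be integers in 1..", n_classes)
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(true_labels))
    cm[true_labels[i], pred_labels[i]] <- cm[true_labels[i], pred_labels[i]] + 1L
  if (!is.null(class_names)) dimnames(cm) <- list(true = class_names,
                                                  predicted = class_names)
  structure(cm, class = c("thz_confusion", "matrix"))
}

#' Overall accuracy from a confusion matrix
#'
#' `Acc = sum_i n_ii / sum_ij n_ij`.
#'
#' @param cm A [confusion_matrix()].
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(cm)) / total
}

#' Per-class precision
#'
#' `Pr_i = n_ii / sum_j n_ij`, normalized by the true-class row exactly
#' as defined alongside the accuracy metric.  (Note this row-normalized
#' form is what is elsewhere called recall or sensitivity; it is kept in
#' the printed form for comparability.)  Classes with an empty row are
#' reported as `NA`.
#'
#' @param cm A [confusion_matrix()].
#' @return Named numeric vector of per-class values in `[0, 1]` or `NA`.
#' @export
precision_per_class <- function(cm) {
  rs <- rowSums(cm)
  pr <- ifelse(rs > 0, diag(as.matrix(cm)) / rs, NA_real_)
  names(pr) <- rownames(cm)
  pr
}

#' Evaluate a model on a dataset split
#'
#' Predicts, tallies the confusion matrix, and computes accuracy and
#' per-class precision.  Optionally measures throughput
#' (items/second), reported for information only.
#'
#' @param model A `thz_ecanet`.
#' @param dataset Split list with `x` and `y` (from
#'   [assemble_datasets()]).
#' @param class_names Optional class names.
#' @param measure_fps Also time the forward passes.
#' @return Object of class `thz_eval`: list with `accuracy`,
#'   `per_class`, `confusion`, `split_tag`, `n_items`, and optionally
#'   `throughput_fps`.
#' @export
evaluate_model <- function(model, dataset, class_names = NULL,
                           measure_fps = FALSE) {
  if (!length(dataset$y)) stop("empty dataset")
  if (max(dataset$y) > model$cfg$n_classes)
    stop("dataset has more classes than the model")
  t0 <- Sys.time()
  pr <- predict(model, dataset$x)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  cm <- confusion_matrix(dataset$y, pr$class, model$cfg$n_classes,
                         class_names)
  out <- list(accuracy = accuracy(cm), per_class = precision_per_class(cm),
              confusion = cm, split_tag = dataset$split_tag,
              n_items = length(dataset$y))
  if (measure_fps) out$throughput_fps <- length(dataset$y) / elapsed
  structure(out, class = "thz_eval")
}

#' @export
print.thz_eval <- function(x, ...) {
  cat("<thz_eval>", x$split_tag %||% "", "-", x$n_items, "items\n")
  cat("  accuracy:", sprintf("%.4f", x$accuracy), "\n")
  pc <- x$per_class
  cat("  per-class precision:",
      paste(sprintf("%.3f", unname(pc)), collapse = " "), "\n")
  if (!is.null(x$throughput_fps))
    cat("  throughput:", round(x$throughput_fps, 1), "items/s (informational)\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
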