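# Confusion matrix, accuracy, per-class precision and recall, Friedman's
# test over repeated cross-validation runs, and the hybrid-vs-single-kernel
# comparison protocol.

#' Confusion matrix
#'
#' Entry `(i, j)` counts rows whose actual class is `i` and predicted class
#' is `j` (rows = actual, columns = predicted).
#'
#' @param y_true,y_pred integer labels in `0..n_classes-1`.
#' @param n_classes number of classes; defaults to the largest label + 1.
#' @return An `n_classes` x `n_classes` integer matrix.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = NULL) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop_hksvm("label lengths differ")
  n_classes <- as.integer(n_classes %||% (max(y_true, y_pred) + 1L))
  if (any(c(y_true, y_pred) < 0) || any(c(y_true, y_pred) >= n_classes)) {
    stop_hksvm("labels out of range 0..", n_classes - 1L)
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  cm
}

#' Per-class precision from a confusion matrix
#'
#' Precision of class j is `TP / (TP + FP)`: the diagonal entry divided by
#' the column sum. A class never predicted has an undefined ratio and is
#' reported as 0 with a warning.
#'
#' @param confusion square confusion matrix (rows = actual).
#' @return Numeric vector of per-class precisions in `[0, 1]`.
#' @export
precision_per_class <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop_hksvm("confusion must be square")
  cs <- colSums(confusion)
  if (any(cs == 0)) {
    warning("some classes were never predicted; reporting precision 0",
            call. = FALSE)
  }
  ifelse(cs > 0, diag(confusion) / cs, 0)
}

#' Per-class recall from a confusion matrix
#'
#' Recall of class i is `TP / (TP + FN)`: the diagonal entry divided by the
#' row sum. A class absent from the evaluated rows is reported as 0 with a
#' warning.
#'
#' @inheritParams precision_per_class
#' @return Numeric vector of per-class recalls in `[0, 1]`.
#' @export
recall_per_class <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop_hksvm("confusion must be square")
  rs <- rowSums(confusion)
  if (any(rs == 0)) {
    warning("some classes are absent from the evaluated rows; reporting recall 0",
            call. = FALSE)
  }
  ifelse(rs > 0, diag(confusion) / rs, 0)
}

#' Full evaluation report
#'
#' Confusion matrix with derived accuracy (percent) and per-class precision
#' and recall.
#'
#' @inheritParams confusion_matrix
#' @param class_names optional class vocabulary.
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(y_true, y_pred, class_names = NULL) {
  n_classes <- if (!is.null(class_names)) length(class_names) else NULL
  cm <- confusion_matrix(y_true, y_pred, n_classes)
  class_names <- class_names %||% as.character(seq_len(nrow(cm)) - 1L)
  dimnames(cm) <- list(actual = class_names, predicted = class_names)
  structure(list(confusion = cm,
                 accuracy = 100 * sum(diag(cm)) / sum(cm),
                 precision_per_class = suppressWarnings(precision_per_class(cm)),
                 recall_per_class = suppressWarnings(recall_per_class(cm)),
                 class_names = class_names),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat(sprintf("Accuracy: %.2f%% (n = %d)\n", x$accuracy, sum(x$confusion)))
  cat("Confusion matrix (rows = actual, columns = predicted):\n")
  print(x$confusion)
  tab <- data.frame(class = x$class_names,
                    precision = round(x$precision_per_class, digits),
                    recall = round(x$recall_per_class, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Friedman's test across matched classifier runs
#'
#' Ranks the models within each run (mean ranks for ties) and computes the
#' Friedman chi-square statistic with `models - 1` degrees of freedom and
#' its upper-tail p-value, with tie correction, via
#' [stats::friedman.test()]. The fully tied case (all models identical in
#' every run) is reported as statistic 0 with p-value 1.
#'
#' @param accuracies numeric runs x models matrix (each row one matched
#'   run).
#' @return A list with `statistic`, `df`, `p_value` and `mean_ranks`.
#' @export
friedman_compare <- function(accuracies) {
  accuracies <- as.matrix(accuracies)
  if (ncol(accuracies) < 2) stop_hksvm("need at least 2 models (columns)")
  if (nrow(accuracies) < 2) stop_hksvm("need at least 2 runs (rows)")
  ranks <- t(apply(accuracies, 1, rank))
  mean_ranks <- colMeans(ranks)
  if (all(apply(accuracies, 1, function(r) length(unique(r)) == 1))) {
    return(list(statistic = 0, df = ncol(accuracies) - 1L, p_value = 1,
                mean_ranks = mean_ranks))
  }
  ft <- stats::friedman.test(accuracies)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p_value = ft$p.value, mean_ranks = mean_ranks)
}

#' Compare the tuned hybrid against single-kernel baselines
#'
#' Runs the protocol used to judge whether the hybrid kernel beats its
#' ingredients: the GA-tuned hybrid and each single-kernel SVM (RBF, linear,
#' polynomial) are scored by `runs` repetitions of k-fold cross-validation
#' with distinct fold seeds (shared across models within a run, so runs are
#' matched blocks), and the accuracies are compared with Friedman's test.
#' Wall-clock training time per model is recorded but is hardware dependent
#' and never part of any assertion.
#'
#' @param x numeric feature matrix.
#' @param y integer labels in `0..C-1`.
#' @param control a [ga_control()] object for the hybrid's tuning step.
#' @param kernel_params a [kernel_params()] object (default gammas `1/d`).
#' @param C box constraint.
#' @param runs repetitions of k-fold cross-validation (default 10).
#' @param folds folds per run (default 5).
#' @param seed master seed; per-run fold seeds derive from it.
#' @return An object of class `hksvm_comparison` with `accuracies` (runs x 4
#'   matrix, columns hybrid/rbf/linear/polynomial), `friedman` (NULL when
#'   `runs < 2`), `runtimes`, and `best_weights`.
#' @export
run_comparison <- function(x, y, control = ga_control(), kernel_params = NULL,
                           C = 1, runs = 10, folds = 5, seed = 1) {
  x <- as.matrix(x); y <- as.integer(y)
  kernel_params <- kernel_params %||% kernel_params(d = ncol(x))
  t0 <- proc.time()[["elapsed"]]
  tuned <- tune_hksvm(x, y, control = control, kernel_params = kernel_params,
                      C = C, folds = folds,
                      fold_seed = derive_seed(seed, 1))
  t_tune <- proc.time()[["elapsed"]] - t0
  models <- list(hybrid = tuned$best_weights,
                 rbf = single_kernel_weights("rbf"),
                 linear = single_kernel_weights("linear"),
                 polynomial = single_kernel_weights("polynomial"))
  acc <- matrix(NA_real_, runs, length(models),
                dimnames = list(NULL, names(models)))
  runtimes <- c(hybrid = t_tune, rbf = 0, linear = 0, polynomial = 0)
  for (r in seq_len(runs)) {
    fold_seed <- derive_seed(seed, r + 1L)
    for (m in names(models)) {
      t0 <- proc.time()[["elapsed"]]
      cv <- cross_validate(x, y, weights = models[[m]],
                           kernel_params = kernel_params,
                           C = if (m == "hybrid") tuned$best_C else C,
                           folds = folds, seed = fold_seed)
      runtimes[m] <- runtimes[m] + proc.time()[["elapsed"]] - t0
      acc[r, m] <- cv$mean_accuracy
    }
  }
  structure(list(accuracies = acc,
                 friedman = if (runs >= 2) friedman_compare(acc) else NULL,
                 runtimes = runtimes, best_weights = tuned$best_weights,
                 tuning = tuned, runs = runs, folds = folds, seed = seed),
            class = "hksvm_comparison")
}

#' @export
print.hksvm_comparison <- function(x, ...) {
  cat(sprintf("Hybrid vs single-kernel comparison (%d runs of %d-fold CV)\n",
              x$runs, x$folds))
  cat("Mean CV accuracy (%):\n")
  print(round(colMeans(x$accuracies), 2))
  if (!is.null(x$friedman)) {
    cat(sprintf("Friedman chi-square = %.3f (df = %d), p = %.4g\n",
                x$friedman$statistic, x$friedman$df, x$friedman$p_value))
  } else {
    cat("Friedman test undefined for a single run\n")
  }
  invisible(x)
}
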