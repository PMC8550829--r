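# Soft-margin SVM training and prediction on precomputed Gram matrices.
#
# Binary subproblems are solved in the dual by the package's compiled SMO
# routine (maximal-violating-pair working-set selection); multiclass is
# one-vs-one with majority voting and ties broken towards the smallest class
# index, matching the behaviour of the common precomputed-kernel solvers.

#' Train an SVM on a precomputed Gram matrix
#'
#' Solves the soft-margin dual for every unordered class pair on the
#' training-by-training Gram matrix. Within each pair the class with the
#' smaller index plays the positive role, so a decision value of exactly
#' zero votes for the smaller index.
#'
#' @param K square training Gram matrix (symmetric PSD within tolerance).
#' @param y integer labels in `0..C-1` (or a factor, converted in level
#'   order).
#' @param C positive box constraint (regularization strength).
#' @param tol SMO stopping tolerance on the KKT gap (default 1e-3).
#' @param psd_action what to do about an indefinite `K`: `"ignore"` (no
#'   check; the default, since callers typically validate once), `"warn"`,
#'   `"fail"`, or `"shift"` (add `|min eigenvalue|` to the diagonal).
#' @param psd_tol eigenvalue tolerance for the PSD check.
#' @return An object of class `svm_precomputed` holding, per class pair, the
#'   signed dual coefficients (each of magnitude at most `C`, summing to 0),
#'   the intercept, and the indices of its training rows.
#' @export
svm_train_precomputed <- function(K, y, C = 1, tol = 1e-3,
                                  psd_action = c("ignore", "warn", "fail", "shift"),
                                  psd_tol = 1e-8) {
  psd_action <- match.arg(psd_action)
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop_hksvm("training Gram must be square")
  if (C <= 0) stop_hksvm("C must be positive")
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (length(y) != nrow(K)) stop_hksvm("length(y) must match nrow(K)")
  classes <- sort(unique(y))
  if (length(classes) < 2) stop_hksvm("need at least 2 classes")

  if (psd_action != "ignore") {
    chk <- check_psd(K, psd_tol)
    if (!chk$psd) {
      msg <- sprintf("Gram matrix is indefinite (min eigenvalue %.3g)",
                     chk$min_eigenvalue)
      if (psd_action == "fail") stop_hksvm(msg)
      if (psd_action == "warn") warning(msg, call. = FALSE)
      if (psd_action == "shift") {
        K <- K + diag(abs(chk$min_eigenvalue), nrow(K))
      }
    }
  }

  pairs <- list()
  for (a in seq_along(classes)) {
    for (b in seq_along(classes)) {
      if (b <= a) next
      ci <- classes[a]; cj <- classes[b]
      idx <- which(y %in% c(ci, cj))
      ysub <- ifelse(y[idx] == ci, 1L, -1L) # smaller class index is positive
      fit <- smo_solve(K[idx, idx, drop = FALSE], ysub, C, tol, 200000L)
      pairs[[length(pairs) + 1L]] <- list(
        class_pos = ci, class_neg = cj, idx = idx,
        coefs = fit$alpha * ysub, b = fit$b,
        iterations = fit$iterations, kkt_gap = fit$kkt_gap)
    }
  }
  structure(list(pairs = pairs, classes = classes, C = C,
                 n_train = nrow(K)),
            class = "svm_precomputed")
}

#' Decision values of a precomputed-kernel SVM
#'
#' @param model an `svm_precomputed` object.
#' @param K_test_train Gram matrix between test rows (rows) and the original
#'   training rows (columns, in training order).
#' @return A matrix with one column per class pair of values
#'   `sum_i coef_i K(x, x_i) + b`.
#' @export
svm_decision_precomputed <- function(model, K_test_train) {
  stopifnot(inherits(model, "svm_precomputed"))
  if (is.null(dim(K_test_train))) {
    K_test_train <- matrix(K_test_train, nrow = 1)
  }
  if (ncol(K_test_train) != model$n_train) {
    stop_hksvm("K_test_train must have one column per training row (",
               model$n_train, ")")
  }
  dec <- vapply(model$pairs, function(p) {
    as.numeric(K_test_train[, p$idx, drop = FALSE] %*% p$coefs) + p$b
  }, numeric(nrow(K_test_train)))
  dec <- matrix(dec, nrow = nrow(K_test_train))
  colnames(dec) <- vapply(model$pairs, function(p) {
    paste0(p$class_pos, "/", p$class_neg)
  }, character(1))
  dec
}

#' Predict classes from a precomputed Gram matrix
#'
#' One-vs-one majority vote over the per-pair decision functions; a decision
#' value `>= 0` votes for the pair's positive (smaller-index) class, and
#' vote ties are broken towards the smallest class index.
#'
#' @inheritParams svm_decision_precomputed
#' @param type `"class"` for labels, `"votes"` for the vote tally matrix.
#' @return Integer labels drawn from the model's classes, or a vote matrix.
#' @export
svm_predict_precomputed <- function(model, K_test_train,
                                    type = c("class", "votes")) {
  type <- match.arg(type)
  dec <- svm_decision_precomputed(model, K_test_train)
  m <- nrow(dec)
  votes <- matrix(0L, m, length(model$classes),
                  dimnames = list(NULL, model$classes))
  for (p in seq_along(model$pairs)) {
    pos <- match(model$pairs[[p]]$class_pos, model$classes)
    neg <- match(model$pairs[[p]]$class_neg, model$classes)
    win <- ifelse(dec[, p] >= 0, pos, neg)
    for (cl in unique(win)) {
      votes[win == cl, cl] <- votes[win == cl, cl] + 1L
    }
  }
  if (type == "votes") return(votes)
  model$classes[apply(votes, 1, which.max)] # which.max ties -> smallest index
}

#' @export
print.svm_precomputed <- function(x, ...) {
  nsv <- sum(vapply(x$pairs, function(p) sum(p$coefs != 0), numeric(1)))
  cat(sprintf(
    "<svm_precomputed> %d classes, %d pairwise machines, C = %g, %d SV slots\n",
    length(x$classes), length(x$pairs), x$C, nsv))
  invisible(x)
}

# ---- user-facing model ------------------------------------------------------

#' Fit a hybrid-kernel SVM
#'
#' Trains a soft-margin SVM with the hybrid kernel
#' `Kh = alpha1 K1 + alpha2 K2 + alpha3 K3` (pairwise mixes of the linear,
#' RBF and polynomial kernels) on a numeric feature matrix. Training rows
#' are retained in the fitted object because prediction with a precomputed
#' kernel requires kernel values between new rows and the training rows.
#'
#' @param x numeric feature matrix (n x d), or a formula.
#' @param y labels: integers in `0..C-1`, or a factor (converted in level
#'   order).
#' @param weights a [hybrid_weights()] object; default is the uniform
#'   mixture `(1/3, 1/3, 1/3)` with `mix_gamma = 0.5`. Use [tune_hksvm()] to
#'   search them.
#' @param kernel_params a [kernel_params()] object; defaults to gammas of
#'   `1/ncol(x)`.
#' @param C positive box constraint (default 1).
#' @param data,... formula-method data frame and further arguments.
#' @return An object of class `hksvm` with [predict()], [print()],
#'   [summary()], [coef()] (the kernel weights) and [fitted()] methods.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 3), 20))
#' y <- rep(0:1, each = 20)
#' fit <- hksvm(x, y)
#' mean(predict(fit, x) == y)
#' @export
hksvm <- function(x, ...) UseMethod("hksvm")

#' @rdname hksvm
#' @export
hksvm.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  out <- hksvm.default(X, y, ...)
  out$terms <- attr(mf, "terms")
  out
}

#' @rdname hksvm
#' @export
hksvm.default <- function(x, y, weights = hybrid_weights(1/3, 1/3, 1/3, 0.5),
                          kernel_params = NULL, C = 1, ...) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  class_names <- NULL
  if (is.factor(y)) {
    class_names <- levels(y)
    y <- as.integer(y) - 1L
  } else if (is.character(y)) {
    class_names <- sort(unique(y))
    y <- match(y, class_names) - 1L
  }
  y <- as.integer(y)
  kernel_params <- kernel_params %||% kernel_params(d = ncol(x))
  K <- hybrid_gram(x, weights = weights, params = kernel_params)
  svm <- svm_train_precomputed(K, y, C = C, ...)
  fitted_y <- svm_predict_precomputed(svm, K)
  structure(list(x_train = x, y_train = y, weights = weights,
                 kernel_params = kernel_params, C = C, svm = svm,
                 fitted_labels = fitted_y,
                 class_names = class_names %||%
                   as.character(sort(unique(y)))),
            class = "hksvm")
}

#' @export
predict.hksvm <- function(object, newdata, type = c("class", "votes", "decision"),
                          ...) {
  type <- match.arg(type)
  if (missing(newdata)) newdata <- object$x_train
  if (!is.null(object$terms) && is.data.frame(newdata)) {
    tt <- stats::delete.response(object$terms)
    mm <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
    newdata <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  }
  newdata <- as.matrix(newdata)
  K <- hybrid_gram(newdata, object$x_train, weights = object$weights,
                   params = object$kernel_params)
  switch(type,
    class = svm_predict_precomputed(object$svm, K),
    votes = svm_predict_precomputed(object$svm, K, type = "votes"),
    decision = svm_decision_precomputed(object$svm, K))
}

#' @export
coef.hksvm <- function(object, ...) as.numeric(object$weights)

#' @export
fitted.hksvm <- function(object, ...) object$fitted_labels

#' @export
print.hksvm <- function(x, ...) {
  cat("Hybrid-kernel SVM\n")
  cat(sprintf("  n = %d, d = %d, classes = %d, C = %g\n",
              nrow(x$x_train), ncol(x$x_train), length(x$svm$classes), x$C))
  cat(sprintf("  weights: alpha = (%.4f, %.4f, %.4f), mix_gamma = %.4f\n",
              x$weights$alpha1, x$weights$alpha2, x$weights$alpha3,
              x$weights$mix_gamma))
  cat(sprintf("  training accuracy: %.2f%%\n",
              100 * mean(x$fitted_labels == x$y_train)))
  invisible(x)
}

#' @export
summary.hksvm <- function(object, ...) {
  rep <- eval_report(object$y_train, object$fitted_labels,
                     object$class_names)
  out <- list(fit = object, training_report = rep)
  class(out) <- "summary.hksvm"
  out
}

#' @export
print.summary.hksvm <- function(x, ...) {
  print(x$fit)
  cat("\nTraining-set evaluation (resubstitution):\n")
  print(x$training_report)
  invisible(x)
}

# ---- cross-validation -------------------------------------------------------

#' Stratified fold assignment
#'
#' Deals each class's shuffled rows round-robin over `k` folds, so per-class
#' fold sizes differ by at most one.
#'
#' @param y integer labels in `0..C-1`.
#' @param k number of folds.
#' @param seed integer seed.
#' @param stratified stratify by class (default `TRUE`).
#' @return An integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(y, k, seed, stratified = TRUE) {
  y <- as.integer(y)
  n <- length(y)
  folds <- integer(n)
  with_seed(seed, {
    if (stratified) {
      for (cl in unique(y)) {
        rows <- which(y == cl)
        rows <- rows[sample.int(length(rows))]
        folds[rows] <- rep_len(seq_len(k), length(rows))
      }
    } else {
      folds <- rep_len(seq_len(k), n)[sample.int(n)]
    }
  })
  folds
}

cv_from_grams <- function(base, y, folds_idx, w, C, literal_signed = FALSE) {
  K <- combine_grams(base, w, literal_signed)
  k <- max(folds_idx)
  acc <- vapply(seq_len(k), function(f) {
    tr <- which(folds_idx != f); va <- which(folds_idx == f)
    m <- svm_train_precomputed(K[tr, tr, drop = FALSE], y[tr], C = C)
    pred <- svm_predict_precomputed(m, K[va, tr, drop = FALSE])
    100 * mean(pred == y[va])
  }, numeric(1))
  acc
}

#' Cross-validated accuracy of a hybrid-kernel SVM
#'
#' Splits the rows into `folds` stratified folds, and for each fold trains
#' on the remainder and scores on the held-out fold; the hybrid Gram blocks
#' used are only those between the relevant training and validation rows.
#' Accuracies are reported in percent.
#'
#' @param x numeric feature matrix.
#' @param y integer labels in `0..C-1`.
#' @param weights a [hybrid_weights()] object.
#' @param kernel_params a [kernel_params()] object (default gammas `1/d`).
#' @param C box constraint.
#' @param folds number of folds (default 5). If some class has fewer members
#'   than `folds`, the fold count is reduced with a warning.
#' @param seed fold-assignment seed.
#' @param stratified stratify folds by class (default `TRUE`).
#' @return An object of class `hksvm_cv` with `fold_accuracies` (percent),
#'   `mean_accuracy`, `fold_assignments`, `folds` and `seed`.
#' @export
cross_validate <- function(x, y, weights = hybrid_weights(1/3, 1/3, 1/3, 0.5),
                           kernel_params = NULL, C = 1, folds = 5, seed = 1,
                           stratified = TRUE) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (folds < 2) stop_hksvm("folds must be at least 2")
  counts <- table(y)
  if (min(counts) < 2) stop_hksvm("every class needs at least 2 members")
  if (min(counts) < folds) {
    folds <- as.integer(min(counts))
    warning(sprintf("smallest class has %d members; reducing to %d folds",
                    min(counts), folds), call. = FALSE)
  }
  kernel_params <- kernel_params %||% kernel_params(d = ncol(x))
  base <- base_grams(x, x, kernel_params)
  folds_idx <- make_folds(y, folds, seed, stratified)
  acc <- cv_from_grams(base, y, folds_idx, weights, C)
  structure(list(fold_accuracies = acc, mean_accuracy = mean(acc),
                 fold_assignments = folds_idx, folds = folds, seed = seed),
            class = "hksvm_cv")
}

#' @export
print.hksvm_cv <- function(x, ...) {
  cat(sprintf("<hksvm_cv> %d-fold CV accuracy: %.2f%% (folds: %s)\n",
              x$folds, x$mean_accuracy,
              paste(sprintf("%.1f", x$fold_accuracies), collapse = ", ")))
  invisible(x)
}
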