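# End-to-end orchestration: load -> encode -> downsample -> split -> impute
# -> scale -> PCA -> (svmlight export) -> GA tuning -> final training on the
# full training split -> held-out evaluation. All stage seeds derive from
# one master seed through derive_seed(), so runs are reproducible and adding
# a stage never reshuffles the others.

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run. Defaults follow the package's
#' standard protocol: one-hot encoding, median/mode imputation,
#' standardization, stratified 80/20 split, PCA to 95% explained variance
#' fitted on the training split, 5-fold cross-validation fitness, C = 1.
#'
#' @param encoding `"onehot"` or `"ordinal"`.
#' @param scaling `"standardize"`, `"minmax"`, or `"none"`.
#' @param train_fraction training fraction of the split (default 0.8).
#' @param stratified stratify the split and folds (default `TRUE`).
#' @param target_per_class optional cap on instances per class, applied
#'   before splitting (rebalancing downsample); `NULL` disables.
#' @param ranges optional named list of `c(min, max)` valid ranges per
#'   column; out-of-range rows are dropped.
#' @param pca_threshold explained-variance retention target in (0, 1], or
#'   `NULL` to skip PCA.
#' @param paper_order if `TRUE`, PCA is fitted on the full dataset before
#'   splitting (the fidelity ordering; a leakage risk). Default `FALSE`:
#'   PCA is fitted on the training split only.
#' @param kernel_params a [kernel_params()] or `NULL` for `1/d` gammas after
#'   reduction.
#' @param ga a [ga_control()] for the tuning stage.
#' @param C box constraint (default 1).
#' @param folds cross-validation folds (default 5).
#' @param runs repetitions for comparison mode (default 10).
#' @param svmlight_export `"none"`, `"write"` (export train/test files), or
#'   `"strict"` (also re-read them and continue from the re-read matrices,
#'   proving format fidelity).
#' @param output_dir directory for exported artifacts (`NULL`: no files).
#' @param seed master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(encoding = "onehot", scaling = "standardize",
                            train_fraction = 0.8, stratified = TRUE,
                            target_per_class = NULL, ranges = NULL,
                            pca_threshold = 0.95, paper_order = FALSE,
                            kernel_params = NULL, ga = ga_control(),
                            C = 1, folds = 5, runs = 10,
                            svmlight_export = c("none", "write", "strict"),
                            output_dir = NULL, seed = 1) {
  structure(list(encoding = encoding, scaling = scaling,
                 train_fraction = train_fraction, stratified = stratified,
                 target_per_class = target_per_class, ranges = ranges,
                 pca_threshold = pca_threshold,
                 paper_order = isTRUE(paper_order),
                 kernel_params = kernel_params, ga = ga, C = C,
                 folds = folds, runs = runs,
                 svmlight_export = match.arg(svmlight_export),
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `ga` key
#' holds [ga_control()] arguments and `kernel_params` holds
#' [kernel_params()] arguments.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$ga)) cfg$ga <- do.call(ga_control, cfg$ga)
  if (!is.null(cfg$kernel_params)) {
    cfg$kernel_params <- do.call(kernel_params, cfg$kernel_params)
  }
  do.call(pipeline_config, cfg)
}

load_stage <- function(input, label_column, config) {
  if (inherits(input, "raw_table")) return(input)
  if (inherits(input, "tabular_dataset")) return(input)
  if (is.character(input) && length(input) == 1) {
    if (grepl("\\.(svm|svmlight|libsvm)$", input)) {
      return(read_svmlight(input))
    }
    return(read_csv_dataset(input, label_column))
  }
  stop_hksvm("input must be a file path, raw_table, or tabular_dataset")
}

prepare_split <- function(input, label_column, config) {
  raw <- load_stage(input, label_column, config)
  ds <- if (inherits(raw, "tabular_dataset")) raw
        else encode_categoricals(raw, config$encoding)
  if (!is.null(config$ranges)) ds <- filter_ranges(ds, config$ranges)
  if (!is.null(config$target_per_class)) {
    ds <- downsample_classes(ds, config$target_per_class,
                             derive_seed(config$seed, 2))
  }
  if (length(unique(ds$labels)) < 2) {
    stop_hksvm("dataset has a single class; nothing to classify")
  }

  if (config$paper_order && !is.null(config$pca_threshold)) {
    # fidelity ordering: impute/scale/PCA on the full table, then split
    ds_full <- impute_missing(ds)
    ds_full <- scale_features(ds_full, config$scaling)
    pca <- fit_pca(ds_full$features, config$pca_threshold)
    scores <- transform_pca(pca, ds_full$features)
    red <- tabular_dataset(scores, ds_full$labels,
                           paste0("PC", seq_len(ncol(scores))),
                           ds_full$class_names)
    split <- shuffle_split(red, derive_seed(config$seed, 3),
                           config$train_fraction, config$stratified)
    return(list(split = split, pca = pca))
  }

  split <- shuffle_split(ds, derive_seed(config$seed, 3),
                         config$train_fraction, config$stratified)
  train <- impute_missing(split$train)
  test <- impute_missing(split$test, values = attr(train, "impute_values"))
  train <- scale_features(train, config$scaling)
  test <- scale_features(test, state = attr(train, "scaler"))
  pca <- NULL
  if (!is.null(config$pca_threshold)) {
    pca <- fit_pca(train$features, config$pca_threshold)
    train <- tabular_dataset(transform_pca(pca, train$features),
                             train$labels,
                             paste0("PC", seq_len(pca$k)), train$class_names)
    test <- tabular_dataset(transform_pca(pca, test$features), test$labels,
                            paste0("PC", seq_len(pca$k)), test$class_names)
  }
  list(split = list(train = train, test = test,
                    train_idx = split$train_idx, test_idx = split$test_idx),
       pca = pca)
}

export_svmlight_stage <- function(train, test, config) {
  if (config$svmlight_export == "none" || is.null(config$output_dir)) {
    return(list(train = train, test = test, files = NULL))
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  f_tr <- file.path(config$output_dir, "train.svmlight")
  f_te <- file.path(config$output_dir, "test.svmlight")
  write_svmlight(train, f_tr)
  write_svmlight(test, f_te)
  if (config$svmlight_export == "strict") {
    tr2 <- read_svmlight(f_tr); te2 <- read_svmlight(f_te)
    train <- tabular_dataset(tr2$features, tr2$labels,
                             train$feature_names, train$class_names)
    test <- tabular_dataset(te2$features, te2$labels,
                            test$feature_names, test$class_names)
  }
  list(train = train, test = test, files = c(f_tr, f_te))
}

#' Run the full diagnostic pipeline
#'
#' Executes the end-to-end protocol on one dataset: load, encode, optional
#' rebalancing downsample, stratified 80/20 split, imputation and scaling
#' fitted on the training split, PCA to the explained-variance target,
#' optional svmlight export, GA tuning of the hybrid-kernel weights by
#' cross-validated fitness, final training on the whole training split with
#' the tuned weights, and evaluation on the held-out test split.
#'
#' @param input a CSV/svmlight path, [raw_table()], or [tabular_dataset()].
#' @param label_column label column name (CSV input only).
#' @param config a [pipeline_config()].
#' @return An object of class `hksvm_run` with the fitted `pca`, `tuning`
#'   ([tune_hksvm()] result), final `model` ([hksvm()] fit), `report`
#'   ([eval_report()] on the test split), `train_cv` (post-tuning CV of the
#'   final weights), stage `timings`, and a config echo.
#' @export
run_pipeline <- function(input, label_column = "class",
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- c()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[name] <<- proc.time()[["elapsed"]] - t0
    out
  }
  prep <- tick("prepare", prepare_split(input, label_column, config))
  train <- prep$split$train; test <- prep$split$test
  exp <- tick("svmlight", export_svmlight_stage(train, test, config))
  train <- exp$train; test <- exp$test
  kp <- config$kernel_params %||% kernel_params(d = ncol(train$features))

  ga_ctrl <- config$ga
  ga_ctrl$seed <- derive_seed(config$seed, 4)
  tuning <- tick("ga", tune_hksvm(train$features, train$labels,
                                  control = ga_ctrl, kernel_params = kp,
                                  C = config$C, folds = config$folds,
                                  fold_seed = derive_seed(config$seed, 5)))
  # CV of the tuned weights after the search (same folds as the fitness)
  train_cv <- cross_validate(train$features, train$labels,
                             weights = tuning$best_weights,
                             kernel_params = kp, C = tuning$best_C,
                             folds = config$folds,
                             seed = derive_seed(config$seed, 5))
  model <- tick("train", hksvm(train$features, train$labels,
                               weights = tuning$best_weights,
                               kernel_params = kp, C = tuning$best_C))
  pred <- tick("predict", predict(model, test$features))
  report <- eval_report(test$labels, pred, train$class_names)
  structure(list(pca = prep$pca, tuning = tuning, model = model,
                 report = report, train_cv = train_cv,
                 config = config, kernel_params = kp,
                 exported_files = exp$files, timings = timings,
                 n_train = nrow(train$features), n_test = nrow(test$features)),
            class = "hksvm_run")
}

#' Run the pipeline with one fixed single kernel
#'
#' Identical protocol to [run_pipeline()] with the GA stage skipped and the
#' hybrid weights pinned at the boundary reproducing the named single
#' kernel, giving the matched baselines the hybrid is compared against.
#'
#' @inheritParams run_pipeline
#' @param kernel `"rbf"`, `"linear"`, or `"polynomial"`.
#' @return An `hksvm_run` (with a degenerate `tuning` entry of `NULL`).
#' @export
run_single_kernel <- function(input, label_column = "class",
                              config = pipeline_config(),
                              kernel = c("rbf", "linear", "polynomial")) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(config, "pipeline_config"))
  w <- single_kernel_weights(kernel)
  prep <- prepare_split(input, label_column, config)
  train <- prep$split$train; test <- prep$split$test
  kp <- config$kernel_params %||% kernel_params(d = ncol(train$features))
  train_cv <- cross_validate(train$features, train$labels, weights = w,
                             kernel_params = kp, C = config$C,
                             folds = config$folds,
                             seed = derive_seed(config$seed, 5))
  model <- hksvm(train$features, train$labels, weights = w,
                 kernel_params = kp, C = config$C)
  pred <- predict(model, test$features)
  report <- eval_report(test$labels, pred, train$class_names)
  structure(list(pca = prep$pca, tuning = NULL, model = model,
                 report = report, train_cv = train_cv, config = config,
                 kernel_params = kp, kernel = kernel,
                 n_train = nrow(train$features), n_test = nrow(test$features)),
            class = "hksvm_run")
}

#' @export
print.hksvm_run <- function(x, ...) {
  cat("Hybrid-kernel SVM pipeline run\n")
  if (!is.null(x$pca)) {
    cat(sprintf("  PCA: %d -> %d components\n", length(x$pca$mean), x$pca$k))
  }
  if (!is.null(x$tuning)) {
    cat(sprintf("  GA best CV accuracy: %.2f%%; ", x$tuning$best_cv_accuracy))
  } else if (!is.null(x[["kernel"]])) {
    cat(sprintf("  single kernel: %s; ", x[["kernel"]]))
  }
  cat(sprintf("post-tuning CV: %.2f%%\n", x$train_cv$mean_accuracy))
  cat(sprintf("  held-out test (n = %d): %.2f%% accuracy\n", x$n_test,
              x$report$accuracy))
  invisible(x)
}

#' Serialize a pipeline run to JSON
#'
#' Writes the run's key artifacts (weights, metrics, confusion matrix,
#' seeds, timings) in a stable JSON layout; two runs under the same config
#' and master seed serialize identically apart from the timing block, which
#' can be excluded.
#'
#' @param run an `hksvm_run`.
#' @param path output path.
#' @param include_timings include wall-clock timings (default `FALSE` for
#'   byte-stable output).
#' @return Invisibly, the path.
#' @export
write_run_json <- function(run, path, include_timings = FALSE) {
  stopifnot(inherits(run, "hksvm_run"))
  payload <- list(
    weights = as.numeric(run$model$weights),
    C = run$model$C,
    kernel = run[["kernel"]] %||% "hybrid",
    pca_components = if (!is.null(run$pca)) run$pca$k else NA,
    ga_best_cv_accuracy = if (!is.null(run$tuning))
      run$tuning$best_cv_accuracy else NA,
    train_cv_accuracy = run$train_cv$mean_accuracy,
    test_accuracy = run$report$accuracy,
    precision_per_class = unname(run$report$precision_per_class),
    recall_per_class = unname(run$report$recall_per_class),
    confusion = run$report$confusion,
    n_train = run$n_train, n_test = run$n_test,
    seed = run$config$seed)
  if (include_timings) payload$timings <- as.list(run$timings)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
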