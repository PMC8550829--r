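# Encoding, imputation, scaling, shuffling, downsampling and the train/test
# split. All statistics (medians, modes, means, standard deviations) are
# computed on one split and can be re-applied to another, so the default
# pipeline never lets test rows inform a training statistic.

#' Encode categorical columns of a raw table
#'
#' A column is classified as categorical when any non-missing cell is
#' non-numeric. One-hot encoding expands a categorical column with k observed
#' levels into k binary columns (named `column=level`); ordinal encoding maps
#' levels to `0..k-1` in alphabetical order. Missing categorical cells stay
#' missing across the derived columns and are filled later by imputation.
#'
#' @param raw a [raw_table()].
#' @param encoding `"onehot"` (default) or `"ordinal"`.
#' @return A [tabular_dataset()], possibly still containing missing values.
#' @export
encode_categoricals <- function(raw, encoding = c("onehot", "ordinal")) {
  stopifnot(inherits(raw, "raw_table"))
  encoding <- match.arg(encoding)
  df <- raw$data
  y_raw <- df[[raw$label_column]]
  if (anyNA(y_raw)) stop_hksvm("label column contains missing values")
  feats <- df[setdiff(names(df), raw$label_column)]
  if (ncol(feats) < 1) stop_hksvm("no feature columns besides the label")

  cols <- list(); mask <- logical(0)
  for (nm in names(feats)) {
    col <- feats[[nm]]
    if (is.numeric(col)) {
      cols[[nm]] <- as.numeric(col)
      mask <- c(mask, FALSE)
    } else {
      col <- as.character(col)
      levels <- sort(unique(col[!is.na(col)]))
      if (length(levels) == 0) stop_hksvm("column '", nm, "' entirely missing")
      if (encoding == "ordinal") {
        cols[[nm]] <- as.numeric(match(col, levels) - 1L)
        mask <- c(mask, TRUE)
      } else {
        for (lv in levels) {
          v <- as.numeric(col == lv)
          v[is.na(col)] <- NA_real_
          cols[[paste0(nm, "=", lv)]] <- v
          mask <- c(mask, TRUE)
        }
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)

  class_vocab <- sort(unique(as.character(y_raw)))
  labels <- match(as.character(y_raw), class_vocab) - 1L
  tabular_dataset(X, labels, names(cols), class_vocab, mask,
                  allow_missing = TRUE)
}

column_mode <- function(x) {
  x <- x[!is.na(x)]
  ux <- sort(unique(x))
  ux[which.max(tabulate(match(x, ux)))] # ties: smallest value
}

#' Fill missing feature values
#'
#' Numeric columns are filled with the column median, categorical-derived
#' columns with the column mode. When `values` is supplied (as computed on a
#' training split), those fill values are applied instead, so test rows never
#' contribute to the statistics.
#'
#' @param ds a [tabular_dataset()], possibly with missing entries.
#' @param values optional named numeric vector of fill values per column, as
#'   stored in the `"impute_values"` attribute of a previous result.
#' @return A complete [tabular_dataset()] carrying an `"impute_values"`
#'   attribute.
#' @export
impute_missing <- function(ds, values = NULL) {
  stopifnot(inherits(ds, "tabular_dataset"))
  X <- ds$features
  if (is.null(values)) {
    values <- vapply(seq_len(ncol(X)), function(j) {
      col <- X[, j]
      if (all(is.na(col))) {
        stop_hksvm("column '", ds$feature_names[j], "' is entirely missing")
      }
      if (ds$categorical_mask[j]) column_mode(col)
      else stats::median(col, na.rm = TRUE)
    }, numeric(1))
    names(values) <- ds$feature_names
  }
  if (length(values) != ncol(X)) stop_hksvm("fill values length mismatch")
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- values[j]
  }
  out <- tabular_dataset(X, ds$labels, ds$feature_names, ds$class_names,
                         ds$categorical_mask)
  attr(out, "impute_values") <- values
  out
}

#' Scale feature columns
#'
#' `"standardize"` centers each column to mean 0 and scales to standard
#' deviation 1 (sample sd, n-1 denominator); `"minmax"` maps to `[0, 1]`.
#' Constant columns map to 0 in either mode. When `state` is supplied the
#' stored centers and scales (fitted on a training split) are re-applied.
#'
#' @param ds a complete [tabular_dataset()].
#' @param method `"standardize"` (default), `"minmax"`, or `"none"`.
#' @param state optional scaler state from the `"scaler"` attribute of a
#'   previous result.
#' @return A scaled [tabular_dataset()] carrying a `"scaler"` attribute.
#' @export
scale_features <- function(ds, method = c("standardize", "minmax", "none"),
                           state = NULL) {
  stopifnot(inherits(ds, "tabular_dataset"))
  method <- if (!is.null(state)) state$method else match.arg(method)
  X <- ds$features
  if (anyNA(X)) stop_hksvm("impute before scaling")
  if (method == "none") {
    out <- ds
    attr(out, "scaler") <- list(method = "none")
    return(out)
  }
  if (is.null(state)) {
    if (method == "standardize") {
      center <- colMeans(X)
      scale <- apply(X, 2, stats::sd)
    } else {
      center <- apply(X, 2, min)
      scale <- apply(X, 2, max) - center
    }
    scale[scale <= 0 | !is.finite(scale)] <- 1 # constant columns -> 0
    state <- list(method = method, center = center, scale = scale)
  }
  X <- sweep(sweep(X, 2, state$center, "-"), 2, state$scale, "/")
  out <- tabular_dataset(X, ds$labels, ds$feature_names, ds$class_names,
                         ds$categorical_mask)
  attr(out, "scaler") <- state
  out
}

#' Shuffle and split into train and test sets
#'
#' By default the split is stratified: each class's rows are shuffled and
#' divided as close to `train_fraction` as rounding permits, which keeps
#' every class represented in the training set even for the small clinical
#' tables. `stratified = FALSE` shuffles the whole table and cuts it once.
#'
#' @param ds a [tabular_dataset()].
#' @param seed integer seed; the split is deterministic given the seed.
#' @param train_fraction fraction of rows assigned to training (default 0.8).
#' @param stratified stratify by class (default `TRUE`).
#' @return A list of class `split_dataset` with elements `train` and `test`
#'   plus the row indices used for each.
#' @export
shuffle_split <- function(ds, seed, train_fraction = 0.8, stratified = TRUE) {
  stopifnot(inherits(ds, "tabular_dataset"))
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop_hksvm("train_fraction must lie in (0, 1)")
  }
  if (n_classes(ds) < 2) stop_hksvm("need at least 2 classes to split")
  counts <- tabulate(ds$labels + 1L, nbins = n_classes(ds))
  if (any(counts < 2)) {
    stop_hksvm("every class needs at least 2 instances to split")
  }
  idx_train <- with_seed(seed, {
    if (stratified) {
      unlist(lapply(seq_len(n_classes(ds)) - 1L, function(cl) {
        rows <- which(ds$labels == cl)
        rows <- rows[sample.int(length(rows))]
        n_tr <- max(1L, min(length(rows), round(length(rows) * train_fraction)))
        rows[seq_len(n_tr)]
      }))
    } else {
      perm <- sample.int(nrow(ds$features))
      perm[seq_len(max(1L, round(nrow(ds$features) * train_fraction)))]
    }
  })
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_len(nrow(ds$features)), idx_train)
  if (length(idx_test) == 0) stop_hksvm("empty test set; lower train_fraction")
  structure(list(train = subset_rows(ds, idx_train),
                 test = subset_rows(ds, idx_test),
                 train_idx = idx_train, test_idx = idx_test),
            class = "split_dataset")
}

#' Downsample over-represented classes
#'
#' Classes larger than `target_per_class` are randomly subsampled to the
#' target; smaller classes are kept whole. Used to rebalance heavily skewed
#' tables before training.
#'
#' @param ds a [tabular_dataset()].
#' @param target_per_class cap on instances per class.
#' @param seed integer seed; selection is deterministic given the seed.
#' @return A [tabular_dataset()] with capped class sizes.
#' @export
downsample_classes <- function(ds, target_per_class, seed) {
  stopifnot(inherits(ds, "tabular_dataset"), is_count(target_per_class))
  keep <- with_seed(seed, {
    unlist(lapply(seq_len(n_classes(ds)) - 1L, function(cl) {
      rows <- which(ds$labels == cl)
      if (length(rows) > target_per_class) {
        sort(rows[sample.int(length(rows), target_per_class)])
      } else rows
    }))
  })
  subset_rows(ds, sort(keep))
}

#' Filter rows by per-column valid ranges
#'
#' Drops rows with out-of-range values in named columns (for example
#' physiologically impossible ages or temperatures). Ranges are user
#' supplied; missing cells are not compared.
#'
#' @param ds a [tabular_dataset()].
#' @param ranges named list of `c(min, max)` per feature column.
#' @return The filtered [tabular_dataset()].
#' @export
filter_ranges <- function(ds, ranges) {
  stopifnot(inherits(ds, "tabular_dataset"))
  if (length(ranges) == 0) return(ds)
  bad <- rep(FALSE, nrow(ds$features))
  for (nm in names(ranges)) {
    j <- match(nm, ds$feature_names)
    if (is.na(j)) stop_hksvm("unknown column in ranges: ", nm)
    col <- ds$features[, j]
    r <- ranges[[nm]]
    bad <- bad | (!is.na(col) & (col < r[1] | col > r[2]))
  }
  if (all(!bad)) return(ds)
  subset_rows(ds, which(!bad))
}
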