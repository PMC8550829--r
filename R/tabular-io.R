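# Canonical in-memory containers and the CSV / svmlight readers and writers.
#
# A `raw_table` holds data as read from disk: untyped cells (numeric or
# character), missing values as NA, and the name of the label column. A
# `tabular_dataset` is the post-encoding form: an all-numeric feature matrix
# plus an integer label vector in 0..C-1 and the bookkeeping needed to map
# back to the original vocabulary.

#' Construct a raw table
#'
#' @param data data.frame of cells; missing values are `NA`.
#' @param label_column name of the column holding the class label.
#' @return An object of class `raw_table`.
#' @export
raw_table <- function(data, label_column) {
  if (!is.data.frame(data)) stop_hksvm("`data` must be a data.frame")
  if (anyDuplicated(names(data))) stop_hksvm("column names must be unique")
  if (!label_column %in% names(data)) {
    stop_hksvm("label column '", label_column, "' not found")
  }
  structure(list(data = data, label_column = label_column),
            class = "raw_table")
}

#' @export
print.raw_table <- function(x, ...) {
  cat(sprintf("<raw_table> %d rows, %d feature columns, label '%s'\n",
              nrow(x$data), ncol(x$data) - 1L, x$label_column))
  n_miss <- sum(is.na(x$data))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", n_miss,
              100 * n_miss / prod(dim(x$data))))
  invisible(x)
}

#' Construct a tabular dataset
#'
#' The canonical numeric container used by every downstream stage: an n x d
#' feature matrix, integer labels in `0..C-1`, and metadata recording the
#' class vocabulary and which columns originated from categorical sources.
#'
#' @param features numeric matrix (n x d).
#' @param labels integer vector of length n with values in `0..C-1`.
#' @param feature_names character vector of length d.
#' @param class_names character vector of length C; `class_names[i + 1]` is
#'   the original vocabulary of integer label `i`.
#' @param categorical_mask logical vector of length d; `TRUE` marks columns
#'   derived from a categorical source.
#' @param allow_missing if `TRUE`, `NA` entries in `features` are permitted
#'   (the state between encoding and imputation).
#' @return An object of class `tabular_dataset`.
#' @export
tabular_dataset <- function(features, labels, feature_names = NULL,
                            class_names = NULL, categorical_mask = NULL,
                            allow_missing = FALSE) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features); d <- ncol(features)
  if (n < 1 || d < 1) stop_hksvm("need n >= 1 and d >= 1")
  labels <- as.integer(labels)
  if (length(labels) != n) stop_hksvm("length(labels) must equal nrow(features)")
  if (anyNA(labels)) stop_hksvm("labels must not be missing")
  feature_names <- feature_names %||% colnames(features) %||%
    paste0("f", seq_len(d))
  if (length(feature_names) != d) stop_hksvm("feature_names length must be d")
  C <- max(labels) + 1L
  class_names <- class_names %||% as.character(seq_len(C) - 1L)
  if (min(labels) < 0 || max(labels) >= length(class_names)) {
    stop_hksvm("labels must lie in 0..C-1")
  }
  categorical_mask <- categorical_mask %||% rep(FALSE, d)
  if (length(categorical_mask) != d) {
    stop_hksvm("categorical_mask length must be d")
  }
  if (!allow_missing && anyNA(features)) {
    stop_hksvm("features contain missing values; impute first")
  }
  colnames(features) <- feature_names
  structure(list(features = features, labels = labels,
                 feature_names = feature_names,
                 class_names = as.character(class_names),
                 categorical_mask = as.logical(categorical_mask)),
            class = "tabular_dataset")
}

#' @export
print.tabular_dataset <- function(x, ...) {
  tab <- table(factor(x$labels, levels = seq_along(x$class_names) - 1L))
  cat(sprintf("<tabular_dataset> %d x %d, %d classes\n",
              nrow(x$features), ncol(x$features), length(x$class_names)))
  cat("  class counts:",
      paste(sprintf("%s=%d", x$class_names, as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.tabular_dataset <- function(x) dim(x$features)

n_classes <- function(ds) length(ds$class_names)

subset_rows <- function(ds, idx) {
  tabular_dataset(ds$features[idx, , drop = FALSE], ds$labels[idx],
                  ds$feature_names, ds$class_names, ds$categorical_mask,
                  allow_missing = TRUE)
}

#' Read a delimited dataset with a header row
#'
#' Reads a CSV file into a [raw_table()], preserving missing cells as `NA`
#' rather than dropping or imputing them; imputation happens later, on the
#' training split only. Columns are typed leniently: a column is numeric only
#' if every non-missing cell parses as a number.
#'
#' @param path path to a CSV file with a header row.
#' @param label_column name of the class-label column.
#' @param na_strings cell values treated as missing. The default covers the
#'   conventions of the common clinical benchmark files, including the
#'   `"?"` used by the chronic kidney disease table.
#' @return A [raw_table()].
#' @export
read_csv_dataset <- function(path, label_column,
                             na_strings = c("", "NA", "NaN", "?")) {
  if (!file.exists(path)) stop_hksvm("file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, na.strings = na_strings,
                        stringsAsFactors = FALSE, check.names = FALSE,
                        strip.white = TRUE, fill = FALSE,
                        colClasses = "character")
  if (anyDuplicated(names(df))) stop_hksvm("duplicate column names in header")
  if (!label_column %in% names(df)) {
    stop_hksvm("label column '", label_column, "' not present")
  }
  for (j in seq_along(df)) {
    col <- df[[j]]
    ok <- !is.na(col)
    if (any(ok)) {
      num <- suppressWarnings(as.numeric(col[ok]))
      if (!anyNA(num)) {
        out <- rep(NA_real_, length(col)); out[ok] <- num
        df[[j]] <- out
      }
    }
  }
  raw_table(df, label_column)
}

#' Write a dataset in svmlight/LIBSVM sparse text format
#'
#' One line per row: `label index:value ...` with 1-based strictly increasing
#' indices and zero-valued features omitted. Labels are written as the
#' dataset's integer codes. Values are printed with enough digits to
#' round-trip through [read_svmlight()] within 1e-12.
#'
#' @param ds a [tabular_dataset()] without missing values.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_svmlight <- function(ds, path) {
  stopifnot(inherits(ds, "tabular_dataset"))
  if (anyNA(ds$features)) stop_hksvm("cannot write missing values to svmlight")
  X <- ds$features
  lines <- vapply(seq_len(nrow(X)), function(i) {
    nz <- which(X[i, ] != 0)
    if (length(nz) == 0) return(as.character(ds$labels[i]))
    paste(ds$labels[i],
          paste(sprintf("%d:%.17g", nz, X[i, nz]), collapse = " "))
  }, character(1))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop_hksvm("cannot open '", path, "' for writing")
  })
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a dataset in svmlight/LIBSVM sparse text format
#'
#' The feature dimension is the largest index seen in the file; absent
#' indices are 0. Labels are remapped to contiguous integers `0..C-1` in
#' increasing order of the original numeric labels, with the original
#' vocabulary recorded in `class_names` so it survives a round-trip.
#'
#' @param path path to an svmlight-format text file.
#' @return A [tabular_dataset()].
#' @export
read_svmlight <- function(path) {
  if (!file.exists(path)) stop_hksvm("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_hksvm("empty svmlight file")
  parsed <- lapply(seq_along(lines), function(li) {
    toks <- strsplit(trimws(lines[li]), "[[:space:]]+")[[1]]
    lab <- suppressWarnings(as.numeric(toks[1]))
    if (is.na(lab)) stop_hksvm("line ", li, ": non-numeric label")
    if (length(toks) == 1) {
      return(list(label = lab, idx = integer(0), val = numeric(0)))
    }
    pieces <- strsplit(toks[-1], ":", fixed = TRUE)
    if (any(lengths(pieces) != 2)) {
      stop_hksvm("line ", li, ": malformed index:value pair")
    }
    idx <- suppressWarnings(as.integer(vapply(pieces, `[`, "", 1)))
    val <- suppressWarnings(as.numeric(vapply(pieces, `[`, "", 2)))
    if (anyNA(idx) || anyNA(val)) {
      stop_hksvm("line ", li, ": non-numeric index or value")
    }
    if (any(idx < 1)) stop_hksvm("line ", li, ": indices must be 1-based")
    if (any(diff(idx) <= 0)) {
      stop_hksvm("line ", li, ": indices must be strictly increasing")
    }
    list(label = lab, idx = idx, val = val)
  })
  d <- max(1L, max(vapply(parsed, function(p) {
    if (length(p$idx)) max(p$idx) else 0L
  }, integer(1))))
  X <- matrix(0, nrow = length(parsed), ncol = d)
  for (i in seq_along(parsed)) X[i, parsed[[i]]$idx] <- parsed[[i]]$val
  raw_labels <- vapply(parsed, `[[`, numeric(1), "label")
  vocab <- sort(unique(raw_labels))
  labels <- match(raw_labels, vocab) - 1L
  tabular_dataset(X, labels, paste0("f", seq_len(d)),
                  class_names = format(vocab, trim = TRUE, digits = 15))
}
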