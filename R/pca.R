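# SVD-based principal component analysis with retention of the leading
# components that explain at least a target fraction of the variance.

#' Fit a PCA model retaining a target explained-variance fraction
#'
#' Principal axes are computed from the singular value decomposition of the
#' column-centered matrix (via [stats::prcomp()]). The retained dimension k
#' is the smallest number of leading components whose cumulative explained
#' variance reaches `variance_threshold`. Variance fractions use the n-1
#' denominator, consistent with the package's feature standardization. The
#' sign of each axis is fixed by making its largest-magnitude entry positive,
#' so fits are deterministic up to row order.
#'
#' @param X numeric matrix (n x d), n >= 2, all entries finite.
#' @param variance_threshold fraction of variance to retain, in (0, 1];
#'   default 0.95.
#' @return An object of class `hksvm_pca` with elements `mean` (length-d
#'   centering vector), `components` (d x k orthonormal matrix),
#'   `explained_ratio` (length-k variance fractions), `k`, and
#'   `all_explained` (fractions for every component).
#' @seealso [transform_pca()]
#' @export
fit_pca <- function(X, variance_threshold = 0.95) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop_hksvm("need at least 2 rows to fit PCA")
  if (!all(is.finite(X))) stop_hksvm("X must be finite")
  if (!(variance_threshold > 0 && variance_threshold <= 1)) {
    stop_hksvm("variance_threshold must lie in (0, 1]")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  total <- sum(vars)
  if (total <= 0) stop_hksvm("X has zero total variance")
  ratio <- vars / total
  cum <- cumsum(ratio)
  k <- which(cum >= variance_threshold - 1e-12)[1]
  if (is.na(k)) k <- length(ratio)
  V <- pc$rotation[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude entry of each axis is positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(mean = pc$center, components = V,
                 explained_ratio = ratio[seq_len(k)], k = k,
                 all_explained = ratio),
            class = "hksvm_pca")
}

#' Project data onto fitted principal axes
#'
#' Computes `(X - mean) %*% components`, reducing d columns to the k axes
#' retained by [fit_pca()].
#'
#' @param model an `hksvm_pca` object.
#' @param X numeric matrix with the same column count the model was fitted on.
#' @return An n x k score matrix.
#' @export
transform_pca <- function(model, X) {
  stopifnot(inherits(model, "hksvm_pca"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean)) {
    stop_hksvm("X has ", ncol(X), " columns; model expects ",
               length(model$mean))
  }
  sweep(X, 2, model$mean, "-") %*% model$components
}

#' @export
predict.hksvm_pca <- function(object, newdata, ...) {
  transform_pca(object, newdata)
}

#' @export
print.hksvm_pca <- function(x, ...) {
  cat(sprintf("<hksvm_pca> %d -> %d components (%.2f%% variance retained)\n",
              length(x$mean), x$k, 100 * sum(x$explained_ratio)))
  invisible(x)
}
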