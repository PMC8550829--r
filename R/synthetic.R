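# Synthetic tabular generators shaped like the clinical benchmark tables
# the model family is normally run on, so every pipeline stage is testable
# without external downloads. Geometries are chosen to favour particular
# kernels (Gaussian blobs for the linear kernel, concentric shells for the
# RBF kernel, a quadratic-form boundary for the polynomial kernel), which is
# what makes kernel-weight recovery testable.

#' Specification of a synthetic clinical-style dataset
#'
#' @param n_per_class instances per class (recycled to `n_classes`).
#' @param n_classes number of classes (default: `length(n_per_class)`).
#' @param n_numeric number of numeric feature columns.
#' @param n_categorical number of categorical feature columns.
#' @param cat_levels levels per categorical column (default 3).
#' @param missing_rate fraction of feature cells set missing completely at
#'   random, in `[0, 1)`.
#' @param class_geometry one of `"linear_separable"` (Gaussian blobs spaced
#'   along a direction), `"radial"` (concentric shells around the origin),
#'   `"polynomial_boundary"` (classes split by the value of a quadratic
#'   form), `"overlapping"` (blobs close enough to overlap).
#' @param separation geometry scale: blob spacing, shell radius step, or
#'   quantile-gap width (default 2).
#' @param correlation target pairwise correlation between numeric columns,
#'   injected by a shared latent factor, in `[0, 1)`.
#' @param seed integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class, n_classes = length(n_per_class),
                           n_numeric = 2, n_categorical = 0, cat_levels = 3,
                           missing_rate = 0,
                           class_geometry = c("linear_separable", "radial",
                                              "polynomial_boundary",
                                              "overlapping"),
                           separation = 2, correlation = 0, seed = 1) {
  class_geometry <- match.arg(class_geometry)
  n_per_class <- rep_len(as.integer(n_per_class), n_classes)
  if (n_classes < 2) stop_hksvm("n_classes must be at least 2")
  if (n_numeric + n_categorical < 1) stop_hksvm("need at least one feature")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_hksvm("missing_rate must lie in [0, 1)")
  }
  if (correlation < 0 || correlation >= 1) {
    stop_hksvm("correlation must lie in [0, 1)")
  }
  if (separation <= 0) stop_hksvm("separation must be positive")
  if (class_geometry %in% c("radial", "polynomial_boundary") && n_numeric < 2) {
    stop_hksvm(class_geometry, " geometry needs at least 2 numeric features")
  }
  structure(list(n_per_class = n_per_class, n_classes = as.integer(n_classes),
                 n_numeric = as.integer(n_numeric),
                 n_categorical = as.integer(n_categorical),
                 cat_levels = as.integer(cat_levels),
                 missing_rate = missing_rate,
                 class_geometry = class_geometry, separation = separation,
                 correlation = correlation, seed = as.integer(seed)),
            class = "synthetic_spec")
}

numeric_features <- function(spec, labels) {
  n <- length(labels); d <- spec$n_numeric; Cn <- spec$n_classes
  X <- switch(spec$class_geometry,
    linear_separable = ,
    overlapping = {
      # class centers spaced along a random direction, so the shared
      # correlation factor (injected along the all-ones vector below) is
      # not confounded with the diagnostic signal
      dir <- stats::rnorm(d)
      dir <- dir / sqrt(sum(dir^2))
      centers <- outer((seq_len(Cn) - 1) * spec$separation, dir)
      matrix(stats::rnorm(n * d), n, d) + centers[labels + 1L, , drop = FALSE]
    },
    radial = {
      radius <- (labels) * spec$separation +
        stats::rnorm(n, 0, 0.15 * spec$separation)
      U <- matrix(stats::rnorm(n * d), n, d)
      U <- U / sqrt(rowSums(U^2))
      U * radius
    },
    polynomial_boundary = {
      # oversample, order rows by a quadratic form, cut into classes with a
      # separation-scaled gap dropped around each threshold
      n_pool <- ceiling(1.6 * n)
      P <- matrix(stats::rnorm(n_pool * d), n_pool, d)
      half <- ceiling(d / 2)
      q <- rowSums(P[, seq_len(half), drop = FALSE]^2) -
        rowSums(P[, -seq_len(half), drop = FALSE]^2)
      ord <- order(q)
      gap <- max(0L, floor((n_pool - n) / max(1L, Cn - 1L)) - 1L)
      gap <- min(gap, floor(0.05 * spec$separation * n_pool / max(1L, Cn - 1L)))
      take <- integer(0); pos <- 0L
      for (cl in seq_len(Cn)) {
        n_cl <- sum(labels == cl - 1L)
        take <- c(take, ord[pos + seq_len(n_cl)])
        pos <- pos + n_cl + gap
      }
      P[take, , drop = FALSE]
    })
  if (spec$correlation > 0 && d >= 2) {
    rho <- spec$correlation
    z <- stats::rnorm(n)
    X <- sqrt(1 - rho) * X + sqrt(rho) * z
  }
  colnames(X) <- paste0("num", seq_len(d))
  X
}

#' Generate a synthetic clinical-style dataset
#'
#' Draws numeric features per the spec's class geometry, adds categorical
#' columns with class-dependent level frequencies, and knocks out feature
#' cells completely at random at the requested rate. Deterministic given the
#' spec's seed. For `polynomial_boundary`, class labels follow ordered
#' quantile slices of a fixed quadratic form, so rows within a class are not
#' independent draws of the other geometries' kind.
#'
#' @param spec a [synthetic_spec()].
#' @return A [raw_table()] whose label column is `"class"` with values
#'   `"c1" .. "cC"`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    labels <- rep(seq_len(spec$n_classes) - 1L, spec$n_per_class)
    n <- length(labels)
    Xnum <- if (spec$n_numeric > 0) numeric_features(spec, labels) else NULL
    df <- if (!is.null(Xnum)) as.data.frame(Xnum) else
      as.data.frame(matrix(nrow = n, ncol = 0))
    if (spec$n_categorical > 0) {
      level_names <- LETTERS[seq_len(spec$cat_levels)]
      for (j in seq_len(spec$n_categorical)) {
        # class-dependent level frequencies, fixed by the seed
        logits <- matrix(stats::rnorm(spec$cat_levels * spec$n_classes, 0, 1.2),
                         spec$cat_levels, spec$n_classes)
        probs <- apply(logits, 2, function(l) exp(l) / sum(exp(l)))
        col <- vapply(labels, function(cl) {
          sample(level_names, 1, prob = probs[, cl + 1L])
        }, character(1))
        df[[paste0("cat", j)]] <- col
      }
    }
    if (spec$missing_rate > 0) {
      for (j in seq_along(df)) {
        miss <- stats::runif(n) < spec$missing_rate
        df[[j]][miss] <- NA
      }
    }
    df$class <- paste0("c", labels + 1L)
    raw_table(df, "class")
  })
}

#' Synthetic suite shaped like common clinical benchmark tables
#'
#' Seven synthetic datasets matching the (instances, features, classes)
#' signatures of widely used diagnosis benchmarks -- a respiratory-style
#' 4-class set at 1000 instances per class with 20 features, a chronic
#' kidney style 400 x 24 binary set with categoricals and missing cells, a
#' heart-disease style 303 x 13 set, a breast-cancer style 569 x 30 set, a
#' lymphography-style 148 x 18 4-class set, and two acute-inflammation
#' style 120 x 6 binary sets -- with mixed class geometries. All content is
#' synthetic; only the shapes echo the benchmarks.
#'
#' @param seed integer seed.
#' @return A named list of [raw_table()] objects.
#' @export
synthetic_clinical_suite <- function(seed = 1) {
  specs <- list(
    respiratory = synthetic_spec(1000, n_classes = 4, n_numeric = 16,
                                 n_categorical = 4, missing_rate = 0.02,
                                 class_geometry = "radial", separation = 2,
                                 correlation = 0.2,
                                 seed = derive_seed(seed, 1)),
    chronic_kidney = synthetic_spec(c(250, 150), n_numeric = 14,
                                    n_categorical = 10, missing_rate = 0.08,
                                    class_geometry = "linear_separable",
                                    separation = 2.5, correlation = 0.3,
                                    seed = derive_seed(seed, 2)),
    heart = synthetic_spec(c(165, 138), n_numeric = 10, n_categorical = 3,
                           class_geometry = "overlapping", separation = 1.2,
                           correlation = 0.2, seed = derive_seed(seed, 3)),
    breast_cancer = synthetic_spec(c(357, 212), n_numeric = 30,
                                   class_geometry = "linear_separable",
                                   separation = 2, correlation = 0.4,
                                   seed = derive_seed(seed, 4)),
    lymphography = synthetic_spec(c(2, 81, 61, 4), n_numeric = 12,
                                  n_categorical = 6,
                                  class_geometry = "overlapping",
                                  separation = 2.5,
                                  seed = derive_seed(seed, 5)),
    nephritis = synthetic_spec(c(70, 50), n_numeric = 2, n_categorical = 4,
                               cat_levels = 2,
                               class_geometry = "linear_separable",
                               separation = 4, seed = derive_seed(seed, 6)),
    bladder_inflammation = synthetic_spec(c(61, 59), n_numeric = 2,
                                          n_categorical = 4, cat_levels = 2,
                                          class_geometry = "polynomial_boundary",
                                          separation = 3,
                                          seed = derive_seed(seed, 7)))
  lapply(specs, generate_synthetic)
}
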