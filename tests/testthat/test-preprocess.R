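make_raw <- function(df, label = "y") raw_table(df, label)

test_that("one-hot encoding expands categoricals and rows sum to one", {
  raw <- make_raw(data.frame(a = c("yes", "no", "yes"),
                             b = c(1.5, 2.5, 3.5),
                             y = c("p", "n", "p")))
  ds <- encode_categoricals(raw, "onehot")
  dummy <- ds$features[, startsWith(ds$feature_names, "a=")]
  expect_equal(ncol(dummy), 2)
  expect_equal(unname(rowSums(dummy)), c(1, 1, 1))
  expect_equal(ds$categorical_mask, c(TRUE, TRUE, FALSE))
  expect_equal(ds$class_names, c("n", "p"))
})

test_that("all-numeric tables encode to their own values", {
  raw <- make_raw(data.frame(a = c(1, 2), b = c(3, 4), y = c("u", "v")))
  ds <- encode_categoricals(raw)
  expect_equal(unname(ds$features), cbind(c(1, 2), c(3, 4)))
  expect_false(any(ds$categorical_mask))
})

test_that("ordinal encoding uses alphabetical level order", {
  raw <- make_raw(data.frame(a = c("mid", "low", "high"), y = c("p","n","p")))
  ds <- encode_categoricals(raw, "ordinal")
  # alphabetical: high=0, low=1, mid=2
  expect_equal(unname(ds$features[, 1]), c(2, 1, 0))
})

test_that("missing categorical cells survive encoding for later imputation", {
  raw <- make_raw(data.frame(a = c("yes", NA, "no"), y = c("p", "n", "p")))
  ds <- encode_categoricals(raw, "onehot")
  expect_true(all(is.na(ds$features[2, ])))
})

test_that("imputation fills medians for numeric and modes for categorical", {
  ds <- tabular_dataset(cbind(num = c(1, 2, NA, 4), bin = c(0, 0, 1, NA)),
                        c(0L, 0L, 1L, 1L),
                        categorical_mask = c(FALSE, TRUE),
                        allow_missing = TRUE)
  out <- impute_missing(ds)
  expect_equal(unname(out$features[3, 1]), 2) # median of {1,2,4}
  expect_equal(unname(out$features[4, 2]), 0) # mode of {0,0,1}
  expect_false(anyNA(out$features))

  # identity on complete data, and train statistics reapply to test
  expect_equal(impute_missing(out)$features, out$features)
  test_ds <- tabular_dataset(cbind(num = NA_real_, bin = NA_real_), 0L,
                             feature_names = c("num", "bin"),
                             class_names = c("a", "b"),
                             allow_missing = TRUE)
  reapplied <- impute_missing(test_ds, values = attr(out, "impute_values"))
  expect_equal(unname(reapplied$features[1, ]), c(2, 0))
  expect_error(impute_missing(tabular_dataset(cbind(c(NA_real_, NA_real_)),
                                              c(0L, 1L),
                                              allow_missing = TRUE)),
               "entirely missing")
})

test_that("standardization uses the sample sd and zeroes constant columns", {
  ds <- tabular_dataset(cbind(a = c(2, 4), b = c(5, 5)), c(0L, 1L))
  out <- scale_features(ds, "standardize")
  expect_equal(unname(out$features[, 1]), c(-1, 1) / sqrt(2),
               tolerance = 1e-9) # sample sd convention
  expect_equal(unname(out$features[, 2]), c(0, 0))

  X <- with_seed(5, matrix(rnorm(60, 3, 2), 20, 3))
  tr <- scale_features(tabular_dataset(X, rep(0:1, 10)))
  expect_equal(unname(colMeans(tr$features)), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(apply(tr$features, 2, sd)), rep(1, 3),
               tolerance = 1e-9)

  # scaler state fitted on train applies unchanged to new rows
  te <- scale_features(tabular_dataset(X[1:3, ], rep(0L, 3)),
                       state = attr(tr, "scaler"))
  expect_equal(te$features, tr$features[1:3, ])
  # none is the identity
  expect_equal(scale_features(ds, "none")$features, ds$features)
})

test_that("stratified splitting follows the per-class rounding arithmetic", {
  ds <- tabular_dataset(matrix(rnorm(200), 100), rep(0:1, each = 50))
  sp <- shuffle_split(ds, seed = 3, train_fraction = 0.8)
  expect_equal(nrow(sp$train$features), 80)
  expect_equal(as.integer(table(sp$train$labels)), c(40L, 40L))
  expect_equal(as.integer(table(sp$test$labels)), c(10L, 10L))

  ds2 <- tabular_dataset(matrix(rnorm(200), 100),
                         rep(0:1, times = c(60, 40)))
  sp2 <- shuffle_split(ds2, seed = 3, train_fraction = 0.8)
  expect_equal(as.integer(table(sp2$train$labels)), c(48L, 32L))

  # partition property: disjoint, union recovers the input
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_equal(sort(c(sp$train_idx, sp$test_idx)), 1:100)

  # determinism
  sp3 <- shuffle_split(ds, seed = 3, train_fraction = 0.8)
  expect_identical(sp3$train_idx, sp$train_idx)
  sp4 <- shuffle_split(ds, seed = 4, train_fraction = 0.8)
  expect_false(identical(sp4$train_idx, sp$train_idx))
})

test_that("downsampling caps large classes and keeps small ones whole", {
  ds <- tabular_dataset(matrix(rnorm(2 * 1300), ncol = 2),
                        rep(0:1, times = c(1000, 300)))
  out <- downsample_classes(ds, 500, seed = 9)
  expect_equal(as.integer(table(out$labels)), c(500L, 300L))
  # target above all class sizes: identity
  out2 <- downsample_classes(ds, 5000, seed = 9)
  expect_equal(dim(out2$features), dim(ds$features))
  # determinism
  expect_equal(downsample_classes(ds, 500, seed = 9)$features, out$features)
})

test_that("range filtering drops out-of-range rows only", {
  ds <- tabular_dataset(cbind(age = c(30, 250, 41), t = c(37, 38, 90)),
                        c(0L, 1L, 0L))
  out <- filter_ranges(ds, list(age = c(0, 120), t = c(30, 45)))
  expect_equal(nrow(out$features), 1)
  expect_equal(unname(out$features[1, ]), c(30, 37))
})
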