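test_that("generated class counts and shapes match the spec exactly", {
  spec <- synthetic_spec(c(30, 20, 10), n_numeric = 5, n_categorical = 2,
                         class_geometry = "linear_separable", seed = 81)
  raw <- generate_synthetic(spec)
  expect_s3_class(raw, "raw_table")
  expect_equal(nrow(raw$data), 60)
  expect_equal(ncol(raw$data), 5 + 2 + 1)
  expect_equal(as.integer(table(raw$data$class)), c(30L, 20L, 10L))
  expect_error(synthetic_spec(10, n_classes = 1), "at least 2")
  expect_error(synthetic_spec(c(10, 10), n_numeric = 1,
                              class_geometry = "radial"), "2 numeric")
})

test_that("generation is deterministic given the seed", {
  spec <- synthetic_spec(c(25, 25), n_numeric = 4, n_categorical = 1,
                         missing_rate = 0.1, seed = 82)
  r1 <- generate_synthetic(spec)
  r2 <- generate_synthetic(spec)
  expect_identical(r1$data, r2$data)
  r3 <- generate_synthetic(synthetic_spec(c(25, 25), n_numeric = 4,
                                          n_categorical = 1,
                                          missing_rate = 0.1, seed = 83))
  expect_false(identical(r1$data, r3$data))
})

test_that("missingness lands within binomial bounds of the target rate", {
  spec <- synthetic_spec(c(500, 500), n_numeric = 10, missing_rate = 0.1,
                         seed = 84)
  raw <- generate_synthetic(spec)
  cells <- as.matrix(raw$data[, setdiff(names(raw$data), "class")])
  frac <- mean(is.na(cells))
  expect_lt(abs(frac - 0.1), 0.03) # 3 sigma of Binomial(10000, 0.1)
})

test_that("shared-factor correlation hits its target at scale", {
  spec <- synthetic_spec(c(600, 600), n_numeric = 6, correlation = 0.4,
                         class_geometry = "linear_separable",
                         separation = 0.5, seed = 85)
  raw <- generate_synthetic(spec)
  X <- as.matrix(raw$data[, 1:6])
  cors <- cor(X)[lower.tri(diag(6))]
  expect_true(all(abs(cors - 0.4) < 0.1))
})

test_that("separable geometry yields a perfect linear-kernel fit", {
  spec <- synthetic_spec(c(40, 40), n_numeric = 3,
                         class_geometry = "linear_separable",
                         separation = 10, seed = 86)
  ds <- impute_missing(encode_categoricals(generate_synthetic(spec)))
  fit <- hksvm(ds$features, ds$labels,
               weights = single_kernel_weights("linear"), C = 100)
  expect_equal(mean(fitted(fit) == ds$labels), 1)
})

test_that("radial geometry favors the RBF kernel over the linear one", {
  spec <- synthetic_spec(c(100, 100), n_numeric = 2,
                         class_geometry = "radial", separation = 2,
                         seed = 87)
  ds <- impute_missing(encode_categoricals(generate_synthetic(spec)))
  cv_rbf <- cross_validate(ds$features, ds$labels,
                           single_kernel_weights("rbf"), seed = 1)
  cv_lin <- cross_validate(ds$features, ds$labels,
                           single_kernel_weights("linear"), seed = 1)
  expect_gt(cv_rbf$mean_accuracy, 90)
  # a half-plane can at best capture one blob plus part of the ring
  expect_lt(cv_lin$mean_accuracy, 80)
  expect_gt(cv_rbf$mean_accuracy, cv_lin$mean_accuracy + 10)
})

test_that("polynomial-boundary geometry favors the polynomial kernel", {
  spec <- synthetic_spec(c(100, 100), n_numeric = 4,
                         class_geometry = "polynomial_boundary",
                         separation = 3, seed = 88)
  ds <- impute_missing(encode_categoricals(generate_synthetic(spec)))
  cv_pol <- cross_validate(ds$features, ds$labels,
                           single_kernel_weights("polynomial"), seed = 1)
  cv_lin <- cross_validate(ds$features, ds$labels,
                           single_kernel_weights("linear"), seed = 1)
  expect_gt(cv_pol$mean_accuracy, cv_lin$mean_accuracy)
})

test_that("the clinical-style suite echoes the benchmark signatures", {
  suite <- synthetic_clinical_suite(seed = 89)
  expect_length(suite, 7)
  shape <- function(r) c(nrow(r$data), ncol(r$data) - 1,
                         length(unique(r$data$class)))
  expect_equal(shape(suite$lymphography), c(148, 18, 4))
  expect_equal(shape(suite$nephritis), c(120, 6, 2))
  expect_equal(shape(suite$bladder_inflammation), c(120, 6, 2))
  expect_equal(shape(suite$breast_cancer), c(569, 30, 2))
  expect_equal(shape(suite$heart), c(303, 13, 2))
  expect_equal(shape(suite$chronic_kidney), c(400, 24, 2))
  expect_equal(shape(suite$respiratory), c(4000, 20, 4))
})

test_that("every suite member passes the preprocessing stages end to end", {
  suite <- synthetic_clinical_suite(seed = 90)
  for (nm in names(suite)) {
    ds <- encode_categoricals(suite[[nm]])
    sp <- shuffle_split(ds, seed = 1)
    tr <- scale_features(impute_missing(sp$train))
    te <- scale_features(impute_missing(sp$test,
                                        attr(impute_missing(sp$train),
                                             "impute_values")),
                         state = attr(tr, "scaler"))
    expect_false(anyNA(tr$features))
    expect_false(anyNA(te$features))
    expect_true(all(sort(unique(tr$labels)) ==
                      seq_along(unique(ds$labels)) - 1))
  }
})
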