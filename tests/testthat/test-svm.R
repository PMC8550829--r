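test_that("two opposed points recover maximal-margin geometry", {
  x <- matrix(c(-1, 1), ncol = 1)
  K <- tcrossprod(x)
  m <- svm_train_precomputed(K, c(0L, 1L), C = 100)
  pred <- svm_predict_precomputed(m, K)
  expect_equal(pred, c(0L, 1L))
  # Gram row of the midpoint (0): kernel value 0 against both -> decision 0
  dec <- svm_decision_precomputed(m, matrix(c(0, 0), 1))
  expect_equal(as.numeric(dec), 0, tolerance = 1e-6)
})

test_that("duplicating every training row leaves predictions unchanged", {
  b <- make_blobs(15, d = 2, sep = 3, seed = 41)
  K <- hybrid_gram(b$x, weights = single_kernel_weights("rbf"),
                   params = kernel_params(d = 2))
  m1 <- svm_train_precomputed(K, b$y, C = 1)
  idx <- rep(seq_len(nrow(K)), 2)
  m2 <- svm_train_precomputed(K[idx, idx], b$y[idx], C = 1)
  p1 <- svm_predict_precomputed(m1, K)
  p2 <- svm_predict_precomputed(m2, K[, idx])
  expect_equal(p1, p2)
})

test_that("dual solutions satisfy box and zero-sum constraints", {
  for (seed in 1:10) {
    b <- make_blobs(20, d = 3, sep = 2, seed = seed)
    w <- random_weights(seed)
    K <- hybrid_gram(b$x, weights = w,
                     params = kernel_params(d = 3, poly_coef0 = 1))
    C <- c(0.5, 1, 10)[seed %% 3 + 1]
    m <- svm_train_precomputed(K, b$y, C = C)
    for (p in m$pairs) {
      expect_lte(max(abs(p$coefs)), C + 1e-9)
      expect_lt(abs(sum(p$coefs)), 1e-6)
    }
  }
})

test_that("precomputed training matches a native-kernel reference solver", {
  for (seed in 1:20) {
    b <- make_blobs(20, d = 2, sep = 4, seed = 500 + seed)
    g <- 0.5
    K <- single_gram(b$x, kernel = "rbf", params = kernel_params(rbf_gamma = g))
    m <- svm_train_precomputed(K, b$y, C = 1)
    mine <- svm_predict_precomputed(m, K)
    ref <- kernlab::ksvm(b$x, factor(b$y), type = "C-svc", C = 1,
                         kernel = "rbfdot", kpar = list(sigma = g),
                         scaled = FALSE)
    theirs <- as.integer(as.character(kernlab::predict(ref, b$x)))
    expect_equal(mine, theirs)
  }
})

test_that("one-vs-one voting matches a hand-enumerated tally", {
  # 3 well-separated classes in 2D
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  x <- with_seed(43, centers[rep(1:3, each = 8), ] + matrix(rnorm(48, 0, 0.4),
                                                           24, 2))
  y <- rep(0:2, each = 8)
  K <- single_gram(x, kernel = "linear")
  m <- svm_train_precomputed(K, y, C = 10)
  dec <- svm_decision_precomputed(m, K)
  votes <- svm_predict_precomputed(m, K, type = "votes")
  # brute-force tally from the pairwise decision signs
  expect_equal(colnames(dec), c("0/1", "0/2", "1/2"))
  hand <- t(apply(dec, 1, function(d) {
    v <- c(0, 0, 0)
    v[if (d[1] >= 0) 1 else 2] <- v[if (d[1] >= 0) 1 else 2] + 1
    v[if (d[2] >= 0) 1 else 3] <- v[if (d[2] >= 0) 1 else 3] + 1
    v[if (d[3] >= 0) 2 else 3] <- v[if (d[3] >= 0) 2 else 3] + 1
    v
  }))
  expect_equal(unname(votes), hand, ignore_attr = TRUE)
  expect_equal(svm_predict_precomputed(m, K), y)
})

test_that("binary predictions flip when decision values are negated", {
  b <- make_blobs(15, sep = 3, seed = 44)
  K <- single_gram(b$x, kernel = "linear")
  m <- svm_train_precomputed(K, b$y, C = 1)
  dec <- svm_decision_precomputed(m, K)
  pred <- svm_predict_precomputed(m, K)
  flipped <- ifelse(-dec >= 0, m$classes[1], m$classes[2])
  # rows away from the boundary flip exactly; |dec| > 0 for all here
  expect_true(all(pred[dec > 0] == 0) && all(pred[dec < 0] == 1))
  expect_equal(as.integer(flipped[dec != 0]), 1L - pred[dec != 0])
})

test_that("prediction is invariant to test-row order", {
  b <- make_blobs(20, sep = 2, seed = 45)
  fit <- hksvm(b$x, b$y)
  newx <- with_seed(46, matrix(rnorm(30), 15, 2))
  p <- predict(fit, newx)
  perm <- with_seed(47, sample.int(15))
  expect_equal(predict(fit, newx[perm, ])[order(perm)], p)
})

test_that("training rejects degenerate inputs", {
  K <- diag(3)
  expect_error(svm_train_precomputed(K, c(0L, 0L, 0L), C = 1), "2 classes")
  expect_error(svm_train_precomputed(K, c(0L, 1L, 0L), C = -1), "positive")
  expect_error(svm_train_precomputed(matrix(1:6, 2), c(0L, 1L), C = 1),
               "square")
  # indefinite Gram is caught when a psd action is requested
  Kbad <- matrix(c(1, 2, 2, 1), 2)
  expect_warning(svm_train_precomputed(Kbad, c(0L, 1L), C = 1,
                                       psd_action = "warn"), "indefinite")
  expect_error(svm_train_precomputed(Kbad, c(0L, 1L), C = 1,
                                     psd_action = "fail"), "indefinite")
})

test_that("cross-validation is exact on separable data and fair on noise", {
  b <- make_blobs(40, d = 2, sep = 8, seed = 48)
  cv <- cross_validate(b$x, b$y, hybrid_weights(1/3, 1/3, 1/3, 0.5), seed = 1)
  expect_equal(cv$mean_accuracy, 100)
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracies), tolerance = 1e-9)

  # randomly permuted labels: accuracy within binomial 3-sigma of 50%
  x <- with_seed(49, matrix(rnorm(500 * 2), 500, 2))
  y <- with_seed(50, sample(rep(0:1, each = 250)))
  cv2 <- cross_validate(x, y, single_kernel_weights("rbf"), seed = 2)
  expect_lt(abs(cv2$mean_accuracy - 50), 7)
})

test_that("fold assignment is stratified, deterministic and exhaustive", {
  y <- rep(0:2, times = c(20, 21, 22))
  f1 <- make_folds(y, 5, seed = 7)
  f2 <- make_folds(y, 5, seed = 7)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:5)
  for (cl in 0:2) {
    sizes <- table(f1[y == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  cv_a <- cross_validate(matrix(rnorm(126), 63), y, seed = 11)
  cv_b <- cross_validate(matrix(rnorm(126), 63), y, seed = 11)
  expect_identical(cv_a$fold_assignments, cv_b$fold_assignments)
})

test_that("fold count shrinks with a warning when a class is tiny", {
  b <- make_blobs(30, sep = 6, seed = 51)
  y <- b$y; y[1:3] <- 2L # classes sized 27, 30, 3
  expect_warning(cv <- cross_validate(b$x, y, folds = 5, seed = 1),
                 "reducing")
  expect_equal(cv$folds, 3L)
})
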