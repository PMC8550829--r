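kp_unit <- kernel_params(rbf_gamma = 1, poly_gamma = 1, poly_coef0 = 1,
                         poly_degree = 2)

test_that("scalar kernels match their closed forms", {
  expect_equal(kernel_linear(c(1, 2), c(3, 4)), 11)
  expect_equal(kernel_linear(c(1, 0), c(0, 1)), 0)
  expect_equal(kernel_linear(c(0, 0), c(5, -2)), 0)
  expect_error(kernel_linear(1:2, 1:3), "equal length")

  expect_equal(kernel_rbf(c(1, 2), c(1, 2), 1), 1)
  expect_equal(kernel_rbf(c(0, 0), c(1, 0), 1), exp(-1))
  expect_equal(kernel_rbf(c(1, 2), c(3, 4), 0.5), exp(-4)) # ||u-v||^2 = 8
  expect_error(kernel_rbf(1, 2, -1), "positive")

  p <- kernel_params(poly_gamma = 1, poly_coef0 = 0, poly_degree = 1)
  expect_equal(kernel_polynomial(c(1, 2), c(3, 4), p),
               kernel_linear(c(1, 2), c(3, 4)))
  expect_equal(kernel_polynomial(c(1, 0), c(1, 0), kp_unit), 4) # (1+1)^2
  p3 <- kernel_params(poly_gamma = 0.5, poly_coef0 = 1, poly_degree = 3)
  expect_equal(kernel_polynomial(c(1, 2), c(3, 4), p3), 6.5^3) # 274.625

  ps <- kernel_params(sigmoid_gamma = 1, sigmoid_coef0 = 0)
  expect_equal(kernel_sigmoid(c(1, 0), c(0, 1), ps), 0)
  ps2 <- kernel_params(sigmoid_gamma = 0.5, sigmoid_coef0 = -1)
  expect_equal(kernel_sigmoid(c(1, 1), c(1, 1), ps2), 0) # tanh(0)
  big <- kernel_sigmoid(rep(10, 2), rep(10, 2), ps)
  expect_lt(abs(big - 1), 1e-8) # tanh saturation
})

test_that("hybrid weights enforce the simplex and gamma constraints", {
  expect_error(hybrid_weights(0.5, 0.5, 0.5, 0.5), "sum to 1")
  expect_error(hybrid_weights(-0.2, 0.6, 0.6, 0.5), "non-negative")
  expect_error(hybrid_weights(1, 0, 0, 1.5), "0, 1")
  w <- hybrid_weights(0.2, 0.3, 0.5, 0.7)
  expect_equal(as.numeric(w), c(0.2, 0.3, 0.5, 0.7))
})

test_that("pairwise mixing interpolates and collapses at the boundaries", {
  Ka <- matrix(c(2, 0, 0, 2), 2); Kb <- matrix(c(4, 1, 1, 4), 2)
  expect_identical(pairwise_hybrid(Ka, Kb, 1), Ka)
  expect_identical(pairwise_hybrid(Ka, Kb, 0), Kb)
  expect_equal(pairwise_hybrid(matrix(2), matrix(4), 0.5), matrix(3))
  expect_error(pairwise_hybrid(Ka, matrix(1), 0.5), "shapes")
  expect_error(pairwise_hybrid(Ka, Kb, 1.2), "0, 1")
  # literal subtractive reading, kept for study: gamma Ka - (1-gamma) Kb
  expect_equal(pairwise_hybrid(matrix(2), matrix(4), 0.25,
                               literal_signed = TRUE), matrix(-2.5))
})

test_that("hybrid Gram collapses to single kernels at every boundary", {
  X <- with_seed(21, matrix(rnorm(24), 8, 3))
  kp <- kernel_params(d = 3, poly_coef0 = 1)
  lin <- single_gram(X, kernel = "linear", params = kp)
  rbf <- single_gram(X, kernel = "rbf", params = kp)
  pol <- single_gram(X, kernel = "polynomial", params = kp)
  cases <- list(
    list(hybrid_weights(1, 0, 0, 1), lin),  # K1 at gamma 1
    list(hybrid_weights(1, 0, 0, 0), rbf),  # K1 at gamma 0
    list(hybrid_weights(0, 1, 0, 1), pol),  # K2 at gamma 1
    list(hybrid_weights(0, 1, 0, 0), rbf),  # K2 at gamma 0
    list(hybrid_weights(0, 0, 1, 1), lin),  # K3 at gamma 1
    list(hybrid_weights(0, 0, 1, 0), pol),  # K3 at gamma 0
    list(hybrid_weights(0.5, 0.5, 0, 0), rbf),  # shared-RBF edge
    list(hybrid_weights(0.5, 0, 0.5, 1), lin))  # shared-linear edge
  for (cs in cases) {
    expect_equal(hybrid_gram(X, weights = cs[[1]], params = kp), cs[[2]],
                 tolerance = 1e-15)
  }
})

test_that("vectorized hybrid Gram equals the scalar-loop oracle entrywise", {
  Xa <- with_seed(22, matrix(rnorm(15), 5, 3))
  Xb <- with_seed(23, matrix(rnorm(12), 4, 3))
  kp <- kernel_params(rbf_gamma = 0.7, poly_gamma = 0.4, poly_coef0 = 1,
                      poly_degree = 3)
  for (seed in 1:5) {
    w <- random_weights(seed)
    expect_equal(hybrid_gram(Xa, Xb, weights = w, params = kp),
                 gram_oracle(Xa, Xb, w, kp), tolerance = 1e-12)
  }
})

test_that("the two-point hybrid composes from the single-kernel values", {
  X <- rbind(c(0, 0), c(1, 0))
  kp <- kernel_params(rbf_gamma = 1, poly_gamma = 1, poly_coef0 = 1,
                      poly_degree = 2)
  w <- hybrid_weights(1/3, 1/3, 1/3, 0.5)
  expect_equal(hybrid_gram(X, weights = w, params = kp),
               gram_oracle(X, X, w, kp), tolerance = 1e-12)
})

test_that("hybrid Grams are symmetric and positive semidefinite", {
  for (seed in 1:20) {
    X <- with_seed(300 + seed, matrix(rnorm(50 * 4), 50, 4))
    w <- random_weights(seed)
    K <- hybrid_gram(X, weights = w,
                     params = kernel_params(d = 4, poly_coef0 = 1))
    expect_lt(max(abs(K - t(K))), 1e-10)
    chk <- check_psd(K, tol = 1e-8)
    expect_true(chk$psd)
    expect_gte(chk$min_eigenvalue, -1e-8)
  }
})

test_that("check_psd reports eigenvalues and rejects non-square input", {
  chk <- check_psd(diag(2))
  expect_true(chk$psd)
  expect_equal(chk$min_eigenvalue, 1)
  chk2 <- check_psd(matrix(c(1, 2, 2, 1), 2))
  expect_false(chk2$psd)
  expect_equal(chk2$min_eigenvalue, -1) # eigenvalues 3 and -1
  expect_error(check_psd(matrix(1:6, 2)), "square")
})

test_that("the literal subtractive hybrid is indefinite where the convex one is not", {
  X <- with_seed(31, matrix(rnorm(40), 20, 2))
  kp <- kernel_params(d = 2)
  w <- hybrid_weights(1, 0, 0, 0.5)
  K_lit <- hybrid_gram(X, weights = w, params = kp, literal_signed = TRUE)
  expect_false(check_psd(K_lit, tol = 1e-8)$psd)
})
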