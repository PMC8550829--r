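# The kernel layer: single kernels, the three pairwise hybrids, the final
# simplex-weighted hybrid kernel, and Gram-matrix construction/validation.
#
# Two distinct gammas appear in this model family and are named apart here:
# `rbf_gamma`/`poly_gamma` live INSIDE the single kernels, while `mix_gamma`
# is the coefficient blending each kernel pair in the hybrids.

#' Kernel-internal parameters
#'
#' Parameters of the single kernels. Defaults follow the common solver
#' convention of `gamma = 1/d` (set when `d` is supplied), `coef0 = 0` and
#' `degree = 3`.
#'
#' @param rbf_gamma positive RBF width parameter.
#' @param poly_gamma positive polynomial scale parameter.
#' @param poly_coef0 polynomial offset.
#' @param poly_degree integer polynomial degree (>= 1).
#' @param sigmoid_gamma,sigmoid_coef0 sigmoid kernel parameters (the sigmoid
#'   kernel is provided as a single kernel only; it never enters the hybrid).
#' @param d optional feature count used to default the gammas to `1/d`.
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(rbf_gamma = NULL, poly_gamma = NULL, poly_coef0 = 0,
                          poly_degree = 3, sigmoid_gamma = NULL,
                          sigmoid_coef0 = 0, d = NULL) {
  fallback <- if (!is.null(d)) 1 / d else 1
  rbf_gamma <- rbf_gamma %||% fallback
  poly_gamma <- poly_gamma %||% fallback
  sigmoid_gamma <- sigmoid_gamma %||% fallback
  if (rbf_gamma <= 0) stop_hksvm("rbf_gamma must be positive")
  if (poly_gamma <= 0) stop_hksvm("poly_gamma must be positive")
  if (!is_count(poly_degree)) stop_hksvm("poly_degree must be an integer >= 1")
  structure(list(rbf_gamma = rbf_gamma, poly_gamma = poly_gamma,
                 poly_coef0 = poly_coef0, poly_degree = as.integer(poly_degree),
                 sigmoid_gamma = sigmoid_gamma, sigmoid_coef0 = sigmoid_coef0),
            class = "kernel_params")
}

#' Hybrid kernel mixing weights
#'
#' The coefficient vector searched by the genetic algorithm: simplex weights
#' `alpha1 + alpha2 + alpha3 = 1` (all non-negative) over the three pairwise
#' hybrids, and the shared pairwise mixing coefficient `mix_gamma` in
#' `[0, 1]`.
#'
#' @param alpha1 weight of the linear-RBF hybrid K1.
#' @param alpha2 weight of the polynomial-RBF hybrid K2.
#' @param alpha3 weight of the linear-polynomial hybrid K3.
#' @param mix_gamma pairwise mixing coefficient in `[0, 1]`.
#' @return An object of class `hybrid_weights`.
#' @export
hybrid_weights <- function(alpha1, alpha2, alpha3, mix_gamma) {
  a <- c(alpha1, alpha2, alpha3)
  if (any(a < -1e-9)) stop_hksvm("alpha weights must be non-negative")
  if (abs(sum(a) - 1) > 1e-9) stop_hksvm("alpha weights must sum to 1")
  if (mix_gamma < -1e-12 || mix_gamma > 1 + 1e-12) {
    stop_hksvm("mix_gamma must lie in [0, 1]")
  }
  structure(list(alpha1 = a[1], alpha2 = a[2], alpha3 = a[3],
                 mix_gamma = min(max(mix_gamma, 0), 1)),
            class = "hybrid_weights")
}

#' @export
print.hybrid_weights <- function(x, ...) {
  cat(sprintf(
    "<hybrid_weights> alpha = (%.4f, %.4f, %.4f), mix_gamma = %.4f\n",
    x$alpha1, x$alpha2, x$alpha3, x$mix_gamma))
  invisible(x)
}

check_lengths <- function(u, v) {
  if (length(u) != length(v)) stop_hksvm("u and v must have equal length")
}

#' Single kernel functions
#'
#' Scalar kernel evaluations between two feature vectors: the inner product
#' (linear), `exp(-gamma * ||u - v||^2)` (RBF), `(gamma * u'v + coef0)^degree`
#' (polynomial) and `tanh(gamma * u'v + coef0)` (sigmoid).
#'
#' @param u,v numeric vectors of equal length.
#' @param rbf_gamma positive RBF width.
#' @param params a [kernel_params()] object.
#' @return A single kernel value.
#' @name single_kernels
NULL

#' @rdname single_kernels
#' @export
kernel_linear <- function(u, v) {
  check_lengths(u, v)
  sum(u * v)
}

#' @rdname single_kernels
#' @export
kernel_rbf <- function(u, v, rbf_gamma) {
  check_lengths(u, v)
  if (rbf_gamma <= 0) stop_hksvm("rbf_gamma must be positive")
  exp(-rbf_gamma * sum((u - v)^2))
}

#' @rdname single_kernels
#' @export
kernel_polynomial <- function(u, v, params) {
  check_lengths(u, v)
  (params$poly_gamma * sum(u * v) + params$poly_coef0)^params$poly_degree
}

#' @rdname single_kernels
#' @export
kernel_sigmoid <- function(u, v, params) {
  check_lengths(u, v)
  tanh(params$sigmoid_gamma * sum(u * v) + params$sigmoid_coef0)
}

#' Gram matrix of a single kernel
#'
#' Vectorized pairwise kernel evaluations between the rows of `Xa` and `Xb`.
#'
#' @param Xa,Xb numeric matrices with equal column counts; `Xb` defaults to
#'   `Xa`.
#' @param kernel one of `"linear"`, `"rbf"`, `"polynomial"`, `"sigmoid"`.
#' @param params a [kernel_params()] object.
#' @return An `nrow(Xa)` x `nrow(Xb)` matrix.
#' @export
single_gram <- function(Xa, Xb = NULL,
                        kernel = c("linear", "rbf", "polynomial", "sigmoid"),
                        params = kernel_params(d = ncol(Xa))) {
  kernel <- match.arg(kernel)
  Xa <- as.matrix(Xa); Xb <- if (is.null(Xb)) Xa else as.matrix(Xb)
  if (ncol(Xa) != ncol(Xb)) stop_hksvm("column counts differ")
  lin <- tcrossprod(Xa, Xb)
  switch(kernel,
    linear = lin,
    rbf = {
      d2 <- outer(rowSums(Xa^2), rowSums(Xb^2), "+") - 2 * lin
      exp(-params$rbf_gamma * pmax(d2, 0))
    },
    polynomial = (params$poly_gamma * lin + params$poly_coef0)^params$poly_degree,
    sigmoid = tanh(params$sigmoid_gamma * lin + params$sigmoid_coef0))
}

#' Mix two Gram matrices pairwise
#'
#' The convex pairwise hybrid `mix_gamma * Ka + (1 - mix_gamma) * Kb`. The
#' three hybrids of the model are K1 = mix(linear, RBF), K2 =
#' mix(polynomial, RBF) and K3 = mix(linear, polynomial), all sharing one
#' `mix_gamma`. With `literal_signed = TRUE` the subtractive form
#' `mix_gamma * Ka - (1 - mix_gamma) * Kb` is computed instead; it is
#' generally indefinite and provided only for studying that reading (see the
#' methods vignette).
#'
#' @param Ka,Kb numeric matrices of identical shape.
#' @param mix_gamma mixing coefficient in `[0, 1]`.
#' @param literal_signed compute the subtractive form (default `FALSE`).
#' @return A matrix of the same shape.
#' @export
pairwise_hybrid <- function(Ka, Kb, mix_gamma, literal_signed = FALSE) {
  if (!all(dim(Ka) == dim(Kb))) stop_hksvm("Ka and Kb shapes differ")
  if (mix_gamma < 0 || mix_gamma > 1) stop_hksvm("mix_gamma must lie in [0, 1]")
  if (literal_signed) mix_gamma * Ka - (1 - mix_gamma) * Kb
  else mix_gamma * Ka + (1 - mix_gamma) * Kb
}

base_grams <- function(Xa, Xb, params) {
  lin <- tcrossprod(as.matrix(Xa), as.matrix(Xb))
  d2 <- outer(rowSums(Xa^2), rowSums(Xb^2), "+") - 2 * lin
  list(linear = lin,
       rbf = exp(-params$rbf_gamma * pmax(d2, 0)),
       polynomial = (params$poly_gamma * lin + params$poly_coef0)^params$poly_degree)
}

combine_grams <- function(base, w, literal_signed = FALSE) {
  g <- w$mix_gamma
  if (literal_signed) {
    K1 <- g * base$linear - (1 - g) * base$rbf
    K2 <- g * base$polynomial - (1 - g) * base$rbf
    K3 <- g * base$linear - (1 - g) * base$polynomial
  } else {
    K1 <- g * base$linear + (1 - g) * base$rbf
    K2 <- g * base$polynomial + (1 - g) * base$rbf
    K3 <- g * base$linear + (1 - g) * base$polynomial
  }
  w$alpha1 * K1 + w$alpha2 * K2 + w$alpha3 * K3
}

#' Hybrid-kernel Gram matrix
#'
#' Builds the final hybrid kernel `Kh = alpha1 K1 + alpha2 K2 + alpha3 K3`
#' between the rows of `Xa` and `Xb`, where K1, K2 and K3 are the pairwise
#' hybrids of [pairwise_hybrid()] built from one shared `mix_gamma`. As a
#' convex combination of Mercer kernels, Kh is symmetric positive
#' semidefinite whenever `Xa` and `Xb` coincide.
#'
#' @param Xa numeric matrix of rows indexing the Gram rows.
#' @param Xb numeric matrix indexing the Gram columns; defaults to `Xa`.
#' @param weights a [hybrid_weights()] object.
#' @param params a [kernel_params()] object.
#' @param literal_signed compute the subtractive pairwise form (see
#'   [pairwise_hybrid()]).
#' @return An `nrow(Xa)` x `nrow(Xb)` Gram matrix.
#' @export
hybrid_gram <- function(Xa, Xb = NULL, weights, params = kernel_params(d = ncol(Xa)),
                        literal_signed = FALSE) {
  stopifnot(inherits(weights, "hybrid_weights"))
  Xa <- as.matrix(Xa); Xb <- if (is.null(Xb)) Xa else as.matrix(Xb)
  if (ncol(Xa) != ncol(Xb)) stop_hksvm("column counts differ")
  combine_grams(base_grams(Xa, Xb, params), weights, literal_signed)
}

#' Check positive semidefiniteness of a Gram matrix
#'
#' Verifies the Mercer property the SVM dual solver assumes: symmetric and
#' smallest eigenvalue at least `-tol`.
#'
#' @param K square numeric matrix.
#' @param tol non-negative tolerance (default 1e-8).
#' @return A list with `psd` (logical) and `min_eigenvalue`.
#' @export
check_psd <- function(K, tol = 1e-8) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop_hksvm("K must be square")
  if (max(abs(K - t(K))) > max(tol, 1e-10) * max(1, max(abs(K)))) {
    stop_hksvm("K is not symmetric within tolerance")
  }
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  list(psd = min(ev) >= -tol, min_eigenvalue = min(ev))
}

#' Boundary weights reproducing a single kernel
#'
#' Returns the [hybrid_weights()] at which the hybrid kernel collapses
#' exactly to one single kernel: `(1,0,0)` with `mix_gamma = 1` is linear,
#' `(1,0,0)` with `mix_gamma = 0` is RBF, `(0,0,1)` with `mix_gamma = 0` is
#' polynomial.
#'
#' @param kernel one of `"linear"`, `"rbf"`, `"polynomial"`.
#' @return A [hybrid_weights()] object.
#' @export
single_kernel_weights <- function(kernel = c("linear", "rbf", "polynomial")) {
  switch(match.arg(kernel),
    linear = hybrid_weights(1, 0, 0, 1),
    rbf = hybrid_weights(1, 0, 0, 0),
    polynomial = hybrid_weights(0, 0, 1, 0))
}
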