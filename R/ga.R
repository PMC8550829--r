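# Genetic algorithm over the hybrid-kernel weights (and optionally C), with
# negative mean k-fold cross-validation accuracy as the fitness to minimize,
# plus an exhaustive simplex-lattice grid search used as a verification
# oracle.

#' Project raw values onto the weight simplex
#'
#' Constraint repair used when decoding a genome: negatives are clipped to
#' zero, then the vector is divided by its sum. An all-zero vector after
#' clipping maps to the uniform weights `(1/3, 1/3, 1/3)`.
#'
#' @param raw numeric vector of 3 raw values.
#' @return A numeric vector on the probability simplex.
#' @export
#' @examples
#' repair_simplex(c(2, 1, 1))
#' repair_simplex(c(-1, 1, 1))
repair_simplex <- function(raw) {
  stopifnot(length(raw) == 3)
  a <- pmax(raw, 0)
  s <- sum(a)
  if (s <= 0) return(rep(1/3, 3))
  a / s
}

#' Genetic algorithm settings
#'
#' Conventional small-scale GA settings: tournament selection, arithmetic
#' blend crossover, per-gene Gaussian mutation, and elitism. The search
#' stops after `generations` generations or once the best fitness has not
#' improved by more than `stall_tol` for `stall_patience` generations.
#'
#' @param population_size individuals per generation (default 50).
#' @param generations maximum generations (default 100).
#' @param tournament_size competitors per tournament (default 3).
#' @param crossover_prob probability a child is produced by blend crossover
#'   (default 0.8).
#' @param mutation_prob per-gene mutation probability (default 0.1).
#' @param mutation_sigma Gaussian mutation standard deviation (default 0.1).
#' @param elitism number of best individuals copied unchanged (default 1).
#' @param stall_patience generations without improvement before stopping
#'   (default 20).
#' @param stall_tol minimum improvement that resets the stall counter.
#' @param search_C also search the box constraint C on a log10 scale.
#' @param C_bounds `c(low, high)` bounds for C when searched.
#' @param seed integer seed for the whole run.
#' @return An object of class `ga_control`.
#' @export
ga_control <- function(population_size = 50, generations = 100,
                       tournament_size = 3, crossover_prob = 0.8,
                       mutation_prob = 0.1, mutation_sigma = 0.1,
                       elitism = 1, stall_patience = 20, stall_tol = 1e-6,
                       search_C = FALSE, C_bounds = c(1e-2, 1e2), seed = 1) {
  stopifnot(population_size >= tournament_size, tournament_size >= 2,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            elitism >= 1, generations >= 0)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 tournament_size = as.integer(tournament_size),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 mutation_sigma = mutation_sigma,
                 elitism = as.integer(elitism),
                 stall_patience = as.integer(stall_patience),
                 stall_tol = stall_tol, search_C = isTRUE(search_C),
                 C_bounds = C_bounds, seed = as.integer(seed)),
            class = "ga_control")
}

decode_genome <- function(genome, control) {
  a <- repair_simplex(genome[1:3])
  g <- min(max(genome[4], 0), 1)
  C <- if (control$search_C) {
    lb <- log10(control$C_bounds[1]); ub <- log10(control$C_bounds[2])
    10^min(max(genome[5], lb), ub)
  } else NA_real_
  list(weights = hybrid_weights(a[1], a[2], a[3], g), C = C)
}

genome_key <- function(genome, control) {
  dec <- decode_genome(genome, control)
  vals <- c(as.numeric(dec$weights), if (control$search_C) dec$C)
  paste(sprintf("%.9f", round(vals, 9)), collapse = ",")
}

make_fitness <- function(x, y, kernel_params, C, folds, fold_seed, control) {
  base <- base_grams(x, x, kernel_params)
  counts <- table(y)
  k <- min(folds, min(counts))
  if (k < folds) {
    warning(sprintf("smallest class has %d members; reducing to %d folds",
                    min(counts), k), call. = FALSE)
  }
  folds_idx <- make_folds(y, k, fold_seed)
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  list(
    fn = function(genome) {
      key <- genome_key(genome, control)
      if (!is.null(cache[[key]])) return(cache[[key]])
      dec <- decode_genome(genome, control)
      Cv <- if (control$search_C) dec$C else C
      val <- tryCatch(
        -mean(cv_from_grams(base, y, folds_idx, dec$weights, Cv)),
        error = function(e) {
          warning("fitness evaluation failed: ", conditionMessage(e),
                  call. = FALSE)
          0 # worst possible: 0% accuracy
        })
      evals <<- evals + 1L
      cache[[key]] <- val
      val
    },
    n_evals = function() evals,
    folds_idx = folds_idx, folds = k)
}

#' Tune hybrid-kernel weights by genetic algorithm
#'
#' Minimizes the negative mean k-fold cross-validation accuracy over the
#' mixing weights (`alpha1, alpha2, alpha3` on the simplex, `mix_gamma` in
#' `[0, 1]`, and optionally `C` on a log scale). Genomes are unconstrained
#' reals repaired on decode via [repair_simplex()] and clipping, so every
#' evaluated candidate is feasible. The fold assignment is fixed across all
#' fitness evaluations within a run, making fitness comparisons exact and
#' cacheable; the single-kernel Gram matrices are computed once and reused.
#'
#' @param x numeric feature matrix.
#' @param y integer labels in `0..C-1`.
#' @param control a [ga_control()] object.
#' @param kernel_params a [kernel_params()] object (default gammas `1/d`).
#' @param C box constraint used when `control$search_C` is `FALSE`.
#' @param folds cross-validation folds for the fitness (default 5).
#' @param fold_seed seed for the fold assignment; defaults to
#'   `derive_seed(control$seed, 1)`.
#' @return An object of class `hksvm_tune` with `best_weights`, `best_C`,
#'   `best_fitness` (negative mean CV accuracy in percent), `best_cv_accuracy`,
#'   `history` (per-generation best and mean fitness), and `evaluations`.
#' @seealso [grid_search_weights()] for the exhaustive oracle.
#' @export
tune_hksvm <- function(x, y, control = ga_control(), kernel_params = NULL,
                       C = 1, folds = 5, fold_seed = NULL) {
  x <- as.matrix(x); y <- as.integer(y)
  kernel_params <- kernel_params %||% kernel_params(d = ncol(x))
  fold_seed <- fold_seed %||% derive_seed(control$seed, 1)
  fit <- make_fitness(x, y, kernel_params, C, folds, fold_seed, control)
  ng <- if (control$search_C) 5L else 4L
  lb <- c(0, 0, 0, 0, if (control$search_C) log10(control$C_bounds[1]))
  ub <- c(1, 1, 1, 1, if (control$search_C) log10(control$C_bounds[2]))

  run <- with_seed(control$seed, {
    pop <- matrix(stats::runif(control$population_size * ng), ncol = ng)
    pop <- sweep(sweep(pop, 2, ub - lb, "*"), 2, lb, "+")
    fitness <- apply(pop, 1, fit$fn)
    best_i <- which.min(fitness)
    best_genome <- pop[best_i, ]; best_fit <- fitness[best_i]
    history <- data.frame(generation = 0L, best = best_fit,
                          mean = mean(fitness))
    stall <- 0L
    gen <- 0L
    while (gen < control$generations && stall < control$stall_patience) {
      gen <- gen + 1L
      ord <- order(fitness)
      elite <- pop[ord[seq_len(control$elitism)], , drop = FALSE]
      children <- matrix(NA_real_, control$population_size - control$elitism,
                         ng)
      for (i in seq_len(nrow(children))) {
        pick <- function() {
          cand <- sample.int(control$population_size, control$tournament_size)
          pop[cand[which.min(fitness[cand])], ]
        }
        p1 <- pick()
        child <- if (stats::runif(1) < control$crossover_prob) {
          p2 <- pick()
          u <- stats::runif(ng) # per-gene arithmetic blend
          u * p1 + (1 - u) * p2
        } else p1
        mut <- stats::runif(ng) < control$mutation_prob
        if (any(mut)) {
          child[mut] <- child[mut] +
            stats::rnorm(sum(mut), 0, control$mutation_sigma * (ub[mut] - lb[mut]))
        }
        children[i, ] <- pmin(pmax(child, lb), ub)
      }
      pop <- rbind(elite, children)
      fitness <- apply(pop, 1, fit$fn)
      gen_best <- which.min(fitness)
      if (fitness[gen_best] < best_fit - control$stall_tol) {
        best_fit <- fitness[gen_best]
        best_genome <- pop[gen_best, ]
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (fitness[gen_best] < best_fit) { # keep tiny improvements too
          best_fit <- fitness[gen_best]
          best_genome <- pop[gen_best, ]
        }
      }
      history <- rbind(history,
                       data.frame(generation = gen, best = best_fit,
                                  mean = mean(fitness)))
    }
    list(best_genome = best_genome, best_fit = best_fit, history = history)
  })

  dec <- decode_genome(run$best_genome, control)
  structure(list(best_weights = dec$weights,
                 best_C = if (control$search_C) dec$C else C,
                 best_fitness = run$best_fit,
                 best_cv_accuracy = -run$best_fit,
                 history = run$history,
                 evaluations = fit$n_evals(),
                 folds = fit$folds, fold_seed = fold_seed,
                 control = control),
            class = "hksvm_tune")
}

#' @export
print.hksvm_tune <- function(x, ...) {
  cat("Genetic-algorithm hybrid-kernel tuning\n")
  cat(sprintf("  best CV accuracy: %.2f%% (%d-fold, %d fitness evaluations)\n",
              x$best_cv_accuracy, x$folds, x$evaluations))
  cat(sprintf("  best weights: alpha = (%.4f, %.4f, %.4f), mix_gamma = %.4f",
              x$best_weights$alpha1, x$best_weights$alpha2,
              x$best_weights$alpha3, x$best_weights$mix_gamma))
  if (x$control$search_C) cat(sprintf(", C = %.4g", x$best_C))
  cat("\n")
  invisible(x)
}

#' @export
plot.hksvm_tune <- function(x, ...) {
  h <- x$history
  graphics::plot(h$generation, -h$best, type = "s", lwd = 2,
                 xlab = "generation", ylab = "CV accuracy (%)",
                 main = "GA search progress", ...)
  graphics::lines(h$generation, -h$mean, lty = 2, col = "grey40")
  graphics::legend("bottomright", c("best", "population mean"),
                   lty = c(1, 2), lwd = c(2, 1), col = c("black", "grey40"),
                   bty = "n")
  invisible(x)
}

#' Exhaustive grid search over the weight simplex
#'
#' Evaluates the cross-validation fitness at every lattice point of the
#' alpha simplex with spacing `step`, crossed with `mix_gamma` on the same
#' lattice of `[0, 1]`. Serves as a brute-force verification oracle for
#' [tune_hksvm()]: ties are broken towards the lexicographically smallest
#' candidate, and the returned fitness is the exact minimum over the
#' lattice.
#'
#' @inheritParams tune_hksvm
#' @param step lattice spacing; `1/step` must be an integer.
#' @param fold_seed fold-assignment seed (use the tuner's to share folds).
#' @return A list with `best_weights`, `best_fitness`, `best_cv_accuracy`,
#'   and `evaluations`.
#' @export
grid_search_weights <- function(x, y, step = 0.1, kernel_params = NULL, C = 1,
                                folds = 5, fold_seed = 1) {
  m <- 1 / step
  if (abs(m - round(m)) > 1e-9) stop_hksvm("1/step must be an integer")
  m <- as.integer(round(m))
  x <- as.matrix(x); y <- as.integer(y)
  kernel_params <- kernel_params %||% kernel_params(d = ncol(x))
  control <- ga_control(seed = 1)
  fit <- make_fitness(x, y, kernel_params, C, folds, fold_seed, control)
  best <- NULL
  n_cand <- 0L
  for (i in 0:m) for (j in 0:(m - i)) {
    k <- m - i - j
    for (g in 0:m) {
      n_cand <- n_cand + 1L
      genome <- c(i / m, j / m, k / m, g / m)
      val <- fit$fn(genome)
      if (is.null(best) || val < best$val) {
        best <- list(val = val, genome = genome)
      }
    }
  }
  w <- decode_genome(best$genome, control)$weights
  list(best_weights = w, best_fitness = best$val,
       best_cv_accuracy = -best$val, evaluations = n_cand)
}
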