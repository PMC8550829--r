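`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random number generator seeded at `seed`, then
#' restores the caller's RNG state, so seeded internals never disturb the
#' user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a stage seed from a master seed
#'
#' Every stage of the pipeline draws its own seed from the master seed and a
#' stage index through a fixed affine map, so adding a stage never silently
#' reshuffles the randomness of the others. Results stay below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stage integer stage index (>= 1).
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1, 1)
#' derive_seed(1, 2)
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), is.numeric(stage), stage >= 1)
  as.integer((abs(master) %% 1e6) * 2039 + stage * 9973) %% 2147483587L + 1L
}

stop_hksvm <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == round(x) && x >= 1
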