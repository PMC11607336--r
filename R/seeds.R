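#' Derive a named child seed from a master seed
#'
#' All randomness in the package flows from a single integer master seed.
#' Each pipeline stage draws its own child seed derived from the master
#' seed and a stage name, so stages are individually reproducible and
#' re-running one stage does not perturb another.
#'
#' The derivation is a small deterministic integer hash (no dependency on
#' the R session RNG state), always in `[1, 2^31 - 2]`.
#'
#' @param seed integer master seed.
#' @param name character stage name, e.g. `"corpus"` or `"attack/rf"`.
#' @return a single integer seed.
#' @export
#' @examples
#' child_seed(1, "corpus")
#' child_seed(1, "corpus") == child_seed(1, "corpus")
child_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name),
            length(name) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (cp in utf8ToInt(name)) {
    h <- (h * 31 + cp) %% m
  }
  # avoid 0 (set.seed accepts it, but keep strictly positive for clarity)
  as.integer(h %% (m - 1) + 1)
}

#' Evaluate an expression under a local RNG state
#'
#' Saves and restores `.Random.seed` around `expr`, seeding with `seed`.
#' Keeps package internals from clobbering the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
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
  set.seed(as.integer(seed))
  expr
}
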