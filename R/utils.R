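#' Round half away from zero
#'
#' Deterministic rounding used for all pixel quantisation so results are
#' bit-stable across platforms (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @return `x` rounded to the nearest integer, halves away from zero.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Clip values to the 8-bit intensity range
#' @param x numeric vector.
#' @keywords internal
clip8 <- function(x) {
  pmin(pmax(x, 0), 255)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not clobber the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a per-item seed from a root seed
#'
#' All randomness in a pipeline run flows from one root seed; per-subject
#' streams are derived by counter so partial re-runs reproduce exactly.
#' The result stays below 2^31 - 1.
#'
#' @param root integer root seed.
#' @param counter nonnegative integer stream index.
#' @keywords internal
derive_seed <- function(root, counter) {
  as.integer((as.numeric(root) * 48271 + as.numeric(counter) * 16807 + 12345) %%
               2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
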