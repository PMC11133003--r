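`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals do not disturb
#' the caller's random number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# format doubles so that read.table round-trips them bit-identically
format_full <- function(x) sprintf("%.17g", x)

check_sex <- function(sex) {
  sex <- as.character(sex)
  bad <- setdiff(unique(sex), c("male", "female"))
  if (length(bad) > 0)
    stopf("unknown sex label(s): %s (expected 'male'/'female')",
          paste(bad, collapse = ", "))
  sex
}
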