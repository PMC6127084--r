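#' @keywords internal
"_PACKAGE"

## Internal utilities shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number stream seeded at `seed`, then
#' restores the previous stream, so no exported function leaks RNG state.
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
  invisible(NULL)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

## genotype key used to compare / deduplicate genotype vectors; NA-safe
geno_key <- function(x) paste(ifelse(is.na(x), "?", x), collapse = ",")
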