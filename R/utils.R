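# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded helpers do not disturb
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream label, kept < 2^31.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    for (ch in utf8ToInt(paste0(p))) h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
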