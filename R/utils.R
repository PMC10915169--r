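#' @keywords internal
#' @useDynLib ribocast, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

#' Evaluate code with a temporary RNG state
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' `.Random.seed` afterwards, so seeded package internals never clobber the
#' caller's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# half-up rounding (Fisher tables need integers; replicate-averaged tracks
# may be fractional)
round_half_up <- function(x) floor(x + 0.5)

abort_if <- function(cond, ...) {
  if (cond) stop(paste0(...), call. = FALSE)
}
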