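## Internal helpers shared across modules.

#' @importFrom stats rnorm runif rpois median
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the global RNG state, seeds it, evaluates `code`, and restores the
#' previous state, so deterministic sub-computations (e.g. a fitness
#' evaluation inside an optimizer loop) do not perturb the caller's RNG
#' stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
withLocalSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

## Derive a sub-seed from a master seed; kept well below .Machine$integer.max.
deriveSeed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

## Structured stage logging used by the pipeline.
logStage <- function(stage, ..., verbose = TRUE) {
  if (!verbose) return(invisible(NULL))
  msg <- paste0("", ...)
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  if (nzchar(msg)) paste0("| ", msg) else ""))
  invisible(NULL)
}

## Clamp a matrix/vector of positions into [lb, ub] (recycled by column).
clampToBounds <- function(x, lb, ub) {
  if (is.matrix(x)) {
    x <- pmin(pmax(x, matrix(lb, nrow(x), ncol(x), byrow = TRUE)),
              matrix(ub, nrow(x), ncol(x), byrow = TRUE))
  } else {
    x <- pmin(pmax(x, lb), ub)
  }
  x
}
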