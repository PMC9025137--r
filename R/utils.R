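`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_validation <- function(rule, ...) {
  stop(sprintf("validation error [%s]: %s", rule, sprintf(...)), call. = FALSE)
}

#' @noRd
stop_parse <- function(field, ...) {
  stop(sprintf("parse error [field '%s']: %s", field, sprintf(...)), call. = FALSE)
}

## Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
## Used by the synthetic-data generator so that the same seed always yields a
## byte-identical dataset without disturbing the session RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## gas constant, J mol-1 K-1
R_GAS <- 8.314
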