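# Classed conditions used across the package.  Every user-facing failure
# path raises one of these so callers (and the CLI) can map errors to
# documented exit codes without string matching.

tm_error <- function(class, message, ..., call = sys.call(-1)) {
  stop(structure(
    class = c(class, "taxomart_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

tm_parse_error      <- function(msg, ...) tm_error("tm_parse_error", msg, ...)
tm_integrity_error  <- function(msg, ...) tm_error("tm_integrity_error", msg, ...)
tm_not_found_error  <- function(msg, ...) tm_error("tm_not_found_error", msg, ...)
tm_usage_error      <- function(msg, ...) tm_error("tm_usage_error", msg, ...)
tm_config_error     <- function(msg, ...) tm_error("tm_config_error", msg, ...)
tm_acquisition_error <- function(msg, ...) tm_error("tm_acquisition_error", msg, ...)
tm_schema_error     <- function(msg, ...) tm_error("tm_schema_error", msg, ...)

#' Run an expression with a temporary RNG state
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's random
#' number generator state afterwards, so deterministic generators do not
#' perturb user simulations.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
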