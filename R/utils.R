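# Internal helpers: classed conditions, scoped RNG, formatting.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a validation error
#'
#' Validation errors (`mcpet_validation_error`) mark violated input
#' contracts; the command-line wrapper maps them to exit status 2, while
#' computation errors map to status 3.
#'
#' @param ... message fragments, pasted together.
#' @return Does not return; throws a classed condition.
#' @keywords internal
#' @noRd
stop_validation <- function(...) {
  stop(structure(
    class = c("mcpet_validation_error", "mcpet_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_computation <- function(...) {
  stop(structure(
    class = c("mcpet_computation_error", "mcpet_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is_number(x)) stop_validation(name, " must be a single finite number")
  if (strict_min && x <= min) stop_validation(name, " must be > ", min)
  if (!strict_min && x < min) stop_validation(name, " must be >= ", min)
  if (x > max) stop_validation(name, " must be <= ", max)
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed and restore the caller's RNG state
# afterwards, so library code never perturbs the user's random stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

fmt_num <- function(x, digits = 2) {
  formatC(x, format = "f", digits = digits)
}
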