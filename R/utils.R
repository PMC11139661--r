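# Internal helpers: classed conditions and seeded evaluation.

abort <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(paste0("blastonet_", class), "blastonet_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package internals do
#' not perturb user-level random streams. A `NULL` seed evaluates the
#' expression under the current RNG state.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# scalar checks ---------------------------------------------------------

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_positive_scalar <- function(x, name) {
  if (!is_scalar_num(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number", name),
          "invalid_parameter")
  }
  invisible(x)
}
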