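#' @keywords internal
"_PACKAGE"

## Classed conditions so callers can distinguish bad input from bad state.

abort_input <- function(msg, class = "colonysizer_input_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "colonysizer_error")))
}

abort_validation <- function(msg) {
  abort_input(msg, class = "colonysizer_validation_error")
}

abort_parse <- function(msg) {
  abort_input(msg, class = "colonysizer_parse_error")
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_validation(sprintf("`%s` must be a single finite number", name))
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper)
    abort_validation(sprintf("`%s` = %g is out of range", name, x))
  invisible(x)
}

is_unknown_dpi <- function(dpi) {
  is.null(dpi) || length(dpi) == 0L || is.na(dpi) ||
    (is.character(dpi) && identical(tolower(dpi), "unknown"))
}

## Evaluate an expression under a fixed RNG seed, restoring the caller's
## RNG state afterwards so generators never perturb user randomness.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
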