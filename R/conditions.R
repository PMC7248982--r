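#' @title Typed failure conditions
#' @description
#' Downstream withdrawal machinery must never turn an uninterpretable dataset
#' into a number. Failure states are signalled as classed conditions so callers
#' can distinguish "not calculable" (a legitimate scientific outcome, mirrored
#' in study reports as `NA`) from programming errors.
#' @name milkwdi-conditions
NULL

#' Signal a not-calculable state
#'
#' @param message human-readable explanation
#' @param class extra condition class, prepended to `"milkwdi_not_calculable"`
#' @param diagnostics named list carried on the condition for reporting
#' @keywords internal
not_calculable <- function(message, class = character(), diagnostics = list()) {
  stop(structure(
    class = c(class, "milkwdi_not_calculable", "error", "condition"),
    list(message = message, call = sys.call(-1), diagnostics = diagnostics)
  ))
}

#' Signal an input-contract (data format) error
#' @inheritParams not_calculable
#' @keywords internal
format_error <- function(message, diagnostics = list()) {
  stop(structure(
    class = c("milkwdi_format_error", "error", "condition"),
    list(message = message, call = sys.call(-1), diagnostics = diagnostics)
  ))
}

#' Capture a not-calculable condition as a value
#'
#' Runs `expr`; on a `milkwdi_not_calculable` condition returns a list with
#' `ok = FALSE`, the message and diagnostics, otherwise `ok = TRUE` and the
#' result. Used by the pipeline so one failed arm does not abort a report.
#' @param expr expression to evaluate
#' @export
tryNotCalculable <- function(expr) {
  tryCatch(
    list(ok = TRUE, result = expr),
    milkwdi_not_calculable = function(cnd) {
      list(ok = FALSE, result = NULL, message = conditionMessage(cnd),
           diagnostics = cnd$diagnostics)
    }
  )
}
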