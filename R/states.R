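#' Health states of the diabetic foot ulcer model
#'
#' The shipped model tracks a cohort of patients with an uninfected diabetic
#' foot ulcer (uDFU) through six mutually exclusive health states. `death` is
#' absorbing; all other states may be left.
#'
#' @return Character vector of the six canonical state names, in matrix order:
#'   `healed`, `uDFU`, `iDFU`, `gangrene`, `postamputation`, `death`.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("healed", "uDFU", "iDFU", "gangrene", "postamputation", "death")
}

# internal: stop() with a consistent prefix so validation errors are greppable
abort_model <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_states <- function(x, states, what = "state") {
  bad <- setdiff(x, states)
  if (length(bad) > 0L) {
    abort_model("unknown %s(s): %s (model states: %s)",
                what, paste(bad, collapse = ", "), paste(states, collapse = ", "))
  }
  invisible(x)
}
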